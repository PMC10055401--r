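# shared fixture builders; everything is generated in code at test time

tiny_genome <- function(...) genome_sequence(c(...))

# a single-exon record on "+"
se_record <- function(id, gene, seqid, start, end, cds_start = NULL,
                      cds_end = NULL, strand = "+") {
  cds <- if (!is.null(cds_start))
    exon_chain(seqid, cds_start, cds_end, strand) else NULL
  transcript_record(id, gene, exon_chain(seqid, start, end, strand), cds)
}

# A locus where the two selection modes must pick different ORFs.
#
# Reference A: a short complete ORF (10 codons + stop) the query contains
# entirely -> candidate O1 with ILPI 1.0 vs A but IL only 30.
# Reference B: a long ORF (100 codons + stop) of which the query contains
# only the first 60 coding bases before splicing into novel sequence with a
# stop -> candidate O2 with IL 60 but ILPI 0.2 vs B.
# maximize_ILPI must choose O1, maximize_IL must choose O2.
mode_divergent_fixture <- function() {
  g <- rep("C", 600)
  put <- function(g, at, s) { g[(at + 1):(at + nchar(s))] <- strsplit(s, "")[[1]]; g }
  o1 <- paste0("ATG", strrep("AAA", 9), "TAA")          # [10, 43)
  g <- put(g, 10, o1)
  bcds <- paste0("ATG", strrep("CAA", 99), "TAA")       # [100, 403)
  g <- put(g, 100, bcds)
  g <- put(g, 500, "CCCTAACCCCCC")                      # stop for O2 in exon 3
  genome <- tiny_genome(m = paste(g, collapse = ""))
  refA <- se_record("refA", "geneA", "m", 5, 50, 10, 43)
  refB <- se_record("refB", "geneB", "m", 95, 410, 100, 403)
  query <- transcript_record("q1", "geneQ",
                             exon_chain("m", c(5, 100, 500),
                                        c(50, 160, 512), "+"))
  list(genome = genome, refs = list(refA, refB), query = query,
       o1_chain = exon_chain("m", 10, 43, "+"),
       o2_chain = exon_chain("m", c(100, 500), c(160, 506), "+"))
}

# prefix all transcript/gene ids of a locus so loci can be merged into one
# annotation without id collisions
relabel_locus <- function(loc, prefix) {
  relab <- function(r) transcript_record(paste0(prefix, ".", r$transcript_id),
                                         paste0(prefix, ".", r$gene_id),
                                         r$exons, r$cds, r$attributes)
  loc$reference <- relab(loc$reference)
  loc$isoforms <- lapply(loc$isoforms, relab)
  loc
}

# strip CDS from records (turn truth isoforms into plain queries)
strip_cds <- function(records) {
  lapply(records, function(r)
    transcript_record(r$transcript_id, r$gene_id, r$exons, NULL,
                      r$attributes))
}

# enumerate every valid ORF of a query transcript as a genomic chain;
# used to check that the selected ORF dominates all alternatives
all_valid_orf_chains <- function(query, genome,
                                 params = search_params()) {
  s <- spliced_sequence(query$exons, genome)
  L <- nchar(s)
  out <- list()
  for (cc in 0:2) {
    M <- (L - cc) %/% 3L
    if (M < 3L) next
    off0 <- cc + 3L * (seq_len(M) - 1L)
    cod <- substring(s, off0 + 1L, off0 + 3L)
    is_stop <- cod %in% params$stop_codons
    is_start <- cod %in% params$start_codons
    for (K in which(is_stop)) {
      k <- K - 1L
      while (k >= 1L && !is_stop[k] && !grepl("N", cod[k], fixed = TRUE)) {
        if (is_start[k] && K - k >= 2L)
          out[[length(out) + 1L]] <-
            chain_from_tx_range(query$exons, off0[k], off0[K] + 3L)
        k <- k - 1L
      }
    }
  }
  out
}

# textbook affine-gap (Gotoh) LOCAL alignment score over BLOSUM62;
# independent check of the alignment route
sw_score_oracle <- function(a, b, open = 10, extend = 1) {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  S <- e$BLOSUM62
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(-Inf, n + 1, m + 1)   # gap in b
  Y <- matrix(-Inf, n + 1, m + 1)   # gap in a
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      X[i, j] <- max(M[i - 1, j] - open - extend, X[i - 1, j] - extend)
      Y[i, j] <- max(M[i, j - 1] - open - extend, Y[i, j - 1] - extend)
      M[i, j] <- max(0,
                     max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) +
                       S[A[i - 1], B[j - 1]])
      best <- max(best, M[i, j])
    }
  }
  best
}

# connected components of the CDS-span overlap graph, brute force;
# returns a canonical partition (sorted character keys)
brute_force_bundles <- function(refs, by_gene = FALSE) {
  n <- length(refs)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j || comp[i] == comp[j]) next
      a <- refs[[i]]; b <- refs[[j]]
      if (!identical(a$cds$seqid, b$cds$seqid) ||
          !identical(a$cds$strand, b$cds$strand)) next
      if (by_gene && !identical(a$gene_id, b$gene_id)) next
      sa <- chain_span(a$cds); sb <- chain_span(b$cds)
      if (sa[1] < sb[2] && sb[1] < sa[2]) {
        comp[comp == comp[j]] <- comp[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  split(vapply(refs, function(r) r$transcript_id, character(1)), comp)
}

# random single-exon reference set for bundling property tests,
# pre-sorted by (seqid, CDS start) as build_bundles expects
random_ref_set <- function(n, geneids = 3L) {
  refs <- lapply(seq_len(n), function(i) {
    s <- sample(0:900, 1)
    w <- sample(30:120, 1)
    cs <- s + 3L * sample(0:3, 1)
    ce <- cs + 3L * sample(4:8, 1) + 3L
    ce <- min(ce, s + w - 3L)
    if (ce - cs < 9L) { cs <- s; ce <- s + 9L }
    se_record(paste0("r", i), paste0("g", sample(geneids, 1)), "chrB",
              s, max(s + w, ce + 3L), cs, ce,
              strand = sample(c("+", "-"), 1))
  })
  refs[order(vapply(refs, function(r) r$cds$starts[1L], integer(1)))]
}
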