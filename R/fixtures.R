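#' Brute-force oracle: best ORF by exhaustive enumeration
#'
#' Independent verifier for the interval-based search: enumerates every
#' valid ORF of the query's spliced sequence (every start codon with its
#' downstream in-frame stop and no internal stop), computes every score
#' against every reference by direct per-position bookkeeping, applies the
#' per-stop start-selection rule and then the mode's selection cascade.
#' Intended for transcripts up to a few kilobases.
#'
#' @param query a [transcript_record()].
#' @param references list of [transcript_record()] with CDS chains.
#' @param genome a `genome_sequence`.
#' @param params [search_params()].
#' @return the winning [candidate_orf()] or `NULL`.
#' @export
oracle_best_orf <- function(query, references, genome,
                            params = search_params()) {
  refs <- Filter(function(r) !is.null(r$cds) &&
                   identical(r$cds$seqid, query$exons$seqid) &&
                   identical(r$cds$strand, query$exons$strand), references)
  if (!length(refs)) return(NULL)
  seq <- spliced_sequence(query$exons, genome)
  L <- nchar(seq)
  minc <- max(2L, params$min_orf_length)
  if (L < 3L * (minc + 1L)) return(NULL)

  ex <- query$exons
  gp <- integer(0)
  for (i in seq_along(ex$starts))
    gp <- c(gp, ex$starts[i]:(ex$ends[i] - 1L))
  if (ex$strand == "-") gp <- rev(gp)

  # genomic position -> reference coding offset, via a name-keyed table
  ref_offsets <- lapply(refs, function(r) {
    cds <- r$cds
    pos <- integer(0)
    for (i in seq_along(cds$starts))
      pos <- c(pos, cds$starts[i]:(cds$ends[i] - 1L))
    if (cds$strand == "-") pos <- rev(pos)
    pos <- pos[seq_len(length(pos) - 3L)]     # stop codon codes no residue
    tab <- stats::setNames(seq_along(pos) - 1L, pos)
    unname(tab[as.character(gp)])
  })

  # enumerate all valid ORFs
  orfs <- list()
  for (cc in 0:2) {
    M <- (L - cc) %/% 3L
    if (M < minc + 1L) next
    off0 <- cc + 3L * (seq_len(M) - 1L)
    cod <- substring(seq, off0 + 1L, off0 + 3L)
    is_start <- cod %in% params$start_codons
    is_stop <- cod %in% params$stop_codons
    bad <- grepl("N", cod, fixed = TRUE)
    matched <- lapply(ref_offsets, function(ro) {
      o1 <- ro[off0 + 1L]; o2 <- ro[off0 + 2L]; o3 <- ro[off0 + 3L]
      !is.na(o1) & !is.na(o2) & !is.na(o3) &
        o2 == o1 + 1L & o3 == o2 + 1L & (o1 %% 3L) == 0L
    })
    for (K in which(is_stop)) {
      for (k in seq_len(K - 1L)) {
        if (!is_start[k]) next
        if (K - k < minc) next
        body <- k:(K - 1L)
        if (any(is_stop[body[-1L]]) || any(bad[body])) next
        il <- vapply(matched, function(m) 3L * sum(m[body]), integer(1))
        orfs[[length(orfs) + 1L]] <- list(cc = cc, k = k, K = K, IL = il)
      }
    }
  }
  if (!length(orfs)) return(NULL)

  ref_lens <- vapply(refs, function(r) chain_length(r$cds) - 3L, integer(1))

  # per-(reference, stop) start selection: keep, for each reference and each
  # stop, the start maximizing the in-frame codon count, ties resolved by
  # mode (ilpi: 3'-most, il: 5'-most); the union over references survives
  keep <- rep(FALSE, length(orfs))
  key <- vapply(orfs, function(o) paste(o$cc, o$K), character(1))
  for (ri in seq_along(refs)) {
    for (kk in unique(key)) {
      idx <- which(key == kk)
      il <- vapply(idx, function(i) orfs[[i]]$IL[ri], integer(1))
      best <- idx[il == max(il)]
      ks <- vapply(best, function(i) orfs[[i]]$k, integer(1))
      pick <- if (params$mode == "ilpi") best[which.max(ks)]
              else best[which.min(ks)]
      keep[pick] <- TRUE
    }
  }
  orfs <- orfs[keep]

  # best score per candidate across references, then global cascade
  better <- function(il_a, rl_a, len_a, il_b, rl_b, len_b) {
    ilpi <- (il_a * rl_b > il_b * rl_a) - (il_a * rl_b < il_b * rl_a)
    il <- (il_a > il_b) - (il_a < il_b)
    len <- (len_a > len_b) - (len_a < len_b)
    ord <- if (params$mode == "ilpi") c(ilpi, il, len) else c(il, ilpi, len)
    nz <- ord[ord != 0L]
    if (length(nz)) nz[1L] else 0L
  }
  best <- NULL
  for (o in orfs) {
    len <- 3L * (o$K - o$k)
    bri <- 1L
    for (ri in seq_along(refs))
      if (ri > 1L && better(o$IL[ri], ref_lens[ri], len,
                            o$IL[bri], ref_lens[bri], len) > 0L) bri <- ri
    if (o$IL[bri] == 0L) next
    o$len <- len; o$bri <- bri
    o$tx_start <- o$cc + 3L * (o$k - 1L)
    if (is.null(best)) { best <- o; next }
    d <- better(o$IL[o$bri], ref_lens[o$bri], o$len,
                best$IL[best$bri], ref_lens[best$bri], best$len)
    if (d > 0L || (d == 0L && o$tx_start < best$tx_start)) best <- o
  }
  if (is.null(best)) return(NULL)

  tx_start <- best$tx_start
  tx_end <- best$cc + 3L * best$K
  p <- sort(gp[(tx_start + 1L):tx_end])
  brk <- which(diff(p) != 1L)
  chain <- exon_chain(ex$seqid, p[c(1L, brk + 1L)],
                      p[c(brk, length(p))] + 1L, ex$strand)
  ri <- best$bri
  # novel bases: candidate coding positions not covered by the best reference
  body_pos <- (tx_start + 1L):(tx_end - 3L)
  covered <- !is.na(ref_offsets[[ri]][body_pos])
  score <- list(IL = best$IL[ri],
                ILPI = best$IL[ri] / ref_lens[ri],
                length = best$len,
                novel_bases = as.integer(best$len - sum(covered)),
                ref_length = ref_lens[ri])
  candidate_orf(chain, tx_start, tx_end, refs[[ri]]$transcript_id, score)
}

.rand_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.rand_codons <- function(n, stop_codons) {
  all_cod <- as.vector(outer(as.vector(outer(c("A", "C", "G", "T"),
                                             c("A", "C", "G", "T"), paste0)),
                             c("A", "C", "G", "T"), paste0))
  paste(sample(setdiff(all_cod, stop_codons), n, replace = TRUE),
        collapse = "")
}

#' Mirror a genome and its annotations to the opposite strand
#'
#' Reverse-complements every sequence and flips all record coordinates and
#' strands so that the mirrored locus encodes exactly the same transcripts.
#' Useful for strand-symmetry checks.
#'
#' @param genome a `genome_sequence`.
#' @param records list of [transcript_record()].
#' @return list with mirrored `genome` and `records`.
#' @export
mirror_annotation <- function(genome, records) {
  seqs <- unclass(genome)
  glen <- stats::setNames(nchar(seqs), names(seqs))
  mg <- genome_sequence(stats::setNames(
    vapply(seqs, revcomp, character(1)), names(seqs)))
  flip <- function(ch) {
    if (is.null(ch)) return(NULL)
    G <- glen[[ch$seqid]]
    exon_chain(ch$seqid, G - ch$ends, G - ch$starts,
               if (ch$strand == "+") "-" else "+")
  }
  recs <- lapply(records, function(r)
    transcript_record(r$transcript_id, r$gene_id, flip(r$exons),
                      flip(r$cds), r$attributes))
  list(genome = mg, records = recs)
}

# apply one splice event to the reference exon structure (plus-strand
# construction coordinates); returns new (starts, ends) or NULL if infeasible
.apply_event <- function(event, starts, ends, glen) {
  n <- length(starts)
  switch(event,
    exon_skip = {
      if (n < 3L) return(NULL)
      j <- sample(2:(n - 1L), 1L)
      list(starts = starts[-j], ends = ends[-j])
    },
    alt_first_exon = {
      lo <- 5L; hi <- starts[1L] - 70L
      if (hi <= lo) return(NULL)
      s <- sample(lo:hi, 1L)
      len <- sample(40:60, 1L)
      list(starts = c(s, starts[-1L]), ends = c(s + len, ends[-1L]))
    },
    alt_3prime = {
      if (n < 2L) return(NULL)
      j <- sample(2:n, 1L)            # shift the acceptor of exon j
      d <- sample(c(-(1:20), 1:20), 1L)
      ns <- starts[j] + d
      if (ns <= ends[j - 1L] + 10L || ends[j] - ns < 10L) return(NULL)
      starts[j] <- ns
      list(starts = starts, ends = ends)
    },
    intron_retention = {
      if (n < 2L) return(NULL)
      j <- sample(seq_len(n - 1L), 1L)
      list(starts = starts[-(j + 1L)], ends = ends[-j])
    },
    extend_5utr = {
      d <- sample(10:100, 1L)
      if (starts[1L] - d < 1L) return(NULL)
      starts[1L] <- starts[1L] - d
      list(starts = starts, ends = ends)
    },
    extra_5utr_exon = {
      lo <- 5L; hi <- starts[1L] - 100L
      if (hi <= lo) return(NULL)
      s <- sample(lo:hi, 1L)
      len <- sample(30:80, 1L)
      if (s + len > starts[1L] - 10L) return(NULL)
      list(starts = c(s, starts), ends = c(s + len, ends))
    },
    extend_3utr = {
      d <- sample(10:100, 1L)
      if (ends[n] + d > glen - 1L) return(NULL)
      ends[n] <- ends[n] + d
      list(starts = starts, ends = ends)
    },
    stop("unknown splice event: ", event))
}

#' Generate a synthetic gene locus with ground-truth ORFs
#'
#' Builds a random 3-10 kb sequence containing one multi-exon gene whose
#' canonical ORF (3-30 codons per exon, valid start and stop guaranteed,
#' no internal in-frame stop) is embedded with 5' and 3' UTRs; isoforms
#' derived from the canonical transcript each apply one sampled splice
#' event, and each isoform's true best ORF (computed by the exhaustive
#' [oracle_best_orf()] against the canonical reference) is recorded as its
#' CDS. The first isoform is always the unmodified canonical transcript.
#' With `preserve_cds = TRUE`, events touch only untranslated regions, so
#' every isoform's exon chain contains the full canonical CDS chain.
#' Deterministic given `seed`. About half of generated loci are mirrored to
#' the minus strand.
#'
#' @param seed integer seed (sets the RNG state); `NULL` leaves the RNG
#'   untouched.
#' @param n_isoforms number of isoforms to derive (>= 1).
#' @param splice_events events sampled for isoforms 2..n: subset of
#'   `exon_skip`, `alt_first_exon`, `alt_3prime`, `intron_retention`.
#' @param preserve_cds restrict events to UTR-only modifications.
#' @param params [search_params()] used for the ground-truth ORFs.
#' @param seqid name of the generated sequence.
#' @return list with `genome`, `reference` (a [transcript_record()] with
#'   the canonical CDS), `isoforms` (records whose `cds` is the true best
#'   ORF, `NULL` when none exists), `strand`.
#' @export
make_locus <- function(seed = NULL, n_isoforms = 1L,
                       splice_events = c("exon_skip", "alt_first_exon",
                                         "alt_3prime", "intron_retention"),
                       preserve_cds = FALSE,
                       params = search_params(), seqid = "chrS") {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_isoforms >= 1L)
  if (preserve_cds)
    splice_events <- c("extend_5utr", "extra_5utr_exon", "extend_3utr")

  n_exons <- sample(3:6, 1L)
  codons <- sample(3:30, n_exons, replace = TRUE)
  coding <- paste0("ATG", .rand_codons(sum(codons) - 1L, params$stop_codons),
                   sample(params$stop_codons, 1L))
  clen <- nchar(coding)
  cuts <- sort(sample(seq_len(clen - 1L), n_exons - 1L))
  piece_len <- diff(c(0L, cuts, clen))
  utr5 <- sample(30:150, 1L)
  utr3 <- sample(30:200, 1L)
  introns <- sample(80:400, n_exons - 1L, replace = TRUE)
  up <- sample(300:600, 1L)

  exon_len <- piece_len
  exon_len[1L] <- exon_len[1L] + utr5
  exon_len[n_exons] <- exon_len[n_exons] + utr3
  starts <- integer(n_exons); ends <- integer(n_exons)
  pos <- up
  for (i in seq_len(n_exons)) {
    starts[i] <- pos
    ends[i] <- pos + exon_len[i]
    pos <- ends[i] + if (i < n_exons) introns[i] else 0L
  }
  down <- max(300L, 3000L - pos)
  glen <- pos + down

  # background sequence, then splice the coding pieces into place
  g <- strsplit(.rand_nt(glen), "")[[1]]
  cpos <- c(0L, cumsum(piece_len))
  for (i in seq_len(n_exons)) {
    cs <- starts[i] + if (i == 1L) utr5 else 0L
    piece <- substring(coding, cpos[i] + 1L, cpos[i + 1L])
    if (nchar(piece))
      g[(cs + 1L):(cs + piece_len[i])] <- strsplit(piece, "")[[1]]
  }
  genome <- genome_sequence(stats::setNames(paste(g, collapse = ""), seqid))

  cds_starts <- starts; cds_ends <- ends
  cds_starts[1L] <- starts[1L] + utr5
  cds_ends[n_exons] <- cds_starts[n_exons] +
    if (n_exons > 1L) piece_len[n_exons] else piece_len[1L]
  if (n_exons == 1L) cds_ends[1L] <- cds_starts[1L] + clen
  reference <- transcript_record(
    "ref1", "gene1",
    exon_chain(seqid, starts, ends, "+"),
    exon_chain(seqid, cds_starts, cds_ends, "+"))

  iso_chains <- vector("list", n_isoforms)
  iso_events <- character(n_isoforms)
  iso_chains[[1L]] <- reference$exons
  iso_events[1L] <- "none"
  if (n_isoforms > 1L) for (i in 2:n_isoforms) {
    done <- FALSE
    for (try_ in 1:50) {
      ev <- sample(splice_events, 1L)
      ne <- .apply_event(ev, reference$exons$starts, reference$exons$ends,
                         glen)
      if (is.null(ne)) next
      if (sum(ne$ends - ne$starts) < 200L) next
      iso_chains[[i]] <- exon_chain(seqid, ne$starts, ne$ends, "+")
      iso_events[i] <- ev
      done <- TRUE
      break
    }
    if (!done) stop("could not generate a feasible isoform (event set: ",
                    paste(splice_events, collapse = ","), ")")
  }

  # half of all loci live on the minus strand
  if (sample(c(TRUE, FALSE), 1L)) {
    m <- mirror_annotation(genome,
                           c(list(reference),
                             lapply(seq_len(n_isoforms), function(i)
                               transcript_record(paste0("iso", i), "gene1",
                                                 iso_chains[[i]]))))
    genome <- m$genome
    reference <- m$records[[1L]]
    iso_chains <- lapply(m$records[-1L], function(r) r$exons)
    strand <- "-"
  } else strand <- "+"

  isoforms <- vector("list", n_isoforms)
  for (i in seq_len(n_isoforms)) {
    rec <- transcript_record(paste0("iso", i), "gene1", iso_chains[[i]],
                             attributes = list(splice_event = iso_events[i]))
    truth <- oracle_best_orf(rec, list(reference), genome, params)
    isoforms[[i]] <- transcript_record(rec$transcript_id, rec$gene_id,
                                       rec$exons,
                                       if (is.null(truth)) NULL
                                       else truth$cds,
                                       rec$attributes)
  }

  list(genome = genome, reference = reference, isoforms = isoforms,
       strand = strand, seqid = seqid)
}

#' Write a generated locus as FASTA + GTF fixture files
#'
#' Produces `<name>.fa` (genome), `<name>.ref.gtf` (the canonical
#' reference with CDS), `<name>.query.gtf` (isoforms stripped of CDS, as a
#' query set) and `<name>.truth.gtf` (isoforms with their ground-truth
#' CDS). Byte-identical for identical loci.
#'
#' @param locus result of [make_locus()].
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return invisibly, the four file paths.
#' @export
write_locus <- function(locus, dir, name = "locus") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, paste0(name, ".fa"))
  ref <- file.path(dir, paste0(name, ".ref.gtf"))
  qry <- file.path(dir, paste0(name, ".query.gtf"))
  tru <- file.path(dir, paste0(name, ".truth.gtf"))
  write_genome(locus$genome, fa)
  write_annotation(list(locus$reference), ref, "gtf")
  stripped <- lapply(locus$isoforms, function(r)
    transcript_record(r$transcript_id, r$gene_id, r$exons, NULL,
                      r$attributes))
  write_annotation(stripped, qry, "gtf")
  write_annotation(locus$isoforms, tru, "gtf")
  invisible(c(fa, ref, qry, tru))
}
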