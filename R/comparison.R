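#' Translate a coding sequence to protein
#'
#' Standard genetic code; a trailing stop codon is dropped; codons
#' containing ambiguous bases translate to `X`.
#'
#' @param cds_seq nucleotide string whose length is a multiple of 3.
#' @return amino-acid string.
#' @examples
#' translate_cds("ATGAAATAG")  # "MK"
#' @export
translate_cds <- function(cds_seq) {
  n <- nchar(cds_seq)
  if (n == 0L || n %% 3L != 0L)
    stop("coding sequence length must be a positive multiple of 3")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq),
                                           if.fuzzy.codon = "X"))
  if (endsWith(aa, "*")) aa <- substr(aa, 1L, nchar(aa) - 1L)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon in coding sequence")
  aa
}

#' Protein percent identity by pairwise alignment
#'
#' Aligns two amino-acid sequences with BLOSUM62 and affine gap penalties
#' (open 10, extend 1). `percent_identity` is the number of identical
#' aligned columns divided by the alignment length (gaps included). The
#' default is a global (Needleman-Wunsch) alignment, which makes identity
#' reflect how much of each protein is conserved — the quantity the
#' interval-based ILPI approximates; `type = "local"` gives a classic
#' Smith-Waterman alignment over the best-matching segment.
#'
#' @param a,b amino-acid strings over the 20-letter alphabet plus `X`.
#' @param type `"global"` or `"local"`.
#' @return list with `percent_identity`, `score`, `aligned_length`.
#' @export
protein_identity <- function(a, b, type = c("global", "local")) {
  type <- match.arg(type)
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  if (grepl("[^ACDEFGHIKLMNPQRSTVWYX]", a) ||
      grepl("[^ACDEFGHIKLMNPQRSTVWYX]", b))
    stop("protein sequences may only contain the 20 amino acids and X")
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1, type = type)
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  cols <- length(p)
  matches <- sum(p == s & p != "-")
  list(percent_identity = if (cols > 0L) matches / cols else 0,
       score = as.numeric(Biostrings::score(aln)),
       aligned_length = as.integer(cols))
}

#' Clean a reference annotation for guided ORF search
#'
#' Mirrors the preparation applied to reference databases before
#' evaluation: transcripts whose spliced CDS is not a valid ORF (missing
#' start or stop codon, internal in-frame stop, length not a multiple of
#' three, ambiguous bases) are removed, as are BOTH members of any pair of
#' genomically overlapping CDS chains labeled with different gene ids.
#' Records without any CDS cannot guide a search and are removed as well.
#'
#' @param records list of [transcript_record()].
#' @param genome a `genome_sequence`.
#' @param params [search_params()] supplying the codon sets.
#' @return list with `kept` (records) and `removed` (data.frame
#'   `transcript_id`, `reason`).
#' @export
clean_reference <- function(records, genome, params = search_params()) {
  reasons <- character(0); ids <- character(0)
  drop <- logical(length(records))
  for (i in seq_along(records)) {
    r <- records[[i]]
    why <- if (is.null(r$cds)) "no_cds"
           else valid_orf_reason(r$cds, genome, params)
    if (!is.na(why)) {
      drop[i] <- TRUE
      ids <- c(ids, r$transcript_id); reasons <- c(reasons, why)
    }
  }
  # cross-gene overlapping ORFs among the survivors
  surv <- which(!drop)
  if (length(surv) > 1L) {
    conflicted <- logical(length(records))
    for (ai in seq_along(surv)) {
      for (bi in seq_len(ai - 1L)) {
        i <- surv[ai]; j <- surv[bi]
        a <- records[[i]]; b <- records[[j]]
        if (!identical(a$gene_id, b$gene_id) &&
            identical(a$cds$seqid, b$cds$seqid) &&
            chain_overlaps(a$cds, b$cds)) {
          conflicted[i] <- TRUE; conflicted[j] <- TRUE
        }
      }
    }
    for (i in which(conflicted)) {
      drop[i] <- TRUE
      ids <- c(ids, records[[i]]$transcript_id)
      reasons <- c(reasons, "overlaps_other_gene")
    }
  }
  list(kept = records[!drop],
       removed = data.frame(transcript_id = ids, reason = reasons,
                            stringsAsFactors = FALSE))
}

.orf_categories <- c("same_as_reference", "differs_matches_canonical",
                     "differs_reference_matches_canonical",
                     "no_reference_orf_found_matches_canonical",
                     "no_reference_orf_found_differs", "other")

#' Classify re-annotated ORFs against the original and canonical annotation
#'
#' For each transcript, the genomic CDS chain assigned by the search is
#' compared (by exact chain equality) with the transcript's original CDS
#' and with the canonical ORF at its locus (matched by same-strand CDS-span
#' overlap), yielding one category per transcript in the style of a
#' database-comparison summary table.
#'
#' @param annotated list of [transcript_record()] produced by
#'   [annotate_orfs()].
#' @param original list of [transcript_record()] sharing transcript ids
#'   with `annotated` (the pre-existing annotation of the same
#'   transcripts).
#' @param canonical list of [transcript_record()] carrying the canonical
#'   ORF per locus.
#' @param genome optional `genome_sequence`; when supplied together with
#'   `align = TRUE`, protein percent identity against the canonical ORF is
#'   added.
#' @param align compute alignment-based identity (requires `genome`).
#' @return list with `comparisons` (one row per transcript: ids, category,
#'   `ilpi_vs_canonical`, `identity_vs_canonical`) and `summary` (category
#'   counts; counts sum to the number of transcripts).
#' @export
classify_orfs <- function(annotated, original, canonical, genome = NULL,
                          align = FALSE) {
  orig_by_id <- stats::setNames(original,
                                vapply(original, function(r) r$transcript_id,
                                       character(1)))
  rows <- vector("list", length(annotated))
  for (i in seq_along(annotated)) {
    a <- annotated[[i]]
    o <- orig_by_id[[a$transcript_id]]
    if (is.null(o))
      stop("transcript ", a$transcript_id, " missing from original annotation")
    # canonical at this locus: same-strand CDS-span overlap, largest overlap
    best_c <- NULL; best_ov <- 0L
    qs <- chain_span(a$exons)
    for (cn in canonical) {
      if (is.null(cn$cds)) next
      if (!identical(cn$cds$seqid, a$exons$seqid) ||
          !identical(cn$cds$strand, a$exons$strand)) next
      cs <- chain_span(cn$cds)
      ov <- min(qs[2], cs[2]) - max(qs[1], cs[1])
      if (ov > best_ov) { best_ov <- ov; best_c <- cn }
    }
    A <- a$cds; O <- o$cds
    C <- if (is.null(best_c)) NULL else best_c$cds
    cat_ <- if (!is.null(A) && !is.null(O)) {
      if (chain_equal(A, O)) "same_as_reference"
      else if (!is.null(C) && chain_equal(A, C)) "differs_matches_canonical"
      else if (!is.null(C) && chain_equal(O, C))
        "differs_reference_matches_canonical"
      else "other"
    } else if (!is.null(A)) {
      if (!is.null(C) && chain_equal(A, C))
        "no_reference_orf_found_matches_canonical"
      else "no_reference_orf_found_differs"
    } else "other"
    ilpi <- if (!is.null(A) && !is.null(C)) score_candidate(A, C)$ILPI
            else NA_real_
    ident <- NA_real_
    if (align && !is.null(genome) && !is.null(A) && !is.null(C)) {
      pa <- translate_cds(spliced_sequence(A, genome))
      pc <- translate_cds(spliced_sequence(C, genome))
      ident <- protein_identity(pa, pc)$percent_identity
    }
    rows[[i]] <- data.frame(
      query_id = a$transcript_id,
      category = cat_,
      canonical_id = if (is.null(best_c)) NA_character_
                     else best_c$transcript_id,
      ilpi_vs_canonical = ilpi,
      identity_vs_canonical = ident,
      stringsAsFactors = FALSE)
  }
  comparisons <- do.call(rbind, rows)
  if (is.null(comparisons))
    comparisons <- data.frame(query_id = character(0), category = character(0),
                              canonical_id = character(0),
                              ilpi_vs_canonical = numeric(0),
                              identity_vs_canonical = numeric(0))
  counts <- table(factor(comparisons$category, levels = .orf_categories))
  list(comparisons = comparisons,
       summary = data.frame(category = names(counts),
                            count = as.integer(counts),
                            stringsAsFactors = FALSE))
}
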