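#' Search parameters for reference-guided ORF assignment
#'
#' @param mode `"ilpi"` applies the selection cascade (max ILPI) then
#'   (max IL) then (max length); `"il"` applies (max IL) then (max ILPI)
#'   then (max length). Maximizing ILPI favours ORFs with as little novel
#'   sequence as possible; maximizing IL may pick longer ORFs with more
#'   novel sequence when that increases the number of in-frame matches.
#' @param start_codons character vector of permitted start codons
#'   (default `ATG`).
#' @param stop_codons character vector of stop codons
#'   (default `TAA`, `TAG`, `TGA`).
#' @param min_orf_length minimum ORF length in codons, counting the start
#'   codon but not the stop. Single-codon ORFs (a start immediately
#'   followed by a stop) are always rejected.
#' @return a `search_params` list.
#' @export
search_params <- function(mode = c("ilpi", "il"),
                          start_codons = "ATG",
                          stop_codons = c("TAA", "TAG", "TGA"),
                          min_orf_length = 1L) {
  mode <- match.arg(mode)
  start_codons <- toupper(start_codons)
  stop_codons <- toupper(stop_codons)
  stopifnot(length(start_codons) > 0L, length(stop_codons) > 0L,
            all(nchar(start_codons) == 3L), all(nchar(stop_codons) == 3L),
            length(intersect(start_codons, stop_codons)) == 0L,
            min_orf_length >= 1L)
  structure(list(mode = mode, start_codons = start_codons,
                 stop_codons = stop_codons,
                 min_orf_length = as.integer(min_orf_length)),
            class = "search_params")
}

# effective minimum number of non-stop codons in a reportable ORF
.min_codons <- function(params) max(2L, params$min_orf_length)

#' One candidate ORF on a query transcript
#'
#' @param cds genomic [exon_chain()] of the ORF, stop codon included.
#' @param tx_start,tx_end transcript-space offsets (0-based half-open) of
#'   the ORF within the query's spliced sequence.
#' @param best_reference_id id of the reference yielding `score`.
#' @param score list with `IL`, `ILPI`, `length`, `novel_bases`,
#'   `ref_length` (see [score_candidate()]).
#' @return an object of class `candidate_orf`.
#' @export
candidate_orf <- function(cds, tx_start, tx_end, best_reference_id, score) {
  stopifnot(inherits(cds, "exon_chain"),
            tx_end - tx_start == chain_length(cds))
  structure(list(cds = cds, tx_start = as.integer(tx_start),
                 tx_end = as.integer(tx_end),
                 best_reference_id = best_reference_id, score = score),
            class = "candidate_orf")
}

#' @export
print.candidate_orf <- function(x, ...) {
  cat(sprintf(
    "<candidate_orf tx [%d, %d) IL=%d ILPI=%.3f length=%d novel=%d ref=%s>\n",
    x$tx_start, x$tx_end, x$score$IL, x$score$ILPI, x$score$length,
    x$score$novel_bases, x$best_reference_id))
  invisible(x)
}

#' Validity check of a CDS chain as an open reading frame
#'
#' A valid ORF is an uninterrupted sequence of 3-base codons that begins
#' with a start codon, ends with a stop codon, and contains no other
#' in-frame stop codon. Codons containing `N` match neither codon set and
#' invalidate the ORF.
#'
#' @param chain CDS [exon_chain()] including the stop codon.
#' @param genome a `genome_sequence`.
#' @param params [search_params()].
#' @return `NA_character_` when valid, else one of `"not_multiple_of_3"`,
#'   `"too_short"`, `"no_start"`, `"no_stop"`, `"internal_stop"`,
#'   `"ambiguous_base"`.
#' @export
valid_orf_reason <- function(chain, genome, params = search_params()) {
  len <- chain_length(chain)
  if (len %% 3L != 0L) return("not_multiple_of_3")
  if (len < 3L * (.min_codons(params) + 1L)) return("too_short")
  s <- spliced_sequence(chain, genome)
  cod <- substring(s, seq(1L, len - 2L, by = 3L), seq(3L, len, by = 3L))
  n <- length(cod)
  if (!cod[1L] %in% params$start_codons) return("no_start")
  if (!cod[n] %in% params$stop_codons) return("no_stop")
  if (any(cod[-n] %in% params$stop_codons)) return("internal_stop")
  if (any(grepl("N", cod, fixed = TRUE))) return("ambiguous_base")
  NA_character_
}

#' Extend an anchored frame 3' to the first stop codon
#'
#' Scans the spliced query sequence from `frame_anchor` in steps of 3 and
#' returns the exclusive end offset of the first stop codon found; only one
#' valid stop can terminate any given frame. `NA` when the transcript ends
#' without an in-frame stop (the candidate is incomplete and discarded).
#'
#' @param query_tx_seq spliced transcript sequence.
#' @param frame_anchor 0-based transcript offset seeding the frame.
#' @param stop_codons stop codon set.
#' @return integer end offset (exclusive, includes the stop codon) or `NA`.
#' @examples
#' extend_to_stop("ATGAAATAG", 0)  # 9
#' extend_to_stop("ATGAAA", 0)     # NA: incomplete
#' @export
extend_to_stop <- function(query_tx_seq, frame_anchor,
                           stop_codons = c("TAA", "TAG", "TGA")) {
  L <- nchar(query_tx_seq)
  frame_anchor <- as.integer(frame_anchor)
  stopifnot(frame_anchor >= 0L, frame_anchor < L)
  if (frame_anchor > L - 3L) return(NA_integer_)
  offs <- seq.int(frame_anchor, L - 3L, by = 3L)
  cod <- substring(query_tx_seq, offs + 1L, offs + 3L)
  hit <- which(cod %in% stop_codons)
  if (!length(hit)) NA_integer_ else offs[hit[1L]] + 3L
}

#' Choose the optimal start codon for a stopped frame
#'
#' Among start-codon offsets `s` in the stop's frame, upstream of the stop
#' and with no intervening in-frame stop, returns the one maximizing the
#' number of reference-matching codons of `[s, stop_end)`; ties are broken
#' by minimizing bases that are novel or out-of-frame (mode `"ilpi"`:
#' the 3'-most tied start) or by maximizing ORF length (mode `"il"`:
#' the 5'-most tied start).
#'
#' @param query_tx_seq spliced transcript sequence.
#' @param stop_end exclusive end offset of the stop codon (see
#'   [extend_to_stop()]).
#' @param inframe logical vector over transcript offsets: `TRUE` where the
#'   offset belongs to a codon fully shared in frame with the reference.
#' @param params [search_params()].
#' @return 0-based start offset, or `NA` when no qualifying start exists.
#' @export
select_start <- function(query_tx_seq, stop_end, inframe,
                         params = search_params()) {
  L <- nchar(query_tx_seq)
  stop_end <- as.integer(stop_end)
  stopifnot(stop_end >= 6L, stop_end <= L, length(inframe) >= stop_end)
  cc <- stop_end %% 3L
  K <- (stop_end - cc) %/% 3L         # 1-based codon index of the stop
  off0 <- cc + 3L * (seq_len(K) - 1L)
  cod <- substring(query_tx_seq, off0 + 1L, off0 + 3L)
  if (!cod[K] %in% params$stop_codons)
    stop("stop_end does not terminate a stop codon")
  barrier <- cod %in% params$stop_codons | grepl("N", cod, fixed = TRUE)
  lo <- if (K > 1L) max(0L, which(barrier[seq_len(K - 1L)])) else 0L
  if (lo + 1L > K - 1L) return(NA_integer_)
  win <- (lo + 1L):(K - 1L)
  ks <- win[cod[win] %in% params$start_codons]
  ks <- ks[K - ks >= .min_codons(params)]
  if (!length(ks)) return(NA_integer_)
  matched <- inframe[off0 + 1L] & inframe[off0 + 2L] & inframe[off0 + 3L]
  cm <- c(0L, cumsum(matched))
  w <- cm[K] - cm[ks]
  tied <- ks[w == max(w)]
  k <- if (params$mode == "ilpi") max(tied) else min(tied)
  cc + 3L * (k - 1L)
}

#' Score a candidate ORF against a reference CDS by interval pseudo-alignment
#'
#' IL (in-frame length) is the number of coding bases belonging to codons
#' fully shared with the reference in the same reading frame (contiguous in
#' both chains' coding coordinates, hence coding identical residues); stop
#' codons of both chains are excluded. ILPI is IL divided by the reference
#' coding length (stop codon excluded).
#'
#' @param candidate a [candidate_orf()] or a CDS [exon_chain()] including
#'   the stop codon.
#' @param reference_cds reference CDS [exon_chain()] including the stop
#'   codon, on the same seqid and strand.
#' @return list with `IL`, `ILPI`, `length` (candidate coding bases, stop
#'   excluded), `novel_bases` (candidate coding bases outside the reference
#'   CDS), `ref_length`.
#' @export
score_candidate <- function(candidate, reference_cds) {
  cds <- if (inherits(candidate, "candidate_orf")) candidate$cds else candidate
  body <- chain_trim3p(cds, 3L)
  refb <- chain_trim3p(reference_cds, 3L)
  len <- chain_length(body)
  reflen <- chain_length(refb)
  iv <- chain_intersect(body, refb)
  IL <- 0L
  shared <- 0L
  if (nrow(iv) > 0L) {
    p5 <- unname(if (body$strand == "+") iv[, 1L] else iv[, 2L] - 1L)
    c_off <- chain_coding_offset(body, p5)
    r_off <- chain_coding_offset(refb, p5)
    lens <- unname(iv[, 2L] - iv[, 1L])
    shared <- sum(lens)
    o <- order(c_off)
    c_off <- c_off[o]; r_off <- r_off[o]; lens <- lens[o]
    # merge runs contiguous in BOTH coding coordinate systems: a codon that
    # spans an exon junction present in both chains still counts
    i <- 1L
    n <- length(lens)
    while (i <= n) {
      c0 <- c_off[i]; r0 <- r_off[i]; run <- lens[i]
      j <- i + 1L
      while (j <= n && c_off[j] == c0 + run && r_off[j] == r0 + run) {
        run <- run + lens[j]; j <- j + 1L
      }
      if (c0 %% 3L == r0 %% 3L) {
        ncod <- (c0 + run) %/% 3L - (c0 + 2L) %/% 3L
        if (ncod > 0L) IL <- IL + 3L * ncod
      }
      i <- j
    }
  }
  list(IL = as.integer(IL),
       ILPI = if (reflen > 0L) IL / reflen else 0,
       length = as.integer(len),
       novel_bases = as.integer(len - shared),
       ref_length = as.integer(reflen))
}

# cascade comparison of two scores; 1 if a better, -1 if b better, 0 tie.
# ILPI compared exactly by cross-multiplication.
.score_better <- function(a, b, mode) {
  cmp <- function(x, y) (x > y) - (x < y)
  ilpi <- cmp(a$IL * b$ref_length, b$IL * a$ref_length)
  ord <- if (mode == "ilpi")
    c(ilpi, cmp(a$IL, b$IL), cmp(a$length, b$length))
  else
    c(cmp(a$IL, b$IL), ilpi, cmp(a$length, b$length))
  nz <- ord[ord != 0L]
  if (length(nz)) nz[1L] else 0L
}

#' Enumerate candidate ORFs for one query against a set of references
#'
#' For every reference, every reading frame of the query's spliced sequence
#' and every in-frame stop codon, the optimal start is chosen with the
#' [select_start()] rule computed against that reference; candidates with
#' identical genomic CDS chains are deduplicated; each surviving candidate
#' is then scored against every reference and keeps the best score (the
#' reference attaining it is recorded). Candidates sharing no in-frame codon
#' with any reference are discarded: with no guide signal the method
#' deliberately reports no ORF.
#'
#' @param query a [transcript_record()].
#' @param references list of [transcript_record()] with CDS chains; those on
#'   a different seqid or strand are ignored.
#' @param genome a `genome_sequence`.
#' @param params [search_params()].
#' @return list of [candidate_orf()].
#' @export
enumerate_candidates <- function(query, references, genome,
                                 params = search_params()) {
  refs <- Filter(function(r) !is.null(r$cds) &&
                   identical(r$cds$seqid, query$exons$seqid) &&
                   identical(r$cds$strand, query$exons$strand), references)
  if (!length(refs)) return(list())
  if (!query$exons$seqid %in% names(unclass(genome)))
    stop("genome is missing sequence ", query$exons$seqid)
  seq <- spliced_sequence(query$exons, genome)
  L <- nchar(seq)
  minc <- .min_codons(params)
  if (L < 3L * (minc + 1L)) return(list())
  gpos <- tx_positions(query$exons)
  roffs <- lapply(refs, function(r) {
    rg <- tx_positions(r$cds)
    rg <- rg[seq_len(length(rg) - 3L)]   # coding positions, stop excluded
    match(gpos, rg) - 1L
  })

  seen <- character(0)
  info <- list()
  for (cc in 0:2) {
    M <- (L - cc) %/% 3L
    if (M < minc + 1L) next
    off0 <- cc + 3L * (seq_len(M) - 1L)
    cod <- substring(seq, off0 + 1L, off0 + 3L)
    is_start <- cod %in% params$start_codons
    is_stop <- cod %in% params$stop_codons
    if (!any(is_stop) || !any(is_start)) next
    barrier <- is_stop | grepl("N", cod, fixed = TRUE)
    lastb <- cummax(ifelse(barrier, seq_len(M), 0L))
    stops <- which(is_stop)
    for (ri in seq_along(refs)) {
      ro <- roffs[[ri]]
      # a query codon is shared in frame iff its three bases map to three
      # consecutive reference coding positions starting on a codon boundary
      o1 <- ro[off0 + 1L]; o2 <- ro[off0 + 2L]; o3 <- ro[off0 + 3L]
      matched <- !is.na(o1) & !is.na(o2) & !is.na(o3) &
        o2 == o1 + 1L & o3 == o2 + 1L & (o1 %% 3L) == 0L
      cm <- c(0L, cumsum(matched))
      for (K in stops) {
        lo <- if (K > 1L) lastb[K - 1L] else 0L
        if (lo + 1L > K - 1L) next
        win <- (lo + 1L):(K - 1L)
        ks <- win[is_start[win]]
        ks <- ks[K - ks >= minc]
        if (!length(ks)) next
        w <- cm[K] - cm[ks]
        tied <- ks[w == max(w)]
        k <- if (params$mode == "ilpi") max(tied) else min(tied)
        key <- paste(cc, k, K)
        if (!key %in% seen) {
          seen <- c(seen, key)
          info[[length(info) + 1L]] <- c(cc, k, K)
        }
      }
    }
  }

  out <- list()
  for (x in info) {
    cc <- x[1L]; k <- x[2L]; K <- x[3L]
    tx_start <- cc + 3L * (k - 1L)
    tx_end <- cc + 3L * K
    chain <- chain_from_tx_range(query$exons, tx_start, tx_end)
    best_s <- NULL; best_id <- NA_character_
    for (r in refs) {
      s <- score_candidate(chain, r$cds)
      if (is.null(best_s) || .score_better(s, best_s, params$mode) > 0L) {
        best_s <- s; best_id <- r$transcript_id
      }
    }
    if (best_s$IL == 0L) next
    out[[length(out) + 1L]] <-
      candidate_orf(chain, tx_start, tx_end, best_id, best_s)
  }
  out
}

#' Select the best candidate ORF by the successive score cascade
#'
#' Applies the mode's cascade over deduplicated candidates; surviving ties
#' go to the 5'-most transcript-space start.
#'
#' @param candidates list of [candidate_orf()].
#' @param params [search_params()].
#' @return the winning [candidate_orf()], or `NULL` when empty.
#' @export
select_best <- function(candidates, params = search_params()) {
  if (!length(candidates)) return(NULL)
  best <- candidates[[1L]]
  for (cand in candidates[-1L]) {
    d <- .score_better(cand$score, best$score, params$mode)
    if (d > 0L || (d == 0L && cand$tx_start < best$tx_start)) best <- cand
  }
  best
}

#' Assign ORFs to query transcripts guided by reference CDS annotations
#'
#' The top-level driver: validates reference ORFs, builds same-strand
#' bundles, searches candidates for every query in every bundle it joined,
#' and attaches the winning ORF (stop codon included) as the query's CDS.
#' Queries with no valid candidate are returned without a CDS; original
#' attributes are preserved. Bundles are independent, so the result does not
#' depend on bundle processing order or thread count.
#'
#' @param references list of [transcript_record()]; records without a CDS
#'   or failing the valid-ORF check are dropped with a warning.
#' @param queries list of [transcript_record()] with unique transcript ids.
#' @param genome a `genome_sequence`.
#' @param params [search_params()].
#' @param group_by_gene forward to [build_bundles()].
#' @param threads process bundles with this many workers
#'   (`parallel::mclapply`); output is identical at any thread count.
#' @return an object of class `orf_annotation`: list with `records` (the
#'   annotated queries, input order preserved) and `stats` (one row per
#'   query: selected scores and best reference).
#' @export
annotate_orfs <- function(references, queries, genome,
                          params = search_params(), group_by_gene = FALSE,
                          threads = 1L) {
  refs <- Filter(function(r) !is.null(r$cds), references)
  if (length(refs) < length(references))
    warning(length(references) - length(refs),
            " reference record(s) without CDS ignored")
  ok <- vapply(refs, function(r)
    is.na(valid_orf_reason(r$cds, genome, params)), logical(1))
  if (any(!ok))
    warning(sum(!ok), " reference record(s) with invalid ORFs dropped")
  refs <- refs[ok]

  qids <- vapply(queries, function(q) q$transcript_id, character(1))
  if (anyDuplicated(qids)) stop("duplicate query transcript ids")

  bb <- build_bundles(refs, queries, group_by_gene)
  worker <- function(b) {
    lapply(b$queries, function(q)
      list(id = q$transcript_id,
           cands = enumerate_candidates(q, b$references, genome, params)))
  }
  res <- if (threads > 1L)
    parallel::mclapply(bb$bundles, worker, mc.cores = threads)
  else lapply(bb$bundles, worker)

  cands_by_id <- list()
  for (bundle_res in res) for (qr in bundle_res)
    cands_by_id[[qr$id]] <- c(cands_by_id[[qr$id]], qr$cands)

  records <- vector("list", length(queries))
  stats <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[[i]]
    best <- select_best(cands_by_id[[q$transcript_id]], params)
    records[[i]] <- transcript_record(q$transcript_id, q$gene_id, q$exons,
                                      if (is.null(best)) NULL else best$cds,
                                      q$attributes)
    stats[[i]] <- data.frame(
      transcript_id = q$transcript_id, gene_id = q$gene_id,
      orf_found = !is.null(best),
      tx_start = if (is.null(best)) NA_integer_ else best$tx_start,
      tx_end = if (is.null(best)) NA_integer_ else best$tx_end,
      IL = if (is.null(best)) NA_integer_ else best$score$IL,
      ILPI = if (is.null(best)) NA_real_ else best$score$ILPI,
      orf_length = if (is.null(best)) NA_integer_ else best$score$length,
      novel_bases = if (is.null(best)) NA_integer_ else best$score$novel_bases,
      best_reference_id = if (is.null(best)) NA_character_
                          else best$best_reference_id,
      stringsAsFactors = FALSE)
  }
  structure(list(records = records, stats = do.call(rbind, stats)),
            class = "orf_annotation")
}

#' @export
print.orf_annotation <- function(x, ...) {
  n <- length(x$records)
  found <- sum(x$stats$orf_found)
  cat(sprintf("<orf_annotation %d quer%s, ORF assigned to %d (%.1f%%)>\n",
              n, if (n == 1) "y" else "ies", found,
              if (n) 100 * found / n else 0))
  invisible(x)
}
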