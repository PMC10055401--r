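#' Strand-aware chains of genomic intervals
#'
#' An `exon_chain` is an ordered set of non-overlapping, non-adjacent
#' intervals on one chromosome and one strand. It underlies both exon
#' structures and CDS chains. All coordinates are internal convention:
#' 0-based, half-open `[start, end)`. GTF/GFF3 1-based inclusive coordinates
#' are converted at the file boundary only.
#'
#' @param seqid chromosome name (length-1 character).
#' @param starts,ends integer vectors of interval starts (0-based) and ends
#'   (exclusive). Overlapping or book-ended intervals are merged.
#' @param strand `"+"` or `"-"`.
#' @return an object of class `exon_chain` with fields `seqid`, `strand`,
#'   `starts`, `ends`.
#' @examples
#' ch <- exon_chain("chr1", c(0, 6), c(3, 9), "+")
#' chain_length(ch)
#' @export
exon_chain <- function(seqid, starts, ends, strand) {
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  stopifnot(length(seqid) == 1L, length(strand) == 1L,
            strand %in% c("+", "-"),
            length(starts) == length(ends), length(starts) > 0L)
  if (any(is.na(starts)) || any(is.na(ends)) || any(starts >= ends))
    stop("exon_chain: every interval must satisfy start < end")
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  # merge overlapping and book-ended intervals
  if (length(starts) > 1L) {
    ms <- starts[1L]; me <- ends[1L]
    out_s <- integer(0); out_e <- integer(0)
    for (i in 2:length(starts)) {
      if (starts[i] <= me) {
        me <- max(me, ends[i])
      } else {
        out_s <- c(out_s, ms); out_e <- c(out_e, me)
        ms <- starts[i]; me <- ends[i]
      }
    }
    starts <- c(out_s, ms); ends <- c(out_e, me)
  }
  structure(list(seqid = as.character(seqid), strand = strand,
                 starts = starts, ends = ends),
            class = "exon_chain")
}

#' @export
print.exon_chain <- function(x, ...) {
  cat(sprintf("<exon_chain %s(%s) %d interval(s), %d bp>\n", x$seqid,
              x$strand, length(x$starts), chain_length(x)))
  cat(paste0("  [", x$starts, ", ", x$ends, ")", collapse = "\n"), "\n")
  invisible(x)
}

#' Total number of bases in a chain
#' @param chain an [exon_chain()].
#' @return integer base count.
#' @export
chain_length <- function(chain) sum(chain$ends - chain$starts)

#' Genomic span of a chain
#' @param chain an [exon_chain()].
#' @return integer vector `c(start, end)` (0-based half-open).
#' @export
chain_span <- function(chain) c(chain$starts[1L], chain$ends[length(chain$ends)])

#' Exact equality of two chains
#' @param a,b [exon_chain()] objects.
#' @return `TRUE` when seqid, strand and the full interval set agree.
#' @export
chain_equal <- function(a, b) {
  if (is.null(a) || is.null(b)) return(is.null(a) && is.null(b))
  identical(a$seqid, b$seqid) && identical(a$strand, b$strand) &&
    length(a$starts) == length(b$starts) &&
    all(a$starts == b$starts) && all(a$ends == b$ends)
}

#' Genomic intersection of two chains
#'
#' Computes the maximal genomic intervals present in both chains, the
#' primitive underlying interval pseudo-alignment of a query exon structure
#' against a reference CDS.
#'
#' @param a,b [exon_chain()] objects on the same seqid and strand.
#' @return a two-column integer matrix (`start`, `end`), zero rows when the
#'   chains are disjoint.
#' @examples
#' a <- exon_chain("c", c(0, 60), c(30, 90), "+")
#' b <- exon_chain("c", 20, 70, "+")
#' chain_intersect(a, b)  # [20,30) and [60,70)
#' @export
chain_intersect <- function(a, b) {
  stopifnot(identical(a$seqid, b$seqid), identical(a$strand, b$strand))
  out_s <- integer(0); out_e <- integer(0)
  i <- 1L; j <- 1L
  na <- length(a$starts); nb <- length(b$starts)
  while (i <= na && j <= nb) {
    s <- max(a$starts[i], b$starts[j])
    e <- min(a$ends[i], b$ends[j])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a$ends[i] < b$ends[j]) i <- i + 1L else j <- j + 1L
  }
  cbind(start = out_s, end = out_e)
}

#' Does any interval of chain `a` overlap chain `b`?
#' @param a,b [exon_chain()] objects on the same seqid (strand not checked).
#' @return `TRUE`/`FALSE`.
#' @export
chain_overlaps <- function(a, b) {
  if (!identical(a$seqid, b$seqid)) return(FALSE)
  i <- 1L; j <- 1L
  while (i <= length(a$starts) && j <= length(b$starts)) {
    if (max(a$starts[i], b$starts[j]) < min(a$ends[i], b$ends[j])) return(TRUE)
    if (a$ends[i] < b$ends[j]) i <- i + 1L else j <- j + 1L
  }
  FALSE
}

# coding offset (0-based, 5'->3' in transcript orientation) of genomic
# positions within a chain; NA outside. Vectorized over pos.
chain_coding_offset <- function(chain, pos) {
  lens <- chain$ends - chain$starts
  idx <- findInterval(pos, chain$starts)
  inside <- idx >= 1L & pos < chain$ends[pmax(idx, 1L)]
  off <- rep(NA_integer_, length(pos))
  if (any(inside)) {
    i <- idx[inside]
    if (chain$strand == "+") {
      before <- cumsum(c(0L, lens))[i]
      off[inside] <- before + (pos[inside] - chain$starts[i])
    } else {
      after <- rev(cumsum(c(0L, rev(lens))))[i + 1L]
      off[inside] <- after + (chain$ends[i] - 1L - pos[inside])
    }
  }
  off
}

#' Reading frame of a genomic position relative to a reference CDS chain
#'
#' For a position inside the CDS chain, returns the offset of that base
#' within the coding sequence (5' to 3' in transcript orientation) modulo 3;
#' `NA` outside the chain.
#'
#' @param reference_cds an [exon_chain()] of CDS intervals.
#' @param pos integer vector of 0-based genomic positions.
#' @return integer vector of 0/1/2 or `NA`.
#' @examples
#' cds <- exon_chain("c", c(10, 20), c(12, 27), "+")
#' frame_of(cds, c(10, 11, 20, 9))  # 0 1 2 NA  (exon1 has 2 coding bases)
#' @export
frame_of <- function(reference_cds, pos) {
  chain_coding_offset(reference_cds, pos) %% 3L
}

# genomic positions (0-based) of a chain in transcript order (5'->3')
tx_positions <- function(chain) {
  p <- sequence(chain$ends - chain$starts, from = chain$starts)
  if (chain$strand == "-") rev(p) else p
}

#' Genomic sub-chain covering a transcript-space range
#'
#' Maps the half-open transcript-space offset range `[a, b)` (0-based,
#' 5' to 3' in transcript orientation) back to genomic intervals of the
#' chain. This is how an ORF found on the spliced sequence becomes a
#' genomic CDS chain.
#'
#' @param chain an [exon_chain()].
#' @param a,b transcript-space offsets, `0 <= a < b <= chain_length(chain)`.
#' @return an [exon_chain()] of `b - a` bases.
#' @examples
#' ch <- exon_chain("c", c(0, 10), c(5, 20), "+")
#' chain_from_tx_range(ch, 3, 8)  # [3,5) plus [10,13)
#' @export
chain_from_tx_range <- function(chain, a, b) {
  p <- tx_positions(chain)
  stopifnot(a >= 0L, b <= length(p), a < b)
  p <- sort(p[(a + 1L):b])
  brk <- which(diff(p) != 1L)
  s <- p[c(1L, brk + 1L)]
  e <- p[c(brk, length(p))] + 1L
  exon_chain(chain$seqid, s, e, chain$strand)
}

# drop n bases from the 3' end of a chain (strand-aware)
chain_trim3p <- function(chain, n) {
  len <- chain_length(chain)
  stopifnot(n < len)
  if (n == 0L) return(chain)
  chain_from_tx_range(chain, 0L, len - as.integer(n))
}

#' Extract the spliced transcript sequence of a chain
#'
#' Concatenates the genome slices of the chain's intervals in 5' to 3'
#' transcript order; on the minus strand the reverse complement of the
#' right-to-left concatenation.
#'
#' @param chain an [exon_chain()].
#' @param genome a `genome_sequence` from [read_genome()].
#' @return a single uppercase nucleotide string.
#' @examples
#' g <- genome_sequence(c(c1 = "ATGCCCTAA"))
#' spliced_sequence(exon_chain("c1", c(0, 6), c(3, 9), "+"), g)  # "ATGTAA"
#' @export
spliced_sequence <- function(chain, genome) {
  seqs <- unclass(genome)
  if (!chain$seqid %in% names(seqs))
    stop("seqid not present in genome: ", chain$seqid)
  s <- seqs[[chain$seqid]]
  if (chain$ends[length(chain$ends)] > nchar(s) || chain$starts[1L] < 0L)
    stop("chain out of bounds for sequence ", chain$seqid)
  parts <- substring(s, chain$starts + 1L, chain$ends)
  out <- paste(parts, collapse = "")
  if (chain$strand == "-") out <- revcomp(out)
  out
}

#' Reverse complement of a nucleotide string
#' @param x a single A/C/G/T/N string.
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
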