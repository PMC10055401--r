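#' Transcript records
#'
#' A `transcript_record` holds one query or reference transcript: its exon
#' chain, an optional CDS chain (which, by internal convention, INCLUDES the
#' stop codon), identifiers and any extra attributes carried in the source
#' annotation.
#'
#' @param transcript_id,gene_id identifier strings.
#' @param exons an [exon_chain()] of exon intervals.
#' @param cds optional [exon_chain()] of coding intervals (stop codon
#'   included); must be contained in `exons` and share its strand.
#' @param attributes named list of extra attribute strings, preserved on
#'   output.
#' @return an object of class `transcript_record`.
#' @export
transcript_record <- function(transcript_id, gene_id, exons, cds = NULL,
                              attributes = list()) {
  stopifnot(inherits(exons, "exon_chain"))
  if (!is.null(cds)) {
    stopifnot(inherits(cds, "exon_chain"))
    if (!identical(cds$strand, exons$strand) ||
        !identical(cds$seqid, exons$seqid))
      stop("transcript ", transcript_id, ": CDS strand/seqid differs from exons")
    iv <- chain_intersect(exons, cds)
    if (sum(iv[, 2] - iv[, 1]) != chain_length(cds))
      stop("transcript ", transcript_id, ": CDS escapes its exons")
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene_id = as.character(gene_id),
                 exons = exons, cds = cds, attributes = attributes),
            class = "transcript_record")
}

#' @export
print.transcript_record <- function(x, ...) {
  cat(sprintf("<transcript_record %s (gene %s) %s(%s) %d exon(s)%s>\n",
              x$transcript_id, x$gene_id, x$exons$seqid, x$exons$strand,
              length(x$exons$starts),
              if (is.null(x$cds)) ", no CDS"
              else sprintf(", CDS %d bp", chain_length(x$cds))))
  invisible(x)
}

#' Genome sequences held in memory
#'
#' @param x a named character vector of nucleotide sequences (one per
#'   seqid); uppercased on construction.
#' @return an object of class `genome_sequence`.
#' @export
genome_sequence <- function(x) {
  stopifnot(is.character(x), !is.null(names(x)), !any(names(x) == ""))
  if (anyDuplicated(names(x))) stop("duplicate seqid in genome")
  structure(toupper(x), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence %d sequence(s): %s>\n", length(x),
              paste(sprintf("%s (%d bp)", names(x), nchar(unclass(x))),
                    collapse = ", ")))
  invisible(x)
}

#' Read a genome FASTA file
#'
#' The first whitespace-delimited token of each header is the seqid.
#' Sequences are uppercased; `N` is allowed.
#'
#' @param path FASTA file path.
#' @return a `genome_sequence`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate seqid in FASTA: ",
                               ids[duplicated(ids)][1L])
  x <- as.character(ss)
  names(x) <- ids
  genome_sequence(x)
}

#' Write a genome FASTA file
#' @param genome a `genome_sequence`.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_genome <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  seqs <- unclass(genome)
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(NULL)
}

.detect_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext == "gtf") return("gtf")
  # sniff: GFF3 attribute columns use key=value
  for (l in readLines(path, n = 50L)) {
    if (startsWith(l, "#") || !nzchar(l)) next
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) == 9L)
      return(if (grepl("=", f[9], fixed = TRUE)) "gff3" else "gtf")
  }
  stop("cannot detect annotation format of ", path)
}

.validate_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    l <- lines[i]
    if (!nzchar(l) || startsWith(l, "#")) next
    if (length(strsplit(l, "\t", fixed = TRUE)[[1]]) != 9L)
      stop("parse error at line ", i, " of ", path,
           ": expected 9 tab-separated columns")
  }
  invisible(NULL)
}

# standard GRanges metadata columns that are not user attributes
.std_cols <- c("source", "type", "score", "phase", "gene_id", "transcript_id",
               "ID", "Parent", "Name")

#' Read a GTF or GFF3 annotation into transcript records
#'
#' Exon and CDS features are grouped under their transcript; 1-based
#' inclusive file coordinates become internal 0-based half-open ones.
#' Separate `stop_codon` features (GTF dialect) are merged into the internal
#' CDS chain, so internal CDS chains always include the stop codon.
#' Transcripts carrying CDS but no exon features get exons synthesized from
#' the CDS chain. Records are sorted by (seqid, start of first exon).
#'
#' @param path annotation file.
#' @param format `"gtf"`, `"gff3"` or `"auto"` (detect from extension or
#'   attribute syntax).
#' @return list of [transcript_record()].
#' @export
read_annotation <- function(path, format = c("auto", "gtf", "gff3")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "auto") format <- .detect_format(path)
  .validate_lines(path)
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  starts <- GenomicRanges::start(gr) - 1L   # to 0-based half-open
  ends <- GenomicRanges::end(gr)

  if (format == "gtf") {
    tid <- if ("transcript_id" %in% names(mc)) as.character(mc$transcript_id)
           else rep(NA_character_, length(gr))
    gid <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
           else rep(NA_character_, length(gr))
  } else {
    parent <- if ("Parent" %in% names(mc))
      vapply(mc$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
             character(1))
    else rep(NA_character_, length(gr))
    id <- if ("ID" %in% names(mc)) as.character(mc$ID)
          else rep(NA_character_, length(gr))
    tid <- ifelse(type %in% c("mRNA", "transcript"), id, parent)
    gid <- rep(NA_character_, length(gr))
  }

  keep <- type %in% c("transcript", "mRNA", "exon", "CDS", "stop_codon")
  if (any(keep & type == "CDS" & (is.na(tid) | tid == "")))
    stop("CDS feature with no parent transcript in ", path)
  keep <- keep & !is.na(tid) & tid != ""

  idx_by_tx <- split(which(keep), tid[keep])
  records <- vector("list", length(idx_by_tx))
  names(records) <- names(idx_by_tx)
  for (t in names(idx_by_tx)) {
    ii <- idx_by_tx[[t]]
    str <- unique(strand[ii])
    if (length(str) != 1L)
      stop("transcript ", t, " has features on mixed strands")
    sq <- unique(seqid[ii])
    if (length(sq) != 1L)
      stop("transcript ", t, " has features on multiple sequences")
    tx_row <- ii[type[ii] %in% c("transcript", "mRNA")]
    ex <- ii[type[ii] == "exon"]
    cd <- ii[type[ii] %in% c("CDS", "stop_codon")]
    cds <- if (length(cd))
      exon_chain(sq, starts[cd], ends[cd], str) else NULL
    exons <- if (length(ex)) exon_chain(sq, starts[ex], ends[ex], str)
             else if (!is.null(cds)) cds
             else next
    # gene id: GTF attribute, or GFF3 Parent of the transcript feature
    g <- NA_character_
    if (format == "gtf") {
      g <- gid[ii][!is.na(gid[ii])][1]
    } else if (length(tx_row)) {
      pp <- mc$Parent[[tx_row[1]]]
      if (length(pp)) g <- pp[[1]]
      if (is.na(g) && "gene_id" %in% names(mc)) g <- mc$gene_id[tx_row[1]]
    }
    if (is.na(g)) g <- t
    attrs <- list()
    arow <- if (length(tx_row)) tx_row[1] else ii[1]
    for (cn in setdiff(names(mc), .std_cols)) {
      v <- mc[[cn]][arow]
      if (inherits(v, "List") || is.list(v)) v <- unlist(v)
      if (length(v) == 1L && !is.na(v)) attrs[[cn]] <- as.character(v)
    }
    records[[t]] <- transcript_record(t, g, exons, cds, attrs)
  }
  records <- Filter(Negate(is.null), records)
  sort_records(unname(records))
}

#' Sort transcript records by (seqid, start of first exon)
#' @param records list of [transcript_record()].
#' @return the sorted list.
#' @export
sort_records <- function(records) {
  if (!length(records)) return(records)
  sq <- vapply(records, function(r) r$exons$seqid, character(1))
  st <- vapply(records, function(r) r$exons$starts[1L], integer(1))
  id <- vapply(records, function(r) r$transcript_id, character(1))
  records[order(sq, st, id)]
}

# phases of CDS pieces given their lengths in transcript order:
# bases to skip to reach the next codon start
.piece_phases <- function(lens) {
  before <- cumsum(c(0L, lens))[seq_along(lens)]
  (3L - (before %% 3L)) %% 3L
}

.fmt_attr_gtf <- function(pairs) {
  paste0(vapply(names(pairs), function(k)
    sprintf('%s "%s";', k, pairs[[k]]), character(1)), collapse = " ")
}

.fmt_attr_gff3 <- function(pairs) {
  paste0(vapply(names(pairs), function(k)
    sprintf("%s=%s", k, pairs[[k]]), character(1)), collapse = ";")
}

#' Write transcript records as GTF or GFF3
#'
#' Internal 0-based half-open coordinates are converted back to 1-based
#' inclusive. CDS lines carry the frame/phase column (bases to skip to reach
#' the next codon start, accumulated 5' to 3' in transcript orientation).
#' On GTF output the final 3 coding bases are emitted as `stop_codon`
#' feature(s) and excluded from CDS lines (GENCODE dialect); on GFF3 output
#' the stop codon stays inside the CDS (NCBI dialect). Reading the written
#' file back reproduces the input coordinates exactly.
#'
#' @param records list of [transcript_record()].
#' @param path output file.
#' @param format `"gtf"` or `"gff3"`.
#' @export
write_annotation <- function(records, path, format = c("gtf", "gff3")) {
  format <- match.arg(format)
  records <- sort_records(records)
  out <- character(0)
  if (format == "gff3") out <- "##gff-version 3"
  src <- "orfscout"
  for (r in records) {
    ex <- r$exons
    span <- c(ex$starts[1L] + 1L, ex$ends[length(ex$ends)])
    tid <- r$transcript_id; gid <- r$gene_id
    base_attr <- if (format == "gtf")
      c(list(gene_id = gid, transcript_id = tid), r$attributes)
    else c(list(ID = tid, Parent = gid), r$attributes)
    fmt <- if (format == "gtf") .fmt_attr_gtf else .fmt_attr_gff3
    feat <- if (format == "gtf") "transcript" else "mRNA"
    out <- c(out, sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                          ex$seqid, src, feat, span[1], span[2], ex$strand,
                          fmt(base_attr)))
    ex_attr <- if (format == "gtf") base_attr
               else list(Parent = tid)
    for (i in seq_along(ex$starts))
      out <- c(out, sprintf("%s\t%s\texon\t%d\t%d\t.\t%s\t.\t%s",
                            ex$seqid, src, ex$starts[i] + 1L, ex$ends[i],
                            ex$strand, fmt(ex_attr)))
    if (!is.null(r$cds)) {
      cds <- r$cds
      if (chain_length(cds) < 6L)
        stop("transcript ", tid, ": CDS shorter than one codon plus stop")
      body <- chain_trim3p(cds, 3L)              # coding part, stop excluded
      stopc <- chain_from_tx_range(cds, chain_length(cds) - 3L,
                                   chain_length(cds))
      emit_pieces <- function(chain, feature, lens_for_phase) {
        ph <- .piece_phases(lens_for_phase)
        n <- length(chain$starts)
        # pieces in transcript order for phase; emit in genomic order
        ord <- if (chain$strand == "-") rev(seq_len(n)) else seq_len(n)
        lines <- character(n)
        for (k in seq_len(n)) {
          i <- ord[k]    # genomic index of k-th transcript-order piece
          lines[i] <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t%d\t%s",
                              chain$seqid, src, feature,
                              chain$starts[i] + 1L, chain$ends[i],
                              chain$strand, ph[k], fmt(ex_attr))
        }
        lines
      }
      if (format == "gtf") {
        body_lens <- body$ends - body$starts
        if (body$strand == "-") body_lens <- rev(body_lens)
        out <- c(out, emit_pieces(body, "CDS", body_lens))
        stop_lens <- stopc$ends - stopc$starts
        if (stopc$strand == "-") stop_lens <- rev(stop_lens)
        # phase of the stop codon continues the accumulation: always 0
        out <- c(out, emit_pieces(stopc, "stop_codon", stop_lens))
      } else {
        lens <- cds$ends - cds$starts
        if (cds$strand == "-") lens <- rev(lens)
        out <- c(out, emit_pieces(cds, "CDS", lens))
      }
    }
  }
  writeLines(out, path)
  invisible(NULL)
}
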