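#' Group overlapping reference CDS chains and queries into bundles
#'
#' A bundle is a connected group of reference CDS chains (by genomic CDS
#' span overlap on one seqid and strand) together with every query
#' transcript whose exon span overlaps the bundle's CDS span on the same
#' strand. Bundles are the independent units of ORF search: the result for
#' one bundle never depends on any other, which is what makes per-bundle
#' parallelism safe.
#'
#' Bundling is a single left-to-right sweep per (seqid, strand): a reference
#' joins the open bundle when its CDS span overlaps the bundle's growing CDS
#' span, otherwise a new bundle opens. With `group_by_gene = TRUE`,
#' references are first partitioned by `gene_id` so that bundles never mix
#' gene ids (overlapping but unrelated genes are then scored separately).
#'
#' @param references list of [transcript_record()], all with a CDS chain.
#' @param queries list of [transcript_record()].
#' @param group_by_gene partition references by `gene_id` before sweeping.
#' @return a list with elements `bundles` (each a list with `seqid`,
#'   `strand`, `references`, `queries`, `span`) and `unplaced` (queries
#'   overlapping no reference CDS span, passed through unmodified).
#' @export
build_bundles <- function(references, queries, group_by_gene = FALSE) {
  stopifnot(all(vapply(references, function(r) !is.null(r$cds), logical(1))))
  if (length(references) > 1L) {
    sq <- vapply(references, function(r) r$cds$seqid, character(1))
    st <- vapply(references, function(r) r$cds$starts[1L], integer(1))
    o <- order(sq, st)
    if (any(o != seq_along(sq))) {
      warning("references not sorted by (seqid, CDS start); re-sorting")
      references <- references[o]
    }
  }

  keyof <- function(r, use_gene) {
    paste(r$cds$seqid, r$cds$strand,
          if (use_gene) r$gene_id else "", sep = "\r")
  }
  groups <- split(references,
                  vapply(references, keyof, character(1),
                         use_gene = isTRUE(group_by_gene)))

  bundles <- list()
  for (grp in groups) {
    cur <- NULL; cur_end <- -1L
    for (r in grp) {
      sp <- chain_span(r$cds)
      if (is.null(cur) || sp[1] >= cur_end) {
        if (!is.null(cur)) bundles[[length(bundles) + 1L]] <- cur
        cur <- list(seqid = r$cds$seqid, strand = r$cds$strand,
                    references = list(r), queries = list(),
                    span = sp)
        cur_end <- sp[2]
      } else {
        cur$references[[length(cur$references) + 1L]] <- r
        cur_end <- max(cur_end, sp[2])
        cur$span[2] <- cur_end
      }
    }
    if (!is.null(cur)) bundles[[length(bundles) + 1L]] <- cur
  }

  placed <- logical(length(queries))
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qs <- chain_span(q$exons)
    for (bi in seq_along(bundles)) {
      b <- bundles[[bi]]
      if (identical(b$seqid, q$exons$seqid) &&
          identical(b$strand, q$exons$strand) &&
          qs[1] < b$span[2] && b$span[1] < qs[2]) {
        bundles[[bi]]$queries[[length(bundles[[bi]]$queries) + 1L]] <- q
        placed[qi] <- TRUE
      }
    }
  }
  list(bundles = bundles, unplaced = queries[!placed])
}
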