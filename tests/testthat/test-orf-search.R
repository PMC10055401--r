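test_that("extend_to_stop scans in codon steps and respects the frame", {
  expect_equal(extend_to_stop("ATGAAATAG", 0), 9L)
  expect_true(is.na(extend_to_stop("ATGAAA", 0)))       # incomplete
  # anchor 1: codons ATG, ATA, then only 2 bases remain -> no stop
  expect_true(is.na(extend_to_stop("AATGATAGA", 1)))
  # an immediate stop codon at the anchor terminates at once
  expect_equal(extend_to_stop("AATGATAGACC", 2), 5L)
})

test_that("select_start maximizes in-frame codons, ties broken by mode", {
  s <- "ATGATGAAATAA"
  all_in <- rep(TRUE, 12)
  expect_equal(select_start(s, 12, all_in), 0L)   # monotone coverage: 5'-most
  # first codon adds only novel sequence: ilpi mode takes the downstream ATG,
  # il mode keeps the longer ORF
  part <- c(rep(FALSE, 3), rep(TRUE, 9))
  expect_equal(select_start(s, 12, part, search_params(mode = "ilpi")), 3L)
  expect_equal(select_start(s, 12, part, search_params(mode = "il")), 0L)
  # no qualifying start at all
  expect_true(is.na(select_start("CCCCCCTAA", 9, rep(TRUE, 9))))
  expect_error(select_start(s, 9, all_in), "stop codon")
})

test_that("score_candidate computes IL/ILPI by shared in-frame codons", {
  ref <- exon_chain("c", 100, 154, "+")       # 17 codons + stop
  cand_same <- exon_chain("c", 100, 154, "+")
  sc <- score_candidate(cand_same, ref)
  expect_equal(sc$ILPI, 1.0)
  expect_equal(sc$IL, 51L)
  expect_equal(sc$novel_bases, 0L)

  # candidate covering codons 1-10 of the reference plus its own stop
  cand10 <- exon_chain("c", 100, 133, "+")
  sc10 <- score_candidate(cand10, ref)
  expect_equal(sc10$IL, 30L)
  expect_equal(sc10$ILPI, 30 / 51)
  expect_equal(sc10$length, 30L)

  # candidate sharing reference bases only out of frame
  shifted <- exon_chain("c", 101, 134, "+")
  expect_equal(score_candidate(shifted, ref)$IL, 0L)
  expect_equal(score_candidate(shifted, ref)$ILPI, 0)

  # a codon spanning an exon junction present in BOTH chains still counts
  ref2 <- exon_chain("c", c(100, 200), c(110, 244), "+")
  sc2 <- score_candidate(ref2, ref2)
  expect_equal(sc2$ILPI, 1.0)
})

test_that("selection cascade orders by mode, length is the third criterion", {
  mk <- function(len_incl_stop, IL, ref_length, tx_start = 0L) {
    chain <- exon_chain("c", 1000L, 1000L + len_incl_stop, "+")
    candidate_orf(chain, tx_start, tx_start + len_incl_stop, "r",
                  list(IL = IL, ILPI = IL / ref_length,
                       length = len_incl_stop - 3L, novel_bases = 0L,
                       ref_length = ref_length))
  }
  a <- mk(303L, 270L, 300L)          # ILPI 0.9, len 300
  b <- mk(453L, 270L, 300L)          # ILPI 0.9, len 450
  expect_equal(select_best(list(a, b))$score$length, 450L)
  expect_equal(select_best(list(b, a))$score$length, 450L)
  expect_identical(select_best(list(), search_params()), NULL)
  expect_equal(select_best(list(a))$score$length, 300L)
  # tie on the full triple: 5'-most transcript start wins
  a2 <- mk(303L, 270L, 300L, tx_start = 12L)
  expect_equal(select_best(list(a2, mk(303L, 270L, 300L, 30L)))$tx_start, 12L)
})

test_that("the two modes diverge exactly as designed on a split fixture", {
  fx <- mode_divergent_fixture()
  for (mode in c("ilpi", "il")) {
    p <- search_params(mode = mode)
    ann <- annotate_orfs(fx$refs, list(fx$query), fx$genome, p)
    got <- ann$records[[1]]$cds
    want <- if (mode == "ilpi") fx$o1_chain else fx$o2_chain
    expect_true(chain_equal(got, want), label = paste("mode", mode))
    o <- oracle_best_orf(fx$query, fx$refs, fx$genome, p)
    expect_true(chain_equal(o$cds, want))
  }
  # maximize_IL accepted more novel sequence for more matches
  il_s <- annotate_orfs(fx$refs, list(fx$query), fx$genome,
                        search_params(mode = "il"))$stats
  ilpi_s <- annotate_orfs(fx$refs, list(fx$query), fx$genome,
                          search_params(mode = "ilpi"))$stats
  expect_gt(il_s$IL, ilpi_s$IL)
  expect_gt(ilpi_s$ILPI, il_s$ILPI)
})

test_that("a query identical to its reference yields that reference's ORF", {
  fx <- mode_divergent_fixture()
  refA <- fx$refs[[1]]
  q <- transcript_record("q", "g", refA$exons)
  cands <- enumerate_candidates(q, list(refA), fx$genome)
  expect_length(cands, 1)
  expect_true(chain_equal(cands[[1]]$cds, refA$cds))
  expect_equal(cands[[1]]$score$ILPI, 1.0)
})

test_that("queries with no reference overlap produce no candidates", {
  fx <- mode_divergent_fixture()
  q <- transcript_record("q", "g", exon_chain("m", 560, 599, "+"))
  expect_length(enumerate_candidates(q, fx$refs, fx$genome), 0)
  ann <- annotate_orfs(fx$refs, list(q), fx$genome)
  expect_null(ann$records[[1]]$cds)
  expect_true(chain_equal(ann$records[[1]]$exons, q$exons))
})

test_that("a codon containing N interrupts and discards the ORF", {
  g <- rep("C", 300)
  g[101:112] <- strsplit("ATGAAACCCTAA", "")[[1]]
  g[201:230] <- strsplit("NGGTAACCCCCCCCCCCCCCCCCCCCCCCC", "")[[1]]
  genome <- tiny_genome(n1 = paste(g, collapse = ""))
  ref <- se_record("r", "g", "n1", 100, 112, 100, 112)
  expect_true(is.na(valid_orf_reason(ref$cds, genome)))
  q <- transcript_record("q", "g",
                         exon_chain("n1", c(100, 200), c(106, 230), "+"))
  expect_length(enumerate_candidates(q, list(ref), genome), 0)
  expect_null(oracle_best_orf(q, list(ref), genome))
})

test_that("identity recovery: containing the reference CDS gives ILPI 1", {
  set.seed(5)
  for (s in 301:310) {
    loc <- make_locus(seed = s, n_isoforms = 3, preserve_cds = TRUE)
    ann <- annotate_orfs(list(loc$reference), strip_cds(loc$isoforms),
                         loc$genome)
    expect_true(all(ann$stats$orf_found))
    expect_true(all(ann$stats$ILPI == 1.0))
    for (r in ann$records)
      expect_true(chain_equal(r$cds, loc$reference$cds))
  }
})

test_that("mode dominance: ILPI mode never loses ILPI, IL mode never loses IL", {
  for (s in 401:415) {
    loc <- make_locus(seed = s, n_isoforms = 3)
    queries <- strip_cds(loc$isoforms)
    a <- annotate_orfs(list(loc$reference), queries, loc$genome,
                       search_params(mode = "ilpi"))$stats
    b <- annotate_orfs(list(loc$reference), queries, loc$genome,
                       search_params(mode = "il"))$stats
    both <- a$orf_found & b$orf_found
    expect_equal(a$orf_found, b$orf_found)
    expect_true(all(a$ILPI[both] >= b$ILPI[both]))
    expect_true(all(b$IL[both] >= a$IL[both]))
  }
})

test_that("strand mirror symmetry: the mirrored locus selects the mirror ORF", {
  for (s in 501:510) {
    loc <- make_locus(seed = s, n_isoforms = 3)
    queries <- strip_cds(loc$isoforms)
    ann <- annotate_orfs(list(loc$reference), queries, loc$genome)
    m <- mirror_annotation(loc$genome, c(list(loc$reference), queries))
    ann_m <- annotate_orfs(list(m$records[[1]]), m$records[-1], m$genome)
    back <- mirror_annotation(m$genome, ann_m$records)$records
    for (i in seq_along(queries))
      expect_true(chain_equal(ann$records[[i]]$cds, back[[i]]$cds))
  }
})

test_that("every emitted CDS is itself a valid ORF", {
  for (s in 601:615) {
    loc <- make_locus(seed = s, n_isoforms = 4)
    ann <- annotate_orfs(list(loc$reference), strip_cds(loc$isoforms),
                         loc$genome)
    for (r in ann$records)
      if (!is.null(r$cds))
        expect_true(is.na(valid_orf_reason(r$cds, loc$genome)))
  }
})
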