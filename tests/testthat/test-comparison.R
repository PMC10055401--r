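test_that("translate_cds follows the standard code and conventions", {
  expect_equal(translate_cds("ATGTAA"), "M")
  expect_equal(translate_cds("ATGAAATAG"), "MK")
  expect_equal(translate_cds("ATGNNNTAA"), "MX")   # ambiguous codon -> X
  expect_equal(translate_cds("ATGAAA"), "MK")      # no trailing stop is fine
  expect_error(translate_cds("ATGTAATAA"), "internal stop")
  expect_error(translate_cds("ATGA"), "multiple of 3")
})

test_that("protein identity: exact, local core, and empty-input contract", {
  p <- protein_identity("MKVLLAGHQW", "MKVLLAGHQW")
  expect_equal(p$percent_identity, 1.0)
  expect_equal(p$aligned_length, 10L)
  # local alignment still finds an exact core inside unrelated sequence
  pl <- protein_identity("MKV", "WWDDEEPPRRGGHHKKLLMMMKVWW", type = "local")
  expect_equal(pl$percent_identity, 1.0)
  expect_equal(pl$aligned_length, 3L)
  # global identity reflects missing coverage
  pg <- protein_identity("MKVLL", "MKVLLAGHQW")
  expect_equal(pg$percent_identity, 0.5)
  expect_error(protein_identity("", "MK"), "empty")
  expect_error(protein_identity("MK*", "MK"), "amino acids")
})

test_that("local alignment scores match an independent Gotoh DP", {
  set.seed(17)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  for (i in 1:12) {
    a <- paste(sample(aas, sample(8:25, 1), replace = TRUE), collapse = "")
    b <- paste(sample(aas, sample(8:25, 1), replace = TRUE), collapse = "")
    got <- protein_identity(a, b, type = "local")$score
    expect_equal(got, sw_score_oracle(a, b))
  }
})

test_that("reference cleaning drops invalid ORFs and cross-gene overlaps", {
  g <- rep("C", 400)
  put <- function(g, at, s) { g[(at+1):(at+nchar(s))] <- strsplit(s, "")[[1]]; g }
  g <- put(g, 10, "ATGAAACCCTAA")     # valid ORF at [10, 22)
  g <- put(g, 100, "CCGAAACCCTAA")    # no start codon
  g <- put(g, 200, "ATGAAACCCTAA")    # valid, overlapping pair below
  genome <- tiny_genome(z = paste(g, collapse = ""))
  ok <- se_record("ok", "g1", "z", 0, 30, 10, 22)
  nostart <- se_record("nostart", "g2", "z", 95, 130, 100, 112)
  twin_a <- se_record("twinA", "gA", "z", 195, 230, 200, 212)
  twin_b <- se_record("twinB", "gB", "z", 195, 230, 200, 212)
  noncoding <- transcript_record("nc", "g3", exon_chain("z", 300, 360, "+"))

  res <- clean_reference(list(ok, nostart, twin_a, twin_b, noncoding), genome)
  kept_ids <- vapply(res$kept, function(r) r$transcript_id, character(1))
  expect_equal(kept_ids, "ok")
  expect_equal(res$removed$reason[res$removed$transcript_id == "nostart"],
               "no_start")
  expect_setequal(
    res$removed$reason[res$removed$transcript_id %in% c("twinA", "twinB")],
    c("overlaps_other_gene", "overlaps_other_gene"))
  expect_equal(res$removed$reason[res$removed$transcript_id == "nc"],
               "no_cds")

  # same-gene overlap is fine
  twin_b2 <- se_record("twinB", "gA", "z", 195, 230, 200, 212)
  res2 <- clean_reference(list(twin_a, twin_b2), genome)
  expect_length(res2$kept, 2)
})

test_that("classification covers the annotation-comparison categories", {
  g <- rep("C", 500)
  put <- function(g, at, s) { g[(at+1):(at+nchar(s))] <- strsplit(s, "")[[1]]; g }
  g <- put(g, 10, "ATGAAAAAACCCTAA")       # canonical ORF [10, 25)
  genome <- tiny_genome(w = paste(g, collapse = ""))
  canon <- se_record("canon1", "g1", "w", 0, 40, 10, 25)
  # annotated == original
  t_same <- se_record("t1", "g1", "w", 0, 40, 10, 25)
  res <- classify_orfs(list(t_same), list(t_same), list(canon))
  expect_equal(res$comparisons$category, "same_as_reference")

  # original had no ORF, annotated matches canonical
  t_orig <- transcript_record("t2", "g1", exon_chain("w", 0, 40, "+"))
  t_ann <- se_record("t2", "g1", "w", 0, 40, 10, 25)
  res2 <- classify_orfs(list(t_ann), list(t_orig), list(canon))
  expect_equal(res2$comparisons$category,
               "no_reference_orf_found_matches_canonical")
  expect_equal(res2$comparisons$ilpi_vs_canonical, 1.0)

  # all three differ pairwise -> other  (chains differ by start offsets)
  t_o3 <- se_record("t3", "g1", "w", 0, 40, 13, 25)
  t_a3 <- se_record("t3", "g1", "w", 0, 40, 16, 25)
  res3 <- classify_orfs(list(t_a3), list(t_o3), list(canon))
  expect_equal(res3$comparisons$category, "other")

  # annotated differs but original matches canonical
  res4 <- classify_orfs(list(t_a3), list(se_record("t3", "g1", "w",
                                                   0, 40, 10, 25)),
                        list(canon))
  expect_equal(res4$comparisons$category,
               "differs_reference_matches_canonical")

  # unknown transcript id -> error
  expect_error(classify_orfs(list(t_same), list(t_ann), list(canon)),
               "missing from original")
})

test_that("classify(x, x, x) is 100% same_as_reference and counts sum", {
  loci <- lapply(701:704, function(s)
    relabel_locus(make_locus(seed = s, n_isoforms = 2,
                             seqid = paste0("c", s)), paste0("L", s)))
  refs <- lapply(loci, function(l) l$reference)
  res <- classify_orfs(refs, refs, refs)
  expect_true(all(res$comparisons$category == "same_as_reference"))
  expect_equal(sum(res$summary$count), length(refs))
  expect_true(all(res$comparisons$ilpi_vs_canonical == 1.0))
})

test_that("ILPI and alignment identity are strongly rank-correlated", {
  # pairs span ILPI 0..1: every ORF sharing frame with the reference, plus
  # one zero-overlap control per transcript (random unrelated ORFs all tie
  # at ILPI 0 and would otherwise reduce the rank statistic to noise)
  set.seed(23)
  ilpi <- c(); ident <- c()
  for (s in 801:830) {
    loc <- make_locus(seed = s, n_isoforms = 2)
    ref <- loc$reference
    ref_prot <- translate_cds(spliced_sequence(ref$cds, loc$genome))
    for (iso in loc$isoforms) {
      q <- transcript_record(iso$transcript_id, iso$gene_id, iso$exons)
      zeros <- 0L
      for (ch in all_valid_orf_chains(q, loc$genome)) {
        sc <- score_candidate(ch, ref$cds)
        if (sc$ILPI == 0) { zeros <- zeros + 1L; if (zeros > 1L) next }
        prot <- translate_cds(spliced_sequence(ch, loc$genome))
        ilpi <- c(ilpi, sc$ILPI)
        ident <- c(ident, protein_identity(prot, ref_prot)$percent_identity)
      }
    }
  }
  expect_gte(length(ilpi), 200)
  expect_gte(stats::cor(ilpi, ident, method = "spearman"), 0.9)
})
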