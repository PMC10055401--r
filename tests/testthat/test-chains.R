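test_that("exon_chain validates, sorts and merges intervals", {
  ch <- exon_chain("c", c(60, 0, 30), c(90, 10, 60), "+")
  expect_equal(ch$starts, c(0L, 30L))   # [30,60) and [60,90) are book-ended
  expect_equal(ch$ends, c(10L, 90L))
  expect_equal(chain_length(ch), 70L)
  expect_equal(chain_span(ch), c(0L, 90L))
  expect_error(exon_chain("c", 10, 10, "+"), "start < end")
  expect_error(exon_chain("c", 0, 10, "*"))
})

test_that("chain_intersect returns maximal shared intervals", {
  q <- exon_chain("c", 0, 100, "+")
  r <- exon_chain("c", c(10, 40), c(20, 50), "+")
  iv <- chain_intersect(q, r)
  expect_equal(unname(iv[, 1]), c(10L, 40L))
  expect_equal(unname(iv[, 2]), c(20L, 50L))

  expect_equal(nrow(chain_intersect(exon_chain("c", 0, 10, "+"),
                                    exon_chain("c", 20, 30, "+"))), 0L)

  a <- exon_chain("c", c(0, 60), c(30, 90), "+")
  b <- exon_chain("c", 20, 70, "+")
  iv <- chain_intersect(a, b)
  expect_equal(unname(iv[, 1]), c(20L, 60L))
  expect_equal(unname(iv[, 2]), c(30L, 70L))
})

test_that("frame_of tracks coding frame across exon junctions", {
  # exon1 contributes 2 coding bases, so the 4th base (offset 3) is frame 0
  cds <- exon_chain("c", c(10, 20), c(12, 27), "+")
  expect_equal(frame_of(cds, 10), 0L)
  expect_equal(frame_of(cds, 11), 1L)
  expect_equal(frame_of(cds, 21), 0L)  # 4th coding base
  expect_true(is.na(frame_of(cds, 9)))
  expect_true(is.na(frame_of(cds, 15)))
  # minus strand: 5' end is the rightmost base
  mcds <- exon_chain("c", c(10, 20), c(12, 27), "-")
  expect_equal(frame_of(mcds, 26), 0L)
  expect_equal(frame_of(mcds, 20), 0L)  # offset 6 across the junction
  expect_equal(frame_of(mcds, 11), 1L)  # offset 7
  expect_equal(frame_of(mcds, 10), 2L)  # offset 8
})

test_that("spliced_sequence concatenates and reverse-complements", {
  g <- tiny_genome(c1 = "ATGCCCTAA")
  plus <- exon_chain("c1", c(0, 6), c(3, 9), "+")
  expect_equal(spliced_sequence(plus, g), "ATGTAA")
  minus <- exon_chain("c1", c(0, 6), c(3, 9), "-")
  expect_equal(spliced_sequence(minus, g), "TTACAT")
  whole <- exon_chain("c1", 0, 9, "+")
  expect_equal(spliced_sequence(whole, g), "ATGCCCTAA")
  expect_error(spliced_sequence(exon_chain("c1", 0, 20, "+"), g), "bounds")
  expect_error(spliced_sequence(exon_chain("nope", 0, 3, "+"), g), "seqid")
})

test_that("spliced sequence properties hold on random chains", {
  set.seed(11)
  g <- tiny_genome(z = paste(sample(c("A", "C", "G", "T", "N"), 500,
                                    replace = TRUE), collapse = ""))
  for (i in 1:25) {
    k <- sample(1:4, 1)
    s <- sort(sample(0:480, 2 * k))
    starts <- s[seq(1, 2 * k, 2)]; ends <- s[seq(2, 2 * k, 2)]
    ok <- starts < ends
    if (!any(ok)) next
    ch <- exon_chain("z", starts[ok], ends[ok], "+")
    seq_p <- spliced_sequence(ch, g)
    expect_equal(nchar(seq_p), chain_length(ch))
    chm <- exon_chain("z", ch$starts, ch$ends, "-")
    expect_equal(spliced_sequence(chm, g), revcomp(seq_p))
  }
})
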