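mk_paf <- function(qname, tname, tstart, tend, strand = "+") {
  squigglemap:::paf_record(qname, qlen = 500, qstart = 0, qend = 500,
                           strand = strand, tname = tname, tlen = 100000,
                           tstart = tstart, tend = tend, nmatch = 400,
                           blocklen = 500, mapq = 60,
                           decision = if (tname == "*")
                             "unmapped_max_chunks" else "mapped")
}

mk_set <- function(n, tname = "chr1") {
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_paf(sprintf("r%02d", i), tname, i * 1000L, i * 1000L + 500L)
  }))
}

test_that("precision, recall and F1 follow the confusion-set formulas", {
  truth <- mk_set(10)
  perfect <- compare_paf(truth, truth)
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))
  expect_identical(c(perfect$tp, perfect$fp, perfect$fn), c(10L, 0L, 0L))

  # 5 correct, 5 unmapped: P = 1, R = 0.5, F1 = 2/3
  half <- rbind(truth[1:5, ],
                do.call(rbind, lapply(6:10, function(i)
                  mk_paf(sprintf("r%02d", i), "*", 0, 0, "*"))))
  res <- compare_paf(half, truth)
  expect_equal(res$precision, 1)
  expect_equal(res$recall, 0.5)
  expect_equal(res$f1, 2 * (1 * 0.5) / 1.5)

  # 4 correct + 1 wrong contig: P = 0.8, R = 0.4, F1 = 0.5333
  four <- truth[1:5, ]
  four$tname[5] <- "chrX"
  res2 <- compare_paf(four, truth)
  expect_identical(c(res2$tp, res2$fp, res2$fn), c(4L, 1L, 6L))
  expect_equal(res2$precision, 0.8)
  expect_equal(res2$recall, 0.4)
  expect_equal(res2$f1, 2 * (0.8 * 0.4) / 1.2)

  # bookkeeping invariants
  expect_identical(res2$tp + res2$fp, 5L)   # mapped test reads
  expect_identical(res2$tp + res2$fn, 10L)  # truth-mapped reads
})

test_that("overlap tolerance and strand gate TP status", {
  truth <- mk_set(1)
  shifted <- truth
  shifted$tstart <- truth$tstart + 550L     # misses by 50 < tol
  shifted$tend <- truth$tend + 550L
  expect_identical(compare_paf(shifted, truth, tol = 100L)$tp, 1L)
  expect_identical(compare_paf(shifted, truth, tol = 10L)$tp, 0L)
  flipped <- truth
  flipped$strand <- "-"
  expect_identical(compare_paf(flipped, truth)$tp, 0L)

  dup <- rbind(truth, truth)
  dup$mapq[2] <- 10L
  expect_warning(res <- compare_paf(dup, truth), "duplicate")
  expect_identical(res$tp, 1L)
})

test_that("relative abundance fractions and distances are exact", {
  gm <- c(chr1 = "gA", chr2 = "gB", chr3 = "gC")
  t10 <- rbind(mk_set(6, "chr1"), mk_set(4, "chr2")[, ])
  t10$qname <- sprintf("r%02d", 1:10)
  truth_frac <- c(gA = 0.6, gB = 0.4)
  ab <- relative_abundance(t10, gm, truth_frac)
  expect_equal(unname(ab$fractions), c(0.6, 0.4))
  expect_equal(ab$euclidean_distance, 0)

  truth_frac2 <- c(gA = 0.5, gB = 0.5)
  ab2 <- relative_abundance(t10, gm, truth_frac2)
  expect_equal(ab2$euclidean_distance, sqrt(0.01 + 0.01))

  # a genome with zero mapped reads keeps fraction 0, vector sums to 1
  frac3 <- c(gA = 0.5, gB = 0.3, gC = 0.2)
  ab3 <- relative_abundance(t10, gm, frac3)
  expect_equal(unname(ab3$fractions["gC"]), 0)
  expect_equal(sum(ab3$fractions), 1)

  unmapped <- mk_paf("r1", "*", 0, 0, "*")
  expect_error(relative_abundance(unmapped, gm, truth_frac), "no mapped")
})
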