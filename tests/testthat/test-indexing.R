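test_that("posting counts follow the L - k + 1 - e + 1 per-strand formula", {
  m <- fixture_model()                      # k = 6
  sp <- seed_params(e = 3, bits_per_value = quant_params()$bits_per_value)
  set.seed(3)
  L <- 50
  ref <- c(ctg = paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                       collapse = ""))
  idx <- build_index(ref, m, sp = sp)
  per_strand <- L - m$k + 1 - sp$e + 1
  expect_identical(nrow(idx$table[strand == "+"]), as.integer(per_strand))
  expect_identical(nrow(idx$table[strand == "-"]), as.integer(per_strand))
  expect_true(all(idx$table$pos >= 0 & idx$table$pos <= L - m$k))
})

test_that("reference frequency filter removes over-represented hashes", {
  m <- fixture_model()
  polyA <- c(pa = strrep("A", 100))
  idx0 <- build_index(polyA, m)
  expect_gt(nrow(idx0$table), 0L)           # unfiltered: repeated hash kept
  expect_identical(length(unique(idx0$table$hash)), 2L)  # one per strand
  idx1 <- build_index(polyA, m, max_ref_occ = 1L)
  expect_identical(nrow(idx1$table), 0L)    # the poly-A hash is gone

  set.seed(4)
  ref <- c(ctg = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                       collapse = ""))
  for (cap in c(1L, 3L)) {
    idx <- build_index(ref, m, max_ref_occ = cap)
    expect_lte(max(idx$table[, .N, by = hash]$N), cap)
  }
  expect_error(build_index(character(0), m), "empty reference")
})

test_that("select_minimizers matches brute-force window minima", {
  seeds <- data.frame(pos = 0:4, hash = c(5, 3, 7, 2, 9))
  expect_identical(select_minimizers(seeds, 1L), seeds)
  got <- select_minimizers(seeds, 3L)
  expect_identical(got$pos, c(1L, 3L))      # windows: min 3, then 2, 2
  expect_identical(got$hash, c(3, 2))

  ties <- data.frame(pos = 0:4, hash = rep(1, 5))
  expect_identical(select_minimizers(ties, 3L)$pos, 0:2)  # leftmost per window

  # brute-force cross-check on random sequences
  set.seed(5)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    w <- sample(2:6, 1)
    s <- data.frame(pos = seq_len(n) - 1L, hash = sample(100, n, replace = TRUE))
    keep <- sort(unique(unlist(lapply(seq_len(max(n - w + 1, 1)), function(st) {
      win <- s[st:min(st + w - 1, n), ]
      st - 1L + which.min(win$hash)
    }))))
    expect_identical(select_minimizers(s, w)$pos, s$pos[keep])
  }
})

test_that("minimizer sketching keeps window coverage and ~2/(w+1) density", {
  set.seed(6)
  seeds <- data.frame(pos = 0:9999, hash = sample(2^30, 10000, replace = TRUE))
  for (w in c(3L, 5L, 9L)) {
    kept <- select_minimizers(seeds, w)
    expect_true(all(kept$pos %in% seeds$pos))          # subset property
    expect_lte(nrow(kept), nrow(seeds))
    expect_lte(max(diff(kept$pos)), w)                  # window coverage
    dens <- nrow(kept) / nrow(seeds)
    expect_lt(abs(dens - 2 / (w + 1)) / (2 / (w + 1)), 0.2)
  }
})

test_that("index save/load round-trips and rejects foreign files", {
  m <- tiny_model(2)
  set.seed(8)
  ref <- c(a = paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                     collapse = ""))
  idx <- build_index(ref, m)
  path <- tempfile(fileext = ".sqm")
  save_index(idx, path)
  back <- load_index(path)
  expect_equal(back$table, idx$table)
  expect_equal(back$params, idx$params)
  expect_equal(back$level_stats, idx$level_stats)

  trunc <- tempfile()
  bytes <- readBin(path, "raw", file.info(path)$size)
  writeBin(bytes[1:20], trunc)
  expect_error(load_index(trunc), "cannot read")
  other <- tempfile()
  saveRDS(list(a = 1), other)
  expect_error(load_index(other), "not a squigglemap index")
})
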