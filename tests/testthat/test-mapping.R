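test_that("query frequency filter removes over-abundant query hashes", {
  seeds <- data.frame(pos = 0:3, hash = c(7, 7, 7, 9))
  expect_identical(query_frequency_filter(seeds, 0L), seeds)     # off
  expect_identical(query_frequency_filter(seeds, 2L)$hash, 9)
  distinct <- data.frame(pos = 0:2, hash = c(1, 2, 3))
  expect_identical(query_frequency_filter(distinct, 1L), distinct)
})

test_that("weighted decision reproduces hand-computed w_sum", {
  dp <- decision_params()
  # saturated case: mapq 30, single chain -> r = (1,1,1), w_sum = 1
  ch <- mapping_quality(list(chain_stub(1000, n_anchors = 50)))
  ch[[1]]$mapq <- 30L
  dec <- weighted_decision(ch, dp)
  expect_equal(dec$w_sum, 1)
  expect_identical(dec$decision, "map")

  expect_identical(weighted_decision(list(), dp),
                   list(decision = "continue", w_sum = 0,
                        ratios = c(0, 0, 0)))

  # all weight on r1, mapq 15 -> w_sum = 0.5; tau picks the decision
  ch15 <- ch
  ch15[[1]]$mapq <- 15L
  d1 <- weighted_decision(ch15, decision_params(weights = c(1, 0, 0),
                                                tau = 0.6))
  expect_equal(d1$w_sum, 0.5)
  expect_identical(d1$decision, "continue")
  d2 <- weighted_decision(ch15, decision_params(weights = c(1, 0, 0),
                                                tau = 0.4))
  expect_identical(d2$decision, "map")
})

test_that("raising tau never flips continue into map", {
  set.seed(11)
  for (i in 1:10) {
    chains <- mapping_quality(list(chain_stub(runif(1, 30, 200),
                                              sample(4:20, 1)),
                                   chain_stub(runif(1, 10, 30))))
    taus <- seq(0, 1, by = 0.05)
    mapped <- vapply(taus, function(tau) {
      weighted_decision(chains, decision_params(tau = tau))$decision == "map"
    }, TRUE)
    expect_false(is.unsorted(rev(mapped)))   # TRUE block precedes FALSE block
  }
})

test_that("PAF writing and reading round-trip records and tags", {
  recs <- rbind(
    squigglemap:::paf_record("r1", 500, 10, 480, "+", "chr1", 60000, 100,
                             580, 300, 480, 60, chunks = 2, events = 400,
                             w_sum = 0.91, decision = "mapped"),
    squigglemap:::paf_record("r2", 300, 0, 0, "*", "*", 0, 0, 0, 0, 0, 0,
                             chunks = 30, events = 250, w_sum = 0.1),
    squigglemap:::paf_record("r3", 700, 5, 650, "-", "chr2", 40000, 2000,
                             2700, 500, 700, 40, chunks = 1, events = 600,
                             w_sum = 0.77, decision = "mapped"))
  path <- tempfile(fileext = ".paf")
  write_paf(recs, path)
  back <- read_paf(path)
  mand <- c("qname", "qlen", "qstart", "qend", "strand", "tname", "tlen",
            "tstart", "tend", "nmatch", "blocklen", "mapq")
  expect_identical(back[mand], recs[mand])
  expect_identical(back$chunks, recs$chunks)       # ch:i tag
  expect_identical(back$decision, recs$decision)   # dc:Z tag
  expect_equal(back$w_sum, recs$w_sum, tolerance = 1e-5)
  expect_identical(back$tname[2], "*")             # unmapped serialization
  expect_identical(back$mapq[2], 0L)

  writeLines(c(readLines(path), "bad\tline"), path)
  expect_warning(back2 <- read_paf(path), "malformed")
  expect_identical(nrow(back2), 3L)
})

test_that("reads map back to their simulated origin; foreign reads do not", {
  model <- fixture_model()
  ref <- random_genome(c(ctgA = 20000L, ctgB = 15000L), seed = 21)
  idx <- build_index(ref, model)
  sim <- simulate_reads(ref, model, sim_params(n_reads = 12, rng_seed = 31))
  recs <- map_reads(sim$reads, idx)
  expect_identical(nrow(recs), 12L)
  mapped <- recs$decision == "mapped"
  expect_gt(mean(mapped), 0.6)
  for (i in which(mapped)) {
    tr <- sim$truth[i, ]
    expect_identical(recs$tname[i], tr$tname)
    expect_identical(recs$strand[i], tr$strand)
    overlap <- min(recs$tend[i], tr$tend) - max(recs$tstart[i], tr$tstart)
    expect_gt(overlap, 0)
  }
  # chunks tag accounting: reported signal cost is chunks * chunk_samples
  ckp <- chunk_params()
  expect_equal(bases_before_decision(recs, ckp),
               recs$chunks * ckp$chunk_samples / ckp$samples_per_base)

  foreign <- random_genome(c(fg = 20000L), seed = 77)
  neg <- simulate_reads(foreign, model, sim_params(n_reads = 6,
                                                   rng_seed = 32))
  nrec <- map_reads(neg$reads, idx)
  expect_true(all(nrec$decision[nrec$tname == "*"] == "unmapped_max_chunks"))
  expect_lte(sum(nrec$decision == "mapped"), 1L)
})
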