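test_that("simulation is byte-identical under a fixed seed", {
  model <- fixture_model()
  ref <- random_genome(c(c1 = 5000L), seed = 41)
  sp <- sim_params(n_reads = 5, read_len_mean = 400, rng_seed = 17)
  d <- tempfile()
  dir.create(d)
  f1 <- file.path(d, "a.slow5"); t1 <- file.path(d, "a.paf")
  f2 <- file.path(d, "b.slow5"); t2 <- file.path(d, "b.paf")
  simulate_reads(ref, model, sp, out_slow5 = f1, out_truth = t1)
  simulate_reads(ref, model, sp, out_slow5 = f2, out_truth = t2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(t1), readLines(t2))
})

test_that("a noiseless read reproduces the model level sequence", {
  model <- fixture_model()
  ref <- random_genome(c(c1 = 3000L), seed = 42)
  sp <- sim_params(n_reads = 3, read_len_mean = 300, read_len_min = 250,
                   dwell_dispersion = 0, noise_sd_scale = 0,
                   per_read_shift_sd = 0, per_read_scale_sd = 0,
                   rng_seed = 19)
  sim <- simulate_reads(ref, model, sp)
  for (i in seq_along(sim$reads)) {
    rd <- sim$reads[[i]]
    tr <- sim$truth[i, ]
    ev <- detect_events(rd$samples, seg_params())
    seq <- substr(ref[[tr$tname]], tr$tstart + 1, tr$tend)
    if (tr$strand == "-") seq <- squigglemap:::revcomp(seq)
    want <- sequence_to_levels(seq, model)[[1]]$levels
    # the writer snaps samples onto the SLOW5 integer grid; adjacent
    # k-mers that collide on that grid merge into one detected event
    # adjacent k-mers that collide on the grid merge into one level run,
    # and the detector may split a long constant run into equal-level
    # events, so compare the run-length-collapsed level sequences
    grid <- squigglemap:::digitise_samples(want, 8192, 0, 1443)
    got_runs <- rle(ev$level)$values
    want_runs <- rle(grid)$values
    expect_identical(length(got_runs), length(want_runs))
    expect_equal(got_runs, want_runs, tolerance = 1e-9)
    expect_equal(normalize_levels(got_runs), normalize_levels(want_runs),
                 tolerance = 1e-6)
  }
})

test_that("dwell and length accounting match the sampling model", {
  model <- fixture_model()
  ref <- random_genome(c(c1 = 15000L), seed = 43)
  sp <- sim_params(n_reads = 1, read_len_mean = 12000, read_len_min = 11000,
                   rng_seed = 23)
  sim <- simulate_reads(ref, model, sp)
  n_steps <- sim$truth$qlen[1] - model$k + 1
  mean_dwell <- length(sim$reads[[1]]$samples) / n_steps
  expect_lt(abs(mean_dwell - 4000 / 450) / (4000 / 450), 0.05)
})

test_that("truth records stay in bounds with balanced strands", {
  model <- fixture_model()
  ref <- random_genome(c(c1 = 8000L, c2 = 4000L), seed = 44)
  sim <- simulate_reads(ref, model, sim_params(n_reads = 60,
                                               read_len_mean = 400,
                                               rng_seed = 29))
  tr <- sim$truth
  expect_true(all(tr$tstart >= 0))
  expect_true(all(tr$tend <= nchar(ref)[match(tr$tname, names(ref))]))
  expect_true(all(tr$tend - tr$tstart == tr$qlen))
  # fair-coin strand: 60 draws stay within a generous binomial band
  expect_gt(mean(tr$strand == "+"), 0.25)
  expect_lt(mean(tr$strand == "+"), 0.75)
})
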