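test_that("Hoechst normalization maps the k-th order statistics to exactly 1 and 2", {
  set.seed(1)
  for (rep in 1:100) {
    x <- stats::runif(400, 100, 10000)
    out <- normalize_hoechst(x, k = 10)
    s <- sort(x)  # brute-force order-statistic oracle
    expect_equal(out[which(x == s[10])[1]], 1)
    expect_equal(out[which(x == s[391])[1]], 2)
  }
})

test_that("Hoechst normalization is affine with the documented anchors, unclipped", {
  # L = 500 -> 1, H = 1000 -> 2, midpoint 750 -> 1.5
  x <- c(rep(500, 10), rep(1000, 10), 750, 400, stats::runif(380, 500, 1000))
  out <- normalize_hoechst(x, k = 10)
  expect_equal(out[1:10], rep(1, 10))
  expect_equal(out[11:20], rep(2, 10))
  expect_equal(out[21], 1.5)
  expect_equal(out[22], 0.8)  # below L maps below 1, no clipping

  # scale invariance and strict monotonicity
  expect_equal(normalize_hoechst(3.7 * x, k = 10), out)
  set.seed(2)
  y <- sort(stats::runif(100, 1, 100))
  expect_true(all(diff(normalize_hoechst(y, k = 10)) > 0))

  expect_error(normalize_hoechst(stats::runif(15), k = 10), "2k")
  expect_error(normalize_hoechst(rep(5, 50), k = 10), "degenerate")
})

test_that("log2 channel normalization matches direct arithmetic and clamps zeros", {
  expect_equal(normalize_channel_log2(rep(3, 20)), rep(0, 20))
  x <- c(1, 2, 4, 8)
  expect_equal(normalize_channel_log2(x), log2(x / 3.75))
  expect_equal(normalize_channel_log2(x / 3.75)[3], log2(4 / 3.75), tolerance = 1e-12)

  withzero <- normalize_channel_log2(c(0, 1, 2, 5))
  expect_equal(withzero[1], -10)

  expect_error(normalize_channel_log2(rep(0, 5)), "zero")
})

test_that("linearized channel normalization has mean 1; log2 mean is <= 0 (Jensen)", {
  set.seed(3)
  for (rep in 1:100) {
    x <- stats::rlnorm(200, 5, 1)
    out <- normalize_channel_log2(x)
    expect_equal(mean(2^out), 1, tolerance = 1e-9)
    expect_lte(mean(out), 0)
  }
  expect_equal(mean(normalize_channel_log2(rep(4, 10))), 0)
})

test_that("reference normalization shifts by the log2 of the scale ratio", {
  set.seed(4)
  ref <- stats::rlnorm(300, 6, 0.5)
  same <- normalize_to_reference(ref, ref)
  expect_equal(mean(2^same), 1, tolerance = 1e-9)
  doubled <- normalize_to_reference(2 * ref, ref)
  expect_equal(doubled, normalize_channel_log2(ref) + 1, tolerance = 1e-12)
  expect_error(normalize_to_reference(ref, rep(0, 10)), "reference")
})

test_that("set8 knockdown H4K20me1 sits below -3 against the control scale", {
  chans <- c("hoechst", "edu", "mcm2", "h4k20me1")
  cfg <- analysis_config(mcm_channel = "mcm2")
  ctrl <- run_simulated_experiment(population_params(n_cells = 400, seed = 121),
                                   render_params(seed = 122), cfg,
                                   channels = chans)
  set8 <- run_simulated_experiment(
    population_params(n_cells = 400, seed = 123, scenario = "set8_sirna"),
    render_params(seed = 124), cfg, channels = chans,
    reference = ctrl$analysis)
  expect_gte(mean(set8$analysis$records$h4k20me1 < -3), 0.95)
})

test_that("subsampling is seeded, order-preserving, and fraction-faithful", {
  res <- small_experiment(n = 500, seed = 130)
  rec <- res$analysis$records
  expect_equal(subsample_cells(rec, nrow(rec), seed = 1), rec)
  s1 <- subsample_cells(rec, 400, seed = 5)
  expect_identical(s1, subsample_cells(rec, 400, seed = 5))
  expect_false(identical(s1$cell_id, subsample_cells(rec, 400, seed = 6)$cell_id))
  expect_false(is.unsorted(s1$cell_id))
  expect_error(subsample_cells(rec, nrow(rec) + 1), "available")

  # binomial oracle: sampled phase fractions track the population over draws
  p_g1 <- mean(rec$phase == "G1")
  se <- sqrt(p_g1 * (1 - p_g1) / 400)
  devs <- vapply(1:100, function(s) {
    mean(subsample_cells(rec, 400, seed = s)$phase == "G1") - p_g1
  }, 0)
  expect_true(all(abs(devs) < 3.5 * se))
  expect_lt(abs(mean(devs)), se / 2)
})

test_that("normalization runs on all non-M nuclei before subsampling", {
  res <- small_experiment(n = 500, seed = 140)
  rec <- res$analysis$records
  smp_a <- subsample_cells(rec, 400, seed = 1)
  smp_b <- subsample_cells(rec, 400, seed = 2)
  shared <- intersect(smp_a$cell_id, smp_b$cell_id)
  expect_gt(length(shared), 0)
  # identical normalized values for shared cells: the sampling seed cannot
  # touch normalization
  expect_equal(smp_a[match(shared, smp_a$cell_id), ],
               smp_b[match(shared, smp_b$cell_id), ])
  # and the configured pipeline sample is a subset of the full records
  expect_true(all(res$analysis$sample$cell_id %in% rec$cell_id))
})
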