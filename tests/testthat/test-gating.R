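cfg <- gating_config()

test_that("phase gates reproduce the printed truth table", {
  rec <- tibble::tibble(
    hoechst_norm = c(1.00, 1.50, 1.80, 1.40),
    edu = c(-4, -1, -4, -4))
  out <- classify_phase(rec, cfg)
  expect_equal(as.character(out$phase), c("G1", "S", "G2", "unclassified"))
  expect_error(classify_phase(tibble::tibble(hoechst_norm = 1), cfg), "edu")
})

test_that("values exactly on a threshold satisfy neither side", {
  rec <- tibble::tibble(
    hoechst_norm = c(1.125, 1.7, 1.0),
    edu = c(-4, -4, -3))
  out <- classify_phase(rec, cfg)
  expect_equal(as.character(out$phase), rep("unclassified", 3))

  g1 <- classify_phase(tibble::tibble(hoechst_norm = c(1, 1, 1),
                                      edu = c(-4, -4, -4),
                                      mcm3 = c(0.7, 0.5, 0.3)), cfg)
  g1 <- split_g1_mcm(g1, "mcm3", cfg)
  expect_equal(as.character(g1$mcm_state), c("high", "low", "low"))
})

test_that("the G1 MCM split applies to G1 only and respects cell-line thresholds", {
  rec <- tibble::tibble(hoechst_norm = c(1.0, 1.5), edu = c(-4, -1),
                        mcm3 = c(0.7, 5))
  out <- split_g1_mcm(classify_phase(rec, cfg), "mcm3", cfg)
  expect_equal(as.character(out$mcm_state), c("high", "n/a"))

  hela <- gating_config(cell_line = "HeLa")
  out2 <- split_g1_mcm(classify_phase(rec, hela), "mcm3", hela)
  expect_equal(as.character(out2$mcm_state[1]), "high")  # 0.7 > 0.3
  expect_equal(mcm_thresholds[["IMR90"]], 1.5)
  expect_error(gating_config(cell_line = "CHO"), "CHO")
})

test_that("named gates match clause-by-clause brute force on 10^4 random records", {
  rec <- random_records(10000, seed = 11)
  expect_equal(apply_gate(rec, "cdt1_high", cfg),
               rec$cdt1 > 1.5 & rec$hoechst_norm < 1.125)
  expect_equal(apply_gate(rec, "edu_positive", cfg), rec$edu > -3)
  expect_equal(apply_gate(rec, "h4k20me1_high", cfg),
               rec$hoechst_norm < 1.125 & rec$h4k20me1 > 0.3)
  expect_equal(apply_gate(rec, "h4k20me2_low", cfg),
               rec$hoechst_norm < 1.125 & rec$h4k20me2 < -0.1)
  expect_equal(apply_gate(rec, "mcm2_high_g1", cfg),
               rec$mcm2 > 0.5 & rec$hoechst_norm < 1.125 & rec$edu < -3)

  one <- tibble::tibble(hoechst_norm = c(1.05, 1.30), cdt1 = c(1.6, 1.6))
  expect_equal(apply_gate(one, "cdt1_high", cfg), c(TRUE, FALSE))
  expect_error(apply_gate(one, "nonexistent", cfg), "available")
  expect_error(apply_gate(one, "mcm2_high_g1", cfg), "mcm2")
})

test_that("phase gates partition: every record gets exactly one label", {
  rec <- random_records(10000, seed = 12)
  out <- classify_phase(rec, cfg)
  expect_false(any(is.na(out$phase)))
  # no record can satisfy two printed gates: S requires EdU+, G1/G2 EdU-,
  # and the G1/G2 Hoechst bands are disjoint; checked on a threshold grid
  grid <- expand.grid(hoechst_norm = c(1.124, 1.125, 1.126, 1.699, 1.7, 1.701),
                      edu = c(-3.001, -3, -2.999))
  g <- classify_phase(tibble::as_tibble(grid), cfg)
  in_s <- g$edu > -3
  in_g1 <- g$edu < -3 & g$hoechst_norm < 1.125
  in_g2 <- g$edu < -3 & g$hoechst_norm > 1.7
  expect_true(all(in_s + in_g1 + in_g2 <= 1))
  expect_equal(as.character(g$phase),
               ifelse(in_s, "S", ifelse(in_g1, "G1",
                      ifelse(in_g2, "G2", "unclassified"))))
})

test_that("gate-recovered phases agree with ground truth away from the boundaries", {
  res <- small_experiment(n = 2000, seed = 150)
  m <- match_truth(res$analysis$measurements[!res$analysis$measurements$m_phase_flag, ],
                   res$stack$truth)
  rec <- res$analysis$records
  stopifnot(all(rec$cell_id == m$nucleus_id))
  truth_phase <- as.character(m$truth_phase)
  truth_phase[truth_phase %in% c("G1_low", "G1_high")] <- "G1"
  nonboundary <- abs(rec$hoechst_norm - 1.125) > 0.05 &
    abs(rec$hoechst_norm - 1.7) > 0.05 &
    abs(rec$edu - (-3)) > 0.05
  agree <- as.character(rec$phase) == truth_phase
  expect_gte(mean(agree[nonboundary]), 0.95)
})

test_that("high-H4K20me1 and high-Mcm2 G1 cells are mutually exclusive", {
  chans <- c("hoechst", "edu", "mcm2", "h4k20me1")
  res <- run_simulated_experiment(
    population_params(n_cells = 2000, seed = 160),
    render_params(seed = 161),
    analysis_config(mcm_channel = "mcm2"), channels = chans)
  rec <- res$analysis$records
  me1_high <- apply_gate(rec, "h4k20me1_high", cfg)
  mcm_high <- apply_gate(rec, "mcm2_high_g1", cfg)
  g1 <- rec$phase == "G1"
  expect_lt(sum(me1_high & mcm_high) / sum(g1), 0.02)
})

test_that("chase-time DNA-content bands split G1 / mid / G2", {
  rec <- tibble::tibble(hoechst_norm = c(1.0, 1.4, 1.9), edu = c(2, 2, 2))
  out <- classify_phase_hoechst(rec, cfg)
  expect_equal(as.character(out$phase), c("G1", "S", "G2"))
})
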