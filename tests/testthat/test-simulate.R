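test_that("degenerate occupancy: all-S populations sit strictly inside 1-2x DNA", {
  p <- quiet_params(total_cycle_h = 20,
                    phase_durations_h = c(G1_low = 0, G1_high = 0, S = 20,
                                          G2 = 0, M = 0),
                    n_cells = 500, seed = 3)
  pop <- simulate_population(p)
  expect_true(all(pop$phase == "S"))
  expect_true(all(pop$dna_content > 1 & pop$dna_content < 2))
})

test_that("uniform ages give occupancy proportional to duration", {
  p <- population_params(n_cells = 10000, seed = 5, age_sampling = "iid")
  pop <- simulate_population(p)
  expected <- p$phase_durations_h / p$total_cycle_h
  obs <- table(pop$phase) / nrow(pop)
  for (ph in names(expected)) {
    se <- sqrt(expected[[ph]] * (1 - expected[[ph]]) / nrow(pop))
    expect_lt(abs(obs[[ph]] - expected[[ph]]), 3 * se)
  }
  # chi-square goodness of fit at n = 1e5 is not rejected
  p2 <- population_params(n_cells = 100000, seed = 6, age_sampling = "iid")
  tab <- table(simulate_population(p2)$phase)
  expect_gt(stats::chisq.test(tab, p = expected)$p.value, 0.01)
})

test_that("stratified age sampling reproduces occupancy almost exactly", {
  pop <- simulate_population(population_params(n_cells = 4500, seed = 8))
  expected <- c(G1_low = 8.1, G1_high = 3, S = 7.9, G2 = 2.5, M = 1) / 22.5
  obs <- table(pop$phase) / nrow(pop)
  for (ph in names(expected)) {
    expect_lt(abs(obs[[ph]] - expected[[ph]]), 1.5 / 4500)
  }
})

test_that("DNA content is piecewise {1, linear, 2} and continuous at boundaries", {
  p <- population_params()
  b <- cumsum(p$phase_durations_h)
  eps <- 1e-9
  expect_equal(dna_content_at(c(0, b[["G1_high"]] / 2, b[["G1_high"]]), p),
               c(1, 1, 1))
  expect_equal(dna_content_at(b[["S"]], p), 2)
  expect_equal(dna_content_at(c(b[["G2"]], 22.49), p), c(2, 2))
  mid <- b[["G1_high"]] + 0.5 * p$phase_durations_h[["S"]]
  expect_equal(dna_content_at(mid, p), 1.5)
  # continuity across every boundary
  for (bb in b[-length(b)]) {
    expect_equal(dna_content_at(bb - eps, p), dna_content_at(bb + eps, p),
                 tolerance = 1e-6)
  }
})

test_that("exponential-growth age density enriches young cells 2:1", {
  p <- population_params(n_cells = 200000, seed = 9,
                         age_distribution = "exponential_growth")
  pop <- simulate_population(p)
  t_half <- p$total_cycle_h / 2
  ratio <- mean(pop$age_h < t_half) / mean(pop$age_h >= t_half)
  # density 2^(-a/T): mass on [0,T/2] vs [T/2,T] is (2-sqrt2)/(sqrt2-1)
  expect_equal(ratio, (2 - sqrt(2)) / (sqrt(2) - 1), tolerance = 0.02)
})

test_that("EdU pulse labels by S-overlap: none in G2, rate x time in mid-S, half on entry", {
  d <- c(G1_low = 8.1, G1_high = 3, S = 7.9, G2 = 2.5, M = 1)
  mk <- function(age) {
    p <- quiet_params(n_cells = 1, seed = 1, edu_rate = 10)
    simulate_population(p, ages = age)
  }
  g2 <- apply_pulse_edu(mk(20.0), 0.5)       # G2 for the whole pulse
  expect_equal(g2$edu_label, 0)
  mid_s <- apply_pulse_edu(mk(15.0), 0.5)    # mid-S for the whole pulse
  expect_equal(mid_s$edu_label, 5.0)
  entering <- apply_pulse_edu(mk(11.1 - 0.25), 0.5)  # enters S halfway through
  expect_equal(entering$edu_label, 10 * 0.5 / 2)
  expect_error(apply_pulse_edu(mk(1), -1), "positive")
})

test_that("centered pulse window straddles the current age", {
  p <- quiet_params(n_cells = 1, seed = 1, edu_rate = 10)
  just_in_s <- apply_pulse_edu(simulate_population(p, ages = 11.1 + 0.05),
                               0.5, window = "centered")
  # window [age-0.25, age+0.25] overlaps S for 0.05 + 0.25 h
  expect_equal(just_in_s$edu_label, 10 * 0.3)
  just_out <- apply_pulse_edu(simulate_population(p, ages = 19.0 + 0.1),
                              0.5, window = "centered")
  expect_equal(just_out$edu_label, 10 * 0.15)  # trailing 0.15 h were in S
})

test_that("advance_chase: identity at dt = 0, label mass conserved through division", {
  p <- quiet_params(n_cells = 50, seed = 4)
  pop <- apply_pulse_edu(simulate_population(p), 0.5)
  expect_identical(advance_chase(pop, 0), pop)

  one <- simulate_population(quiet_params(n_cells = 1, seed = 2), ages = 15)
  one$edu_label <- 8.0
  one$sig_edu <- 8.0
  adv <- advance_chase(one, 7.6)   # crosses T exactly once, into early G1
  expect_equal(nrow(adv), 2)
  expect_equal(adv$edu_label, c(4, 4))
  expect_equal(adv$dna_content, c(1, 1))
  expect_equal(adv$generation, c(1L, 1L))
  expect_equal(unique(adv$lineage_id), one$lineage_id)
  # total label over the lineage is conserved
  expect_equal(sum(adv$edu_label), sum(one$edu_label))
})

test_that("populations and images are bit-identical given the same seed", {
  p <- population_params(n_cells = 60, seed = 77)
  expect_identical(simulate_population(p), simulate_population(p))
  pop <- simulate_population(p)
  r <- render_params(seed = 78)
  s1 <- render_image(pop, r, channels = c("hoechst", "edu"))
  s2 <- render_image(pop, r, channels = c("hoechst", "edu"))
  expect_identical(s1$channels, s2$channels)
  expect_identical(s1$truth, s2$truth)
})

test_that("set8 scenario: arrested cells are G1 with depleted H4K20me1 and peak MCM", {
  p <- population_params(n_cells = 400, seed = 12, scenario = "set8_sirna",
                         arrest_fraction = 1)
  pop <- simulate_population(p)
  gm <- growth_channel_means(p)
  expect_true(all(pop$phase %in% c("G1_low", "G1_high")))
  expect_true(all(pop$sig_h4k20me1 <= 2^-3 * gm[["h4k20me1"]]))
  expect_true(all(pop$sig_mcm2 == p$mcm_curve[["g1s_peak"]]))
})

test_that("invalid configurations are rejected", {
  expect_error(population_params(phase_durations_h = c(G1_low = -1, G1_high = 4,
                                                       S = 15, G2 = 3.5, M = 1)),
               "non-negative")
  expect_error(population_params(total_cycle_h = 20), "sum")
  expect_error(population_params(n_cells = 0), "n_cells")
  expect_error(population_params(scenario = "nocodazole"))
})
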