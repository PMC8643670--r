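test_that("background estimation: constant images, exact renders, salt robustness", {
  expect_equal(estimate_background(matrix(7, 32, 32)), 7)

  p <- quiet_params(n_cells = 20, seed = 60)
  st <- render_image(simulate_population(p),
                     render_params(seed = 61, read_noise_sigma = 0,
                                   background_level = 50),
                     channels = "hoechst")
  expect_equal(estimate_background(st$channels$hoechst), 50)

  img <- st$channels$hoechst
  flat <- which(img == 50)
  set.seed(1)
  img[sample(flat, length(img) %/% 100)] <- 10000  # 1% hot pixels off-cell
  expect_equal(estimate_background(img), 50)
})

test_that("segmentation recovers counts and areas on clean scenes and filters debris", {
  p <- quiet_params(n_cells = 12, seed = 70)
  st <- render_image(simulate_population(p), quiet_render(seed = 71),
                     channels = "hoechst")
  labels <- segment_nuclei(st$channels$hoechst, background = 0)
  expect_equal(max(labels), 12)
  meas <- match_truth(measure_nuclei(labels, st, backgrounds = list(hoechst = 0)),
                      st$truth)
  expect_true(all(abs(meas$area_px / (pi * meas$truth_radius_px^2) - 1) < 0.05))

  # a 4-px speck is dropped by the area filter
  img <- st$channels$hoechst
  img[5:6, 5:6] <- 5000
  labels2 <- segment_nuclei(img, min_area_px = 50, background = 0)
  expect_equal(max(labels2), 12)
})

test_that("uniform-image segmentation warns and returns an empty map", {
  expect_warning(labels <- segment_nuclei(matrix(3, 64, 64), background = 3),
                 "uniform")
  expect_equal(max(labels), 0)
  expect_equal(nrow(measure_nuclei(labels, list(hoechst = matrix(3, 64, 64)),
                                   backgrounds = list(hoechst = 3))), 0)
})

test_that("measurement arithmetic: uniform disk, background subtraction, invariants", {
  img <- matrix(0, 40, 40)
  labels <- matrix(0L, 40, 40)
  yy <- row(img) - 20.5; xx <- col(img) - 20.5
  disk <- yy^2 + xx^2 <= 5.6^2  # ~100 px
  img[disk] <- 10
  labels[disk] <- 1L
  m0 <- measure_nuclei(labels, list(hoechst = img),
                       backgrounds = list(hoechst = 0))
  expect_equal(m0$mean_hoechst, 10)
  expect_equal(m0$sum_hoechst, 10 * m0$area_px)

  img4 <- img + 4
  m4 <- measure_nuclei(labels, list(hoechst = img4),
                       backgrounds = list(hoechst = 4))
  expect_equal(m4$mean_hoechst, 10)
  expect_equal(m4$sum_hoechst, m4$mean_hoechst * m4$area_px)
})

test_that("measurement is translation-invariant", {
  p <- quiet_params(n_cells = 6, seed = 80)
  st <- render_image(simulate_population(p), quiet_render(seed = 81),
                     channels = "hoechst")
  img <- st$channels$hoechst
  pad <- matrix(0, nrow(img) + 10, ncol(img) + 10)
  base <- pad; base[1:nrow(img), 1:ncol(img)] <- img
  shifted <- pad; shifted[5 + 1:nrow(img), 7 + 1:ncol(img)] <- img
  m1 <- measure_nuclei(segment_nuclei(base, background = 0),
                       list(hoechst = base), backgrounds = list(hoechst = 0))
  m2 <- measure_nuclei(segment_nuclei(shifted, background = 0),
                       list(hoechst = shifted), backgrounds = list(hoechst = 0))
  ord1 <- order(m1$row, m1$col); ord2 <- order(m2$row, m2$col)
  expect_equal(m2$row[ord2] - m1$row[ord1], rep(5, 6))
  expect_equal(m2$col[ord2] - m1$col[ord1], rep(7, 6))
  expect_equal(m2$sum_hoechst[ord2], m1$sum_hoechst[ord1])
  expect_equal(m2$area_px[ord2], m1$area_px[ord1])
})

test_that("segmentation count is exact over 50 random clean scenes", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(5:25, 1)
    p <- quiet_params(n_cells = n, seed = 1000 + i)
    st <- render_image(simulate_population(p), quiet_render(seed = 2000 + i),
                       channels = "hoechst")
    labels <- segment_nuclei(st$channels$hoechst, background = 0)
    expect_equal(max(labels), n)
  }
})

test_that("M-phase flagging: all condensed cells flagged, no false positives", {
  # 395 interphase + 5 M cells, fixed seed, default heuristics
  p <- population_params(n_cells = 400, seed = 90)
  set.seed(90)
  ages <- c(stats::runif(395, 0, 21.5 - 1e-6), 21.5 + stats::runif(5, 0, 1))
  pop <- simulate_population(p, ages = ages)
  expect_equal(sum(pop$phase == "M"), 5)
  st <- render_image(pop, render_params(seed = 91), channels = "hoechst")
  labels <- segment_nuclei(st$channels$hoechst)
  meas <- flag_m_phase(measure_nuclei(labels, st))
  m <- match_truth(meas, st$truth)
  expect_equal(sum(m$m_phase_flag & m$truth_m_phase), 5)
  expect_equal(sum(m$m_phase_flag & !m$truth_m_phase), 0)

  # no condensed objects -> nothing flagged
  set.seed(94)
  interphase <- simulate_population(p, ages = stats::runif(400, 0, 21.4))
  st2 <- render_image(interphase, render_params(seed = 92), channels = "hoechst")
  meas2 <- flag_m_phase(measure_nuclei(segment_nuclei(st2$channels$hoechst), st2))
  expect_equal(sum(meas2$m_phase_flag), 0)

  # flagged objects never reach the records
  res <- small_experiment(n = 400, seed = 93)
  flagged <- res$analysis$measurements$nucleus_id[res$analysis$measurements$m_phase_flag]
  expect_gt(length(flagged), 0)
  expect_length(intersect(res$analysis$records$cell_id, flagged), 0)
})
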