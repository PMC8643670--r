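# Piecewise-linear marker dynamics as functions of age within the cycle.
# All helpers are vectorized over `age_h` and tolerate zero-length phases.

phase_levels <- c("G1_low", "G1_high", "S", "G2", "M")

phase_boundaries <- function(params) {
  cumsum(params$phase_durations_h)
}

#' Phase at a given age within the cycle
#'
#' @param age_h Hours since the last division, in `[0, T)`.
#' @param params A [population_params()].
#' @return Factor with levels `G1_low`, `G1_high`, `S`, `G2`, `M`.
#' @export
phase_at <- function(age_h, params) {
  b <- phase_boundaries(params)
  idx <- findInterval(age_h, c(0, b[-length(b)]), rightmost.closed = FALSE)
  idx[age_h >= b[length(b)]] <- length(phase_levels)
  factor(phase_levels[pmax(idx, 1L)], levels = phase_levels)
}

#' DNA content (genome equivalents) at a given age
#'
#' 1 throughout G1, rising linearly from 1 to 2 across S, 2 through G2 and M;
#' continuous at the phase boundaries.
#'
#' @inheritParams phase_at
#' @return Numeric in `[1, 2]`.
#' @export
dna_content_at <- function(age_h, params) {
  b <- phase_boundaries(params)
  s0 <- b[["G1_high"]]
  s1 <- b[["S"]]
  if (s1 > s0) {
    frac <- pmin(pmax((age_h - s0) / (s1 - s0), 0), 1)
  } else {
    frac <- as.numeric(age_h >= s0)
  }
  1 + frac
}

# linear interpolation on [x0, x1] that degrades gracefully when x1 <= x0
.lin <- function(age, x0, x1, y0, y1) {
  if (x1 <= x0) return(ifelse(age < x1, y0, y1))
  ifelse(age < x0, y0,
         ifelse(age >= x1, y1, y0 + (y1 - y0) * (age - x0) / (x1 - x0)))
}

# Noise-free per-cell marker totals (a.u.) at a given age.  Chromatin-bound
# MCM: plateau in early G1, ramp to the G1/S peak beginning at
# `mcm_ramp_start_h`, linear decline across S, flat floor through G2/M.
marker_totals_at <- function(age_h, params) {
  b <- phase_boundaries(params)
  g1_end <- b[["G1_high"]]
  s_end <- b[["S"]]
  mc <- params$mcm_curve
  hc <- params$h4k20_curve
  cc <- params$cdt1_curve
  a0 <- min(params$mcm_ramp_start_h, g1_end)

  mcm <- ifelse(age_h < g1_end,
                .lin(age_h, a0, g1_end, mc[["early_plateau"]], mc[["g1s_peak"]]),
                .lin(age_h, g1_end, s_end, mc[["g1s_peak"]], mc[["g2_floor"]]))
  me1 <- .lin(age_h, 0, g1_end, hc[["me1_peak"]], hc[["me1_floor"]])
  me23 <- .lin(age_h, 0, g1_end, hc[["me23_floor"]], hc[["me23_peak"]])
  cdt1 <- ifelse(age_h < g1_end,
                 .lin(age_h, 0, g1_end, cc[["g1_floor"]], cc[["g1s_peak"]]),
                 cc[["s_floor"]])

  tibble::tibble(
    sig_hoechst = params$hoechst_unit * dna_content_at(age_h, params),
    sig_mcm2 = mcm,
    sig_mcm3 = mcm,
    sig_cdt1 = cdt1,
    sig_h4k20me1 = me1,
    sig_h4k20me2 = me23,
    sig_h4k20me3 = me23
  )
}

#' Analytic channel means of an asynchronous growth population
#'
#' Expected per-cell totals of each marker channel for a uniform-age
#' population, averaged over the non-M part of the cycle (M-phase nuclei are
#' excluded from all normalization populations).  Used to calibrate gate
#' thresholds and to anchor the arrest-scenario signal levels to a
#' growth-phase reference.
#'
#' @param params A [population_params()].
#' @param n_grid Resolution of the trapezoidal integration.
#' @return Named numeric of channel means (a.u.), including `edu` for a 30-min
#'   pulse at fixation (`pulse_h` attribute 0.5).
#' @export
growth_channel_means <- function(params, n_grid = 4096) {
  t_nm <- params$total_cycle_h - params$phase_durations_h[["M"]]
  ages <- seq(0, t_nm, length.out = n_grid)
  sig <- marker_totals_at(ages, params)
  w <- rep(1, n_grid); w[c(1, n_grid)] <- 0.5
  out <- vapply(sig, function(x) sum(x * w) / sum(w), 0)
  names(out) <- sub("^sig_", "", names(out))
  out
}
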