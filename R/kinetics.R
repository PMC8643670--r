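# Growth-curve doubling time, the count-fraction phase-duration estimator,
# and pulse-chase cohort summaries.

#' Fit a doubling time to a growth curve
#'
#' Ordinary least squares of log2(count) against time; the doubling time is
#' the reciprocal slope.  In steady exponential growth the doubling time
#' equals the total cell-cycle length, the T of the duration estimator.
#'
#' @param time_h Strictly increasing sampling times (hours), >= 3 points.
#' @param count Positive cell counts at those times.
#' @return A list of class `cc_doubling_fit`: `doubling_time_h`, `slope`
#'   (log2 units/h), `r_squared`, and the `lm` fit.
#' @export
fit_doubling_time <- function(time_h, count) {
  if (is.data.frame(time_h)) {
    count <- time_h$count
    time_h <- time_h$time_h
  }
  stopifnot(length(time_h) == length(count))
  if (length(time_h) < 3) stop("need at least 3 growth-curve points")
  if (any(diff(time_h) <= 0)) stop("`time_h` must be strictly increasing")
  if (any(count <= 0)) stop("counts must be positive")
  fit <- stats::lm(log2(count) ~ time_h)
  slope <- unname(stats::coef(fit)[2])
  if (slope <= 0) stop("population not growing: non-positive slope")
  # noise-free curves fit perfectly; summary.lm warns about that, harmlessly
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(list(doubling_time_h = 1 / slope, slope = slope,
                 r_squared = r2, fit = fit),
            class = "cc_doubling_fit")
}

#' @export
print.cc_doubling_fit <- function(x, ...) {
  cat(sprintf("Doubling time: %.2f h (slope %.4f log2/h, R^2 %.4f)\n",
              x$doubling_time_h, x$slope, x$r_squared))
  invisible(x)
}

#' Simulate a growth curve
#'
#' Exponential growth with multiplicative log-normal count noise; the
#' synthetic counterpart of a hemocytometer/plate-counting time course.
#'
#' @param doubling_time_h True doubling time (hours).
#' @param times_h Sampling times (hours).
#' @param n0 Count at time 0.
#' @param noise_sigma_log SD (natural-log) of the count noise.
#' @param seed Integer seed.
#' @return Tibble with `time_h`, `count`.
#' @export
simulate_growth_curve <- function(doubling_time_h, times_h = seq(0, 120, 24),
                                  n0 = 1e4, noise_sigma_log = 0.02,
                                  seed = 1L) {
  stopifnot(doubling_time_h > 0, n0 > 0)
  set.seed(seed)
  tibble::tibble(
    time_h = times_h,
    count = n0 * 2^(times_h / doubling_time_h) *
      stats::rlnorm(length(times_h), 0, noise_sigma_log)
  )
}

#' Estimate per-phase durations from gated cell counts
#'
#' Duration of each phase = (cells in that phase / total cells) x total cycle
#' length.  Unclassified cells stay in the denominator but receive no
#' duration (so durations under-sum T when the EdU-negative mid-Hoechst band
#' is populated); `unclassified = "redistribute"` instead spreads their mass
#' proportionally over the phases, for sensitivity analysis.
#'
#' @param counts Named counts over any subset of
#'   `G1_low, G1_high, G1, S, G2, M, unclassified`.  M counts come from
#'   image-level flagging, not Hoechst gating.
#' @param total_cycle_h Total cell-cycle length T (hours), e.g. the fitted
#'   doubling time.
#' @param unclassified `"denominator"` (default) or `"redistribute"`.
#' @return A list of class `cc_phase_durations`: `counts`, `fractions`
#'   (summing to 1 over all keys), `durations_h`, `total_cycle_h`.
#' @export
estimate_phase_durations <- function(counts, total_cycle_h,
                                     unclassified = c("denominator",
                                                      "redistribute")) {
  unclassified <- match.arg(unclassified)
  if (length(counts) == 0) stop("empty phase counts")
  stopifnot(!is.null(names(counts)), all(counts >= 0), total_cycle_h > 0)
  total <- sum(counts)
  if (total <= 0) stop("total cell count must be positive")

  fractions <- counts / total
  phase_keys <- setdiff(names(counts), "unclassified")
  denom <- if (unclassified == "redistribute") {
    total - sum(counts[names(counts) == "unclassified"])
  } else {
    total
  }
  if (denom <= 0) stop("no classified cells to estimate durations from")
  durations <- counts[phase_keys] / denom * total_cycle_h

  structure(list(counts = counts, fractions = fractions,
                 durations_h = durations, total_cycle_h = total_cycle_h,
                 unclassified = unclassified),
            class = "cc_phase_durations")
}

#' @export
print.cc_phase_durations <- function(x, ...) {
  cat(sprintf("Phase durations (T = %.2f h, n = %d):\n", x$total_cycle_h,
              round(sum(x$counts))))
  for (p in names(x$durations_h)) {
    cat(sprintf("  %-12s %5d cells  %5.1f%%  %6.2f h\n", p, round(x$counts[[p]]),
                100 * x$fractions[[p]], x$durations_h[[p]]))
  }
  if ("unclassified" %in% names(x$counts)) {
    cat(sprintf("  %-12s %5d cells  %5.1f%%  (no duration)\n", "unclassified",
                round(x$counts[["unclassified"]]),
                100 * x$fractions[["unclassified"]]))
  }
  invisible(x)
}

#' Summarize a pulse-chase cohort
#'
#' Per-phase fractions of the EdU-labeled cohort at one chase time: the
#' "orange dot" overlay of the single-cell plots, tabulated.  The mask is the
#' EdU-positive gate at fixation (the label persists through divisions,
#' diluting twofold at each).
#'
#' @param records Gated records at the chase time (with `phase`).
#' @param labeled_mask Logical mask of the labeled cohort, e.g.
#'   `apply_gate(records, "edu_positive", config)`.
#' @return Tibble with `phase`, `n`, `fraction` (fractions sum to 1 over
#'   G1/S/G2/unclassified).
#' @export
pulse_chase_cohort_summary <- function(records, labeled_mask) {
  stopifnot(length(labeled_mask) == nrow(records))
  cohort <- records[labeled_mask, ]
  if (nrow(cohort) == 0) stop("empty labeled cohort")
  tab <- table(cohort$phase)
  tibble::tibble(phase = names(tab), n = as.integer(tab),
                 fraction = as.numeric(tab) / nrow(cohort))
}
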