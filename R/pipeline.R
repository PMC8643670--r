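# End-to-end wiring: stack -> segment -> measure -> M-exclusion ->
# normalized records -> gates, and the simulated-experiment driver.

#' Analyze an image stack into gated cell records
#'
#' Runs the full measurement pipeline on one multi-channel stack: per-channel
#' background estimation, Hoechst segmentation, per-nucleus measurement,
#' M-phase exclusion, normalization (on all non-M nuclei, before any
#' subsampling), phase gating and the low/high MCM split.
#'
#' @param stack A `cc_image_stack` (from [render_image()] or
#'   [read_image_stack()]).
#' @param config An [analysis_config()].
#' @param reference Optional reference for control-relative normalization:
#'   a `cc_analysis` of the control batch (its non-M measurements supply the
#'   Hoechst anchors and channel means).
#' @return A list of class `cc_analysis`: `records` (all non-M cells, gated),
#'   `sample` (the fixed-N plotting subsample, when configured),
#'   `measurements`, `backgrounds`, `n_m_flagged`, `labels`.
#' @export
analyze_stack <- function(stack, config = analysis_config(),
                          reference = NULL) {
  stopifnot(inherits(stack, "cc_image_stack"),
            inherits(config, "cc_analysis_config"))
  bg_hoechst <- estimate_background(stack$channels$hoechst)
  labels <- segment_nuclei(stack$channels$hoechst,
                           min_area_px = config$min_area_px,
                           max_area_px = config$max_area_px,
                           background = bg_hoechst)
  if (max(labels) == 0) stop("0 nuclei found in the Hoechst channel")
  # marker backgrounds: median outside the (Hoechst-defined) cells, which is
  # unbiased even for channels with hardly any foreground of their own
  outside <- labels == 0
  backgrounds <- vapply(stack$channels, function(ch) {
    max(stats::median(ch[outside]), 0)
  }, 0)
  backgrounds[["hoechst"]] <- bg_hoechst
  meas <- measure_nuclei(labels, stack, backgrounds = as.list(backgrounds))
  meas <- flag_m_phase(meas, area_quantile = config$m_area_quantile,
                       mean_hoechst_factor = config$m_hoechst_factor)

  ref_meas <- NULL
  if (!is.null(reference)) {
    ref_meas <- if (inherits(reference, "cc_analysis")) {
      reference$measurements
    } else {
      reference
    }
  }
  records <- build_cell_records(meas, config, reference = ref_meas)
  records <- classify_phase(records, config$gating,
                            edu_channel = config$edu_channel)
  if (config$mcm_channel %in% names(records)) {
    records <- split_g1_mcm(records, mcm_channel = config$mcm_channel,
                            config = config$gating)
  }

  smp <- NULL
  if (!is.null(config$subsample_n) && config$subsample_n > 0 &&
      nrow(records) >= config$subsample_n) {
    smp <- subsample_cells(records, config$subsample_n, config$subsample_seed)
  }
  structure(list(records = records, sample = smp, measurements = meas,
                 backgrounds = backgrounds,
                 n_m_flagged = sum(meas$m_phase_flag), labels = labels),
            class = "cc_analysis")
}

#' @export
print.cc_analysis <- function(x, ...) {
  cat(sprintf("<cc_analysis> %d nuclei (%d M-flagged excluded)\n",
              nrow(x$measurements), x$n_m_flagged))
  print(table(x$records$phase))
  invisible(x)
}

#' Gated phase counts of an analysis
#'
#' Tabulates the gated records into the keys of the duration estimator:
#' `G1_low`/`G1_high` (the MCM split of G1, when available, otherwise `G1`),
#' `S`, `G2`, `unclassified`, plus `M` from the image-level flag count.
#'
#' @param analysis A `cc_analysis`.
#' @param records Records to count (defaults to the full non-M records; pass
#'   `analysis$sample` to count the plotting subsample instead).
#' @return Named numeric counts.
#' @export
phase_counts <- function(analysis, records = NULL) {
  stopifnot(inherits(analysis, "cc_analysis"))
  if (is.null(records)) records <- analysis$records
  counts <- c()
  if (!is.null(records$mcm_state)) {
    counts <- c(G1_low = sum(records$phase == "G1" & records$mcm_state == "low"),
                G1_high = sum(records$phase == "G1" & records$mcm_state == "high"))
  } else {
    counts <- c(G1 = sum(records$phase == "G1"))
  }
  c(counts,
    S = sum(records$phase == "S"),
    G2 = sum(records$phase == "G2"),
    M = analysis$n_m_flagged,
    unclassified = sum(records$phase == "unclassified"))
}

#' Run a complete simulated pulse-fix experiment
#'
#' Simulates a population, applies the EdU pulse, renders, analyzes, and
#' estimates phase durations.  For a pulse-and-fix sample (no chase) the
#' recorded ages time-stamp the middle of the pulse (centered label window),
#' which keeps the labeling smear symmetric between the phases flanking S;
#' for a chase series the cohort is labeled at pulse start and then advanced
#' by `pulse_h / 2 + chase_h`.
#'
#' @param params A [population_params()].
#' @param render A [render_params()].
#' @param config An [analysis_config()].
#' @param pulse_h EdU pulse length (hours); 0 skips the pulse (no EdU
#'   labeling).
#' @param chase_h Additional chase time after the pulse before fixation.
#' @param fixation Passed to [render_image()].
#' @param channels Channels to render.
#' @param reference Optional control `cc_analysis` for reference
#'   normalization.
#' @return A list: `population` (at fixation), `stack`, `analysis`,
#'   `durations` (a `cc_phase_durations`).
#' @export
run_simulated_experiment <- function(params,
                                     render = render_params(),
                                     config = analysis_config(),
                                     pulse_h = 0.5,
                                     chase_h = 0,
                                     fixation = "pre_extraction",
                                     channels = c("hoechst", "edu", "mcm3"),
                                     reference = NULL) {
  pop <- simulate_population(params)
  if (pulse_h > 0 && chase_h > 0) {
    # pulse-chase: label the cohort at pulse start, then chase
    pop <- apply_pulse_edu(pop, pulse_h)
    pop <- advance_chase(pop, pulse_h / 2 + chase_h)
  } else if (pulse_h > 0) {
    # pulse-and-fix: ages time-stamp the pulse midpoint
    pop <- apply_pulse_edu(pop, pulse_h, window = "centered")
  } else if (chase_h > 0) {
    pop <- advance_chase(pop, chase_h)
  }
  stack <- render_image(pop, render = render, fixation = fixation,
                        channels = channels)
  analysis <- analyze_stack(stack, config, reference = reference)
  durations <- estimate_phase_durations(phase_counts(analysis),
                                        params$total_cycle_h)
  list(population = pop, stack = stack, analysis = analysis,
       durations = durations)
}

#' Run a simulated pulse-chase series
#'
#' Labels the population with a forward EdU pulse at time 0, then fixes one
#' sample per chase time and follows the labeled cohort (the "orange dots")
#' through the cycle.  At the 0-h time point the cohort is, by construction
#' of the label, in S phase and phases come from the EdU/Hoechst gates; at
#' later times the label only marks the cohort, so phases are read from DNA
#' content alone ([classify_phase_hoechst()]).
#'
#' @inheritParams run_simulated_experiment
#' @param chase_h Numeric vector of chase times (hours); 0 is the pulse-fix
#'   panel.
#' @return A list with `cohort` (tibble: `chase_h`, `phase`, `n`,
#'   `fraction`) and `analyses` (one `cc_analysis` per chase time, with the
#'   cohort mask in `$cohort_mask`).
#' @export
run_pulse_chase <- function(params,
                            render = render_params(),
                            config = analysis_config(),
                            chase_h = c(0, 4, 8, 12, 16, 20, 24),
                            pulse_h = 0.5,
                            fixation = "pre_extraction",
                            channels = c("hoechst", "edu", "mcm3")) {
  pop0 <- simulate_population(params)
  pop0 <- apply_pulse_edu(pop0, pulse_h)
  analyses <- list()
  cohort <- list()
  for (i in seq_along(chase_h)) {
    t <- chase_h[i]
    pop <- advance_chase(pop0, pulse_h / 2 + t)
    rp <- render
    rp$seed <- render$seed + i - 1L
    stack <- render_image(pop, render = rp, fixation = fixation,
                          channels = channels)
    an <- analyze_stack(stack, config)
    if (t > 0) {
      an$records <- classify_phase_hoechst(an$records, config$gating)
    }
    mask <- apply_gate(an$records, "edu_positive", config$gating)
    an$cohort_mask <- mask
    analyses[[as.character(t)]] <- an
    cs <- pulse_chase_cohort_summary(an$records, mask)
    cs$chase_h <- t
    cohort[[i]] <- cs
  }
  list(cohort = dplyr::bind_rows(cohort)[, c("chase_h", "phase", "n", "fraction")],
       analyses = analyses)
}
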