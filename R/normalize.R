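# The two plotting scales of single-cell plot analysis: a linear DNA-content
# scale anchored on Hoechst order statistics, and a log2 mean-relative scale
# for every other channel.

#' Hoechst order-statistic anchors
#'
#' The k-th lowest and k-th highest Hoechst sums of the analyzed population
#' (defaults k = 10), used as the 1 and 2 anchors of the linear DNA-content
#' scale; the single most extreme nuclei are often outliers, hence an
#' interior rank.
#'
#' @param sums Per-nucleus Hoechst sum intensities (length >= 2k, values >= 0).
#' @param k Order-statistic rank.
#' @return Named numeric `c(L, H)`.
#' @export
hoechst_anchors <- function(sums, k = 10) {
  n <- length(sums)
  if (n < 2 * k) {
    stop(sprintf("need at least 2k = %d nuclei to anchor the Hoechst scale, got %d",
                 2 * k, n))
  }
  s <- sort(sums)
  anchors <- c(L = s[k], H = s[n - k + 1])
  if (anchors[["H"]] <= anchors[["L"]]) {
    stop("degenerate Hoechst spread: k-th lowest and k-th highest sums coincide")
  }
  anchors
}

#' Normalize Hoechst sums to the linear 1-2 DNA-content scale
#'
#' Affine map sending the k-th smallest sum to 1 and the k-th largest to 2
#' (G1 and G2 DNA content).  Values outside the anchors map outside `[1, 2]`
#' and are not clipped.  Strictly monotone and invariant to rescaling all
#' inputs by a positive constant.
#'
#' @inheritParams hoechst_anchors
#' @param anchors Optional anchors from a reference population (e.g. the
#'   control batch of an arrest experiment), as returned by
#'   [hoechst_anchors()].
#' @return Numeric vector on the linear DNA-content scale.
#' @export
normalize_hoechst <- function(sums, k = 10, anchors = NULL) {
  if (is.null(anchors)) anchors <- hoechst_anchors(sums, k)
  1 + (sums - anchors[["L"]]) / (anchors[["H"]] - anchors[["L"]])
}

#' Normalize a marker channel to the log2 mean-relative scale
#'
#' Divides by the arithmetic mean of the vector (so the population average is
#' 0 on the log2 scale) and takes log2; ratios below `2^floor_log2` are
#' clamped to `floor_log2` so zero-intensity nuclei (e.g. EdU-negative cells)
#' stay finite and below every printed gate.
#'
#' @param sums Per-nucleus sum intensities (>= 0).
#' @param floor_log2 Clamp for the log2 ratio.
#' @param reference_mean Optional externally supplied divisor (see
#'   [normalize_to_reference()]).
#' @return Numeric vector of log2 mean-relative values.
#' @export
normalize_channel_log2 <- function(sums, floor_log2 = -10,
                                   reference_mean = NULL) {
  stopifnot(length(sums) >= 1, all(sums >= 0))
  m <- if (is.null(reference_mean)) mean(sums) else reference_mean
  if (m <= 0) {
    stop("cannot normalize: mean intensity is zero (all-zero channel?)")
  }
  log2(pmax(sums / m, 2^floor_log2))
}

#' Normalize against a reference population
#'
#' Same log2 scale as [normalize_channel_log2()] but divided by the mean of a
#' reference population (the control-siRNA or untreated batch), so treated
#' and control cells share one scale.
#'
#' @param sums Per-nucleus sum intensities of the treated population.
#' @param reference_sums Sum intensities of the reference population.
#' @param floor_log2 Clamp for the log2 ratio.
#' @return Numeric vector of log2 reference-relative values.
#' @export
normalize_to_reference <- function(sums, reference_sums, floor_log2 = -10) {
  if (length(reference_sums) == 0 || mean(reference_sums) <= 0) {
    stop("reference population has non-positive mean intensity")
  }
  normalize_channel_log2(sums, floor_log2 = floor_log2,
                         reference_mean = mean(reference_sums))
}

#' Draw the fixed-N plotting sample
#'
#' Seeded uniform sample without replacement, keeping the records in
#' `cell_id` order.  Panels in this workflow show 400-450 cells; sampling
#' happens after normalization and gating, so results do not depend on the
#' sampling seed.
#'
#' @param records A per-cell records tibble (must contain `cell_id`).
#' @param n Sample size.
#' @param seed Integer seed.
#' @return The sampled records.
#' @export
subsample_cells <- function(records, n, seed = 1L) {
  if (nrow(records) < n) {
    stop(sprintf("cannot sample %d cells: only %d available", n, nrow(records)))
  }
  set.seed(seed)
  idx <- sort(sample.int(nrow(records), n))
  out <- records[idx, ]
  out[order(out$cell_id), ]
}

#' Build normalized cell records from nucleus measurements
#'
#' Drops M-flagged objects, puts Hoechst on the linear DNA-content scale and
#' every other channel on the log2 mean-relative scale.  When a `reference`
#' is given (measurements of a control batch), its non-M nuclei supply both
#' the Hoechst anchors and the channel means, mirroring control-siRNA
#' normalization.
#'
#' @param measurements Output of [measure_nuclei()]/[flag_m_phase()].
#' @param config An [analysis_config()].
#' @param reference Optional measurements tibble of the control batch.
#' @return A tibble of cell records: `cell_id`, `hoechst_norm`, one log2
#'   column per marker channel (named by channel), plus `area_px`, `row`,
#'   `col`.
#' @export
build_cell_records <- function(measurements, config = analysis_config(),
                               reference = NULL) {
  stopifnot(inherits(config, "cc_analysis_config"))
  meas <- measurements[!measurements$m_phase_flag, ]
  chans <- sub("^sum_", "", grep("^sum_", names(meas), value = TRUE))
  stopifnot("hoechst" %in% chans)

  ref <- NULL
  if (!is.null(reference)) ref <- reference[!reference$m_phase_flag, ]

  anchors <- hoechst_anchors(
    if (is.null(ref)) meas$sum_hoechst else ref$sum_hoechst, config$k)

  rec <- tibble::tibble(
    cell_id = meas$nucleus_id,
    hoechst_norm = normalize_hoechst(meas$sum_hoechst, anchors = anchors)
  )
  for (ch in setdiff(chans, "hoechst")) {
    ref_mean <- if (is.null(ref)) NULL else mean(ref[[paste0("sum_", ch)]])
    rec[[ch]] <- normalize_channel_log2(meas[[paste0("sum_", ch)]],
                                        floor_log2 = config$floor_log2,
                                        reference_mean = ref_mean)
  }
  rec$area_px <- meas$area_px
  rec$row <- meas$row
  rec$col <- meas$col
  rec
}
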