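# Per-nucleus quantification: background estimation, Hoechst segmentation,
# per-channel sum intensities, and the M-phase exclusion heuristic.

otsu_threshold <- function(image) {
  rng <- range(image)
  if (diff(rng) == 0) return(NA_real_)
  x <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(x), range = c(0, 1), levels = 256L)
  rng[1] + th * diff(rng)
}

#' Estimate the image background level
#'
#' Automatic threshold (Otsu) of the image defines a foreground mask; the
#' background is the median intensity of the pixels outside it (robust to a
#' small fraction of hot pixels).  A constant image is all background.
#'
#' @param image 2D intensity matrix.
#' @return Scalar background level (a.u., clamped at >= 0).
#' @export
estimate_background <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0)
  th <- otsu_threshold(image)
  if (is.na(th)) return(max(image[1], 0))
  bg_px <- image[image <= th]
  if (length(bg_px) == 0) {
    stop("no background estimable: every pixel is foreground")
  }
  max(stats::median(bg_px), 0)
}

#' Segment nuclei from the Hoechst channel
#'
#' Background-subtracted Hoechst is thresholded by Otsu's method, the binary
#' mask is hole-filled and labeled, and components outside
#' `[min_area_px, max_area_px]` are discarded.  Labels are renumbered
#' `1..K`; 0 is background.
#'
#' @param hoechst 2D Hoechst intensity matrix.
#' @param min_area_px,max_area_px Area limits in pixels^2.
#' @param background Optional known background level; estimated from the image
#'   when `NULL`.
#' @return Integer label matrix.  A uniform image (nothing to threshold)
#'   yields an empty label map with a warning.
#' @export
segment_nuclei <- function(hoechst, min_area_px = 50, max_area_px = 2500,
                           background = NULL) {
  stopifnot(min_area_px < max_area_px)
  if (is.null(background)) background <- estimate_background(hoechst)
  sub <- hoechst - background
  th <- otsu_threshold(sub)
  if (is.na(th)) {
    warning("uniform image: no threshold separates foreground from background")
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  }
  # Reject thresholds that merely split unimodal background noise: for any
  # unimodal distribution the class-mean separation is a small multiple of
  # the background-class SD (~2-3x for Gaussian noise), while real nuclei
  # sit far above it.
  m0 <- sub[sub <= th]
  m1 <- sub[sub > th]
  sd0 <- stats::sd(m0)
  if (length(m1) == 0 ||
      (is.finite(sd0) && sd0 > 0 && (mean(m1) - mean(m0)) < 6 * sd0)) {
    warning("no nuclei: threshold does not separate two intensity classes")
    return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  }
  mask <- EBImage::fillHull(EBImage::Image(sub > th))
  labels <- EBImage::imageData(EBImage::bwlabel(mask))
  if (max(labels) == 0) return(matrix(0L, nrow(hoechst), ncol(hoechst)))
  areas <- tabulate(labels[labels > 0], nbins = max(labels))
  keep <- which(areas >= min_area_px & areas <= max_area_px)
  remap <- integer(max(labels))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(hoechst), ncol(hoechst))
  fg <- labels > 0
  out[fg] <- remap[labels[fg]]
  out
}

#' Measure per-nucleus area and intensities
#'
#' For every label and channel: mean intensity = mean(pixel - background)
#' clamped at >= 0, and sum intensity = mean x area (the working quantity of
#' the single-cell plots).  Centroids are unweighted pixel centroids, 0-based
#' `(row, col)`.
#'
#' @param labels Integer label matrix from [segment_nuclei()].
#' @param stack A `cc_image_stack` (or named list of matrices).
#' @param backgrounds Named numeric of per-channel background levels; missing
#'   channels are estimated from their images.
#' @return A tibble with one row per nucleus: `nucleus_id`, `row`, `col`,
#'   `area_px`, `mean_<channel>`, `sum_<channel>`, `m_phase_flag` (FALSE; see
#'   [flag_m_phase()]).  Empty label maps give an empty tibble.
#' @export
measure_nuclei <- function(labels, stack, backgrounds = NULL) {
  channels <- if (inherits(stack, "cc_image_stack")) stack$channels else stack
  stopifnot(all(vapply(channels, function(m) all(dim(m) == dim(labels)), TRUE)))

  k <- max(labels)
  base <- tibble::tibble(nucleus_id = integer(), row = numeric(),
                         col = numeric(), area_px = integer())
  if (k == 0) {
    for (ch in names(channels)) {
      base[[paste0("mean_", ch)]] <- numeric()
      base[[paste0("sum_", ch)]] <- numeric()
    }
    base$m_phase_flag <- logical()
    return(base)
  }

  idx <- which(labels > 0)
  lab <- labels[idx]
  area <- tabulate(lab, nbins = k)
  rows0 <- (idx - 1) %% nrow(labels)
  cols0 <- (idx - 1) %/% nrow(labels)
  out <- tibble::tibble(
    nucleus_id = seq_len(k),
    row = as.numeric(rowsum(rows0, lab)) / area,
    col = as.numeric(rowsum(cols0, lab)) / area,
    area_px = area
  )
  for (ch in names(channels)) {
    bg <- backgrounds[[ch]]
    if (is.null(bg)) bg <- estimate_background(channels[[ch]])
    sums_raw <- as.numeric(rowsum(channels[[ch]][idx], lab))
    mn <- pmax(sums_raw / area - bg, 0)
    out[[paste0("mean_", ch)]] <- mn
    out[[paste0("sum_", ch)]] <- mn * area
  }
  out$m_phase_flag <- FALSE
  out
}

#' Flag M-phase nuclei
#'
#' Condensed mitotic chromosomes are substantially smaller and brighter than
#' interphase nuclei, so sum intensities are not comparable and M-phase
#' objects must be excluded from normalization and gating (their count is
#' still reported to the duration estimator).  An object is flagged when its
#' area falls below the `area_quantile` population quantile AND its mean
#' Hoechst exceeds `mean_hoechst_factor` times the population median.
#'
#' @param measurements Output of [measure_nuclei()] (>= 1 row).
#' @param area_quantile Area quantile below which an object is small.
#' @param mean_hoechst_factor Brightness factor over the median mean-Hoechst.
#' @return `measurements` with `m_phase_flag` set.
#' @export
flag_m_phase <- function(measurements, area_quantile = 0.1,
                         mean_hoechst_factor = 1.8) {
  stopifnot(nrow(measurements) >= 1)
  a_th <- stats::quantile(measurements$area_px, area_quantile, names = FALSE)
  h_th <- mean_hoechst_factor * stats::median(measurements$mean_hoechst)
  measurements$m_phase_flag <- measurements$area_px < a_th &
    measurements$mean_hoechst > h_th
  measurements
}

#' Match measured nuclei to simulated ground truth
#'
#' Joins each segmented nucleus to the nearest ground-truth cell center
#' (within `max_dist_px`), so gate labels can be audited against truth.
#'
#' @param measurements Output of [measure_nuclei()].
#' @param truth Ground-truth table of a rendered stack.
#' @param max_dist_px Maximum centroid-to-center distance for a match.
#' @return `measurements` with the matched truth columns appended
#'   (unmatched nuclei get NA).
#' @export
match_truth <- function(measurements, truth, max_dist_px = 10) {
  if (nrow(measurements) == 0) return(measurements)
  nearest <- integer(nrow(measurements))
  dist <- numeric(nrow(measurements))
  step <- 1000L
  for (start in seq(1, nrow(measurements), by = step)) {
    i <- start:min(start + step - 1L, nrow(measurements))
    d2 <- outer(measurements$row[i], truth$y, `-`)^2 +
      outer(measurements$col[i], truth$x, `-`)^2
    nearest[i] <- max.col(-d2, ties.method = "first")
    dist[i] <- sqrt(d2[cbind(seq_along(i), nearest[i])])
  }
  matched <- truth[nearest, ]
  matched[dist > max_dist_px, ] <- NA
  names(matched) <- paste0("truth_", names(matched))
  dplyr::bind_cols(measurements, matched)
}
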