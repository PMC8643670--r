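#' Single-cell plot
#'
#' The scatter at the heart of the analysis: one dot per cell, DNA content
#' (linear Hoechst scale, 1 = G1, 2 = G2) on the x axis and a marker's log2
#' mean-relative intensity on the y axis, with optional gate overlays in the
#' conventional colors (EdU-positive cohort orange; named gates pink, blue,
#' light blue).
#'
#' @param records Gated cell records.
#' @param channel Marker channel to plot on the y axis.
#' @param overlay Named character: gate name -> color, drawn over the base
#'   dots, e.g. `c(edu_positive = "orange")`.
#' @param config A [gating_config()] (evaluates the overlay gates; its MCM
#'   threshold is drawn as a tick when `channel` is an MCM channel).
#' @param point_size Dot size.
#' @return A ggplot object.
#' @export
plot_single_cell <- function(records, channel,
                             overlay = c(edu_positive = "orange"),
                             config = gating_config(),
                             point_size = 0.8) {
  stopifnot(channel %in% names(records))
  df <- tibble::tibble(hoechst = records$hoechst_norm,
                       y = records[[channel]])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = hoechst, y = .data$y)) +
    ggplot2::geom_point(size = point_size, color = "grey40", alpha = 0.7) +
    ggplot2::scale_x_continuous(breaks = c(1, 1.5, 2)) +
    ggplot2::labs(x = "Hoechst (DNA content, linear)",
                  y = bquote(log[2] * "(" * .(channel) * ")")) +
    ggplot2::theme_classic()
  for (g in names(overlay)) {
    mask <- apply_gate(records, g, config)
    if (any(mask)) {
      p <- p + ggplot2::geom_point(data = df[mask, ], size = point_size,
                                   color = overlay[[g]])
    }
  }
  if (channel %in% c("mcm2", "mcm3")) {
    p <- p + ggplot2::geom_hline(yintercept = config$mcm_high_log2,
                                 linetype = "dashed", linewidth = 0.3)
  }
  p
}

#' Phase-duration bar plot
#'
#' @param durations A `cc_phase_durations` (or a named list of them, one bar
#'   group per name).
#' @return A ggplot object.
#' @export
plot_phase_durations <- function(durations) {
  if (inherits(durations, "cc_phase_durations")) {
    durations <- list(estimate = durations)
  }
  df <- dplyr::bind_rows(lapply(names(durations), function(nm) {
    d <- durations[[nm]]
    tibble::tibble(group = nm, phase = names(d$durations_h),
                   hours = as.numeric(d$durations_h))
  }))
  df$phase <- factor(df$phase, levels = unique(df$phase))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phase, y = .data$hours,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "duration (h)") +
    ggplot2::theme_classic()
}
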