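# Threshold gating on the normalized scales: cell-cycle phases from DNA
# content and EdU, the low/high chromatin-MCM split of G1, and named
# subpopulation gates defined as data (channel, comparator, threshold).

#' Built-in low/high MCM thresholds per cell line
#'
#' log2(MCM) values (relative to the population mean) separating the low- and
#' high-MCM states of G1, anchored on the MCM level of early-G1 cells
#' (the 8-h pulse-chase cohort) in each line.
#' @export
mcm_thresholds <- c("hTERT-RPE1" = 0.5, "HeLa" = 0.3, "U2OS" = 0.7,
                    "MRC5" = 1.0, "IMR90" = 1.5)

default_gates <- function(hoechst_g1_max = 1.125, log2_edu_s_min = -3) {
  gate <- function(channel, cmp, threshold) {
    tibble::tibble(channel = channel, cmp = cmp, threshold = threshold)
  }
  list(
    edu_positive = gate("edu", ">", log2_edu_s_min),
    cdt1_high = gate(c("cdt1", "hoechst"), c(">", "<"),
                     c(1.5, hoechst_g1_max)),
    h4k20me1_high = gate(c("hoechst", "h4k20me1"), c("<", ">"),
                         c(hoechst_g1_max, 0.3)),
    h4k20me2_low = gate(c("hoechst", "h4k20me2"), c("<", "<"),
                        c(hoechst_g1_max, -0.1)),
    mcm2_high_g1 = gate(c("mcm2", "hoechst", "edu"), c(">", "<", "<"),
                        c(0.5, hoechst_g1_max, log2_edu_s_min))
  )
}

#' Gating configuration
#'
#' The printed thresholds of the phase gates and named subpopulation gates:
#' G1 is Hoechst < `hoechst_g1_max` with log2(EdU) < `log2_edu_s_min`; S is
#' log2(EdU) > `log2_edu_s_min` at any Hoechst; G2 is Hoechst >
#' `hoechst_g2_min` with log2(EdU) < `log2_edu_s_min`.  All comparisons are
#' strict, so a value exactly at a threshold satisfies neither side: such
#' cells fall to `"unclassified"` (and exact-boundary MCM values to
#' `"low"`).
#'
#' @param cell_line Cell line selecting the low/high MCM threshold from
#'   [mcm_thresholds] (ignored when `mcm_high_log2` is given).
#' @param mcm_high_log2 Explicit low/high MCM threshold (log2 units).
#' @param hoechst_g1_max,hoechst_g2_min Linear-scale DNA-content bounds of the
#'   G1 and G2 gates.
#' @param log2_edu_s_min log2(EdU) bound of the S gate.
#' @param named_gates Named list of gate tables, each with columns `channel`
#'   (`"hoechst"` for the linear scale, a channel name for its log2 scale),
#'   `cmp` (`">"` or `"<"`), `threshold`.  Figure-specific gates are rows of
#'   data, not code.
#' @return A list of class `cc_gating_config`.
#' @export
gating_config <- function(cell_line = "hTERT-RPE1",
                          mcm_high_log2 = NULL,
                          hoechst_g1_max = 1.125,
                          hoechst_g2_min = 1.7,
                          log2_edu_s_min = -3,
                          named_gates = NULL) {
  if (hoechst_g1_max >= hoechst_g2_min) {
    stop("`hoechst_g1_max` must be below `hoechst_g2_min`")
  }
  if (is.null(mcm_high_log2)) {
    if (!cell_line %in% names(mcm_thresholds)) {
      stop("no low/high MCM threshold known for cell line \"", cell_line,
           "\"; known: ", paste(names(mcm_thresholds), collapse = ", "),
           " (or give `mcm_high_log2` explicitly)")
    }
    mcm_high_log2 <- mcm_thresholds[[cell_line]]
  }
  if (is.null(named_gates)) {
    named_gates <- default_gates(hoechst_g1_max, log2_edu_s_min)
  }
  stopifnot(is.finite(mcm_high_log2), is.finite(hoechst_g1_max),
            is.finite(hoechst_g2_min), is.finite(log2_edu_s_min))
  structure(list(cell_line = cell_line, mcm_high_log2 = mcm_high_log2,
                 hoechst_g1_max = hoechst_g1_max,
                 hoechst_g2_min = hoechst_g2_min,
                 log2_edu_s_min = log2_edu_s_min,
                 named_gates = named_gates),
            class = "cc_gating_config")
}

#' Assign cell-cycle phases from the normalized scales
#'
#' S if log2(EdU) above the EdU gate (any Hoechst); G1 if Hoechst below the
#' G1 bound and EdU-negative; G2 if Hoechst above the G2 bound and
#' EdU-negative; otherwise `"unclassified"` (the EdU-negative mid-Hoechst
#' band, retained in totals but given no duration).  The three gates are
#' mutually exclusive by construction.
#'
#' @param records Records tibble with `hoechst_norm` and the EdU log2 column.
#' @param config A [gating_config()].
#' @param edu_channel Name of the EdU log2 column.
#' @return `records` with a `phase` factor (`G1`, `S`, `G2`, `unclassified`).
#' @export
classify_phase <- function(records, config = gating_config(),
                           edu_channel = "edu") {
  stopifnot(inherits(config, "cc_gating_config"))
  if (!edu_channel %in% names(records)) {
    stop("records lack the EdU channel \"", edu_channel,
         "\" required for phase gating")
  }
  edu <- records[[edu_channel]]
  h <- records$hoechst_norm
  phase <- rep("unclassified", nrow(records))
  phase[edu > config$log2_edu_s_min] <- "S"
  phase[edu < config$log2_edu_s_min & h < config$hoechst_g1_max] <- "G1"
  phase[edu < config$log2_edu_s_min & h > config$hoechst_g2_min] <- "G2"
  records$phase <- factor(phase, levels = c("G1", "S", "G2", "unclassified"))
  records
}

#' Assign cell-cycle phases from DNA content alone
#'
#' During a chase, EdU marks the pulse-labeled cohort rather than cells
#' currently in S, so chase-time phases can only be read from DNA content:
#' G1 below the G1 bound, G2 above the G2 bound, S in the mid band.
#'
#' @inheritParams classify_phase
#' @return `records` with a `phase` factor (`G1`, `S`, `G2`, `unclassified`;
#'   the last level is unused here but kept so chase and pulse-fix records
#'   share one phase scale).
#' @export
classify_phase_hoechst <- function(records, config = gating_config()) {
  stopifnot(inherits(config, "cc_gating_config"))
  h <- records$hoechst_norm
  phase <- rep("S", nrow(records))
  phase[h < config$hoechst_g1_max] <- "G1"
  phase[h > config$hoechst_g2_min] <- "G2"
  records$phase <- factor(phase, levels = c("G1", "S", "G2", "unclassified"))
  records
}

#' Split G1 cells into low- and high-MCM states
#'
#' G1 cells are `"high"` when their MCM log2 value strictly exceeds the
#' cell-line threshold, `"low"` otherwise; non-G1 cells get `"n/a"`.
#'
#' @param records Records with phases assigned by [classify_phase()].
#' @param mcm_channel Name of the MCM log2 column.
#' @param config A [gating_config()].
#' @return `records` with an `mcm_state` factor (`low`, `high`, `n/a`).
#' @export
split_g1_mcm <- function(records, mcm_channel = "mcm3",
                         config = gating_config()) {
  stopifnot(inherits(config, "cc_gating_config"))
  if (is.null(records$phase)) stop("assign phases before the MCM split")
  if (!mcm_channel %in% names(records)) {
    stop("records lack MCM channel \"", mcm_channel, "\"")
  }
  state <- rep("n/a", nrow(records))
  g1 <- records$phase == "G1"
  state[g1] <- ifelse(records[[mcm_channel]][g1] > config$mcm_high_log2,
                      "high", "low")
  records$mcm_state <- factor(state, levels = c("low", "high", "n/a"))
  records
}

#' Evaluate a named subpopulation gate
#'
#' Returns the conjunction of the gate's clauses over the records; clause
#' channels named `"hoechst"` compare on the linear DNA-content scale
#' (`hoechst_norm`), all others on their log2 column.
#'
#' @param records Records tibble.
#' @param gate_name One of the configured gates (built-ins: `edu_positive`,
#'   `cdt1_high`, `h4k20me1_high`, `h4k20me2_low`, `mcm2_high_g1`).
#' @param config A [gating_config()].
#' @return Logical mask over the rows of `records`.
#' @export
apply_gate <- function(records, gate_name, config = gating_config()) {
  stopifnot(inherits(config, "cc_gating_config"))
  if (!gate_name %in% names(config$named_gates)) {
    stop("unknown gate \"", gate_name, "\"; available: ",
         paste(names(config$named_gates), collapse = ", "))
  }
  gate <- config$named_gates[[gate_name]]
  mask <- rep(TRUE, nrow(records))
  for (i in seq_len(nrow(gate))) {
    col <- if (gate$channel[i] == "hoechst") "hoechst_norm" else gate$channel[i]
    if (!col %in% names(records)) {
      stop("gate \"", gate_name, "\" needs channel \"", gate$channel[i],
           "\" which is absent from the records")
    }
    x <- records[[col]]
    mask <- mask & switch(gate$cmp[i],
                          ">" = x > gate$threshold[i],
                          "<" = x < gate$threshold[i],
                          stop("unsupported comparator: ", gate$cmp[i]))
  }
  mask
}
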