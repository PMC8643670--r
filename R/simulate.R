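#' Simulate a ground-truth cell population
#'
#' Draws `n_cells` cells with ages from the configured age distribution,
#' assigns cell-cycle phases from the cumulative phase boundaries, DNA content
#' and noise-free marker totals from the piecewise-linear marker curves, and
#' per-cell multiplicative staining-noise factors.  Non-growth scenarios then
#' arrest `arrest_fraction` of the cells and override their signals with the
#' qualitative pattern of the corresponding perturbation (see Details).
#'
#' @details
#' Scenario presets (applied to the arrested subset; the remainder keeps the
#' asynchronous growth pattern):
#' \describe{
#'   \item{confluent}{G1 arrest; chromatin MCM at low-to-moderate levels
#'     (log2 of -4.5 to -0.5 relative to the growth-population mean) and
#'     H4K20me1 at -3 to 0.}
#'   \item{set8_sirna}{G1 arrest with H4K20me1 depleted (below -3 log2 units
#'     relative to the growth mean; mono-methylation writer silenced) while
#'     chromatin MCM sits at the G1/S peak level and H4K20me2/3 is unchanged.}
#'   \item{suv420h1_sirna}{G1 arrest with H4K20me1 retained at its early-G1
#'     peak, H4K20me2/3 at the floor (me1-to-me2/3 conversion blocked), and
#'     MCM on the early-G1 plateau.}
#'   \item{palbociclib_1um}{Early-G1 arrest (ages before the MCM ramp), MCM on
#'     the early plateau.}
#'   \item{palbociclib_150nm}{G1 arrest spread across G1, MCM heterogeneous
#'     from plateau to peak.}
#'   \item{hydroxyurea}{Early-S arrest: DNA content just above 1x, cells
#'     actively synthesizing (EdU-positive after a pulse).}
#' }
#' Arrested cells carry `arrested = TRUE`, do not advance during a chase, and
#' never divide.
#'
#' @param params A [population_params()].
#' @param ages Optional numeric vector of ages (hours, in `[0, T)`) overriding
#'   the age draw; used for controlled experiments.
#' @return A tibble of class `cc_population`, one row per cell, with the
#'   parameters attached as attribute `params`.  Columns: `cell_id`,
#'   `lineage_id`, `age_h`, `phase`, `dna_content`, `generation`, `edu_label`,
#'   `arrested`, noise-free totals `sig_*`, and staining factors `nf_*`.
#' @export
simulate_population <- function(params, ages = NULL) {
  stopifnot(inherits(params, "cc_population_params"))
  n <- params$n_cells
  t_total <- params$total_cycle_h
  set.seed(params$seed)

  if (is.null(ages)) {
    u <- switch(params$age_sampling,
                stratified = (sample.int(n) - stats::runif(n)) / n,
                iid = stats::runif(n))
    ages <- switch(params$age_distribution,
                   uniform = u * t_total,
                   exponential_growth = -t_total * log2(1 - u / 2))
    ages <- pmin(ages, t_total * (1 - 1e-12))
  } else {
    stopifnot(length(ages) == n, all(ages >= 0), all(ages < t_total))
  }

  pop <- tibble::tibble(
    cell_id = seq_len(n),
    lineage_id = seq_len(n),
    age_h = as.numeric(ages),
    phase = phase_at(ages, params),
    dna_content = dna_content_at(ages, params),
    generation = 0L,
    edu_label = 0,
    arrested = FALSE
  )
  pop <- dplyr::bind_cols(pop, marker_totals_at(pop$age_h, params))
  pop$sig_edu <- 0

  # per-cell multiplicative staining factors, persistent through the chase
  marker_chans <- c("mcm2", "mcm3", "cdt1", "h4k20me1", "h4k20me2",
                    "h4k20me3", "edu")
  pop$nf_hoechst <- stats::rlnorm(n, 0, params$dna_noise_sigma_log)
  for (ch in marker_chans) {
    pop[[paste0("nf_", ch)]] <- stats::rlnorm(n, 0, params$noise_sigma_log)
  }

  if (params$scenario != "growth") {
    pop <- apply_scenario(pop, params)
  }

  structure(pop, params = params, class = c("cc_population", class(pop)))
}

# Overrides the arrested subset of a base growth population with the
# qualitative signal pattern of the perturbation.
apply_scenario <- function(pop, params) {
  n <- nrow(pop)
  n_arrest <- round(params$arrest_fraction * n)
  idx <- sort(sample.int(n, n_arrest))
  if (n_arrest == 0) return(pop)

  b <- phase_boundaries(params)
  g1_end <- b[["G1_high"]]
  d_s <- params$phase_durations_h[["S"]]
  gm <- growth_channel_means(params)
  a0 <- min(params$mcm_ramp_start_h, g1_end)
  k <- length(idx)

  g1_ages <- stats::runif(k, 0, max(g1_end, 1e-9) * (1 - 1e-12))
  sc <- params$scenario
  age <- switch(sc,
    confluent = ,
    set8_sirna = ,
    suv420h1_sirna = ,
    palbociclib_150nm = g1_ages,
    palbociclib_1um = stats::runif(k, 0, max(a0, 1e-9) * (1 - 1e-12)),
    hydroxyurea = g1_end + stats::runif(k, 0, 0.05) * d_s)

  pop$age_h[idx] <- age
  pop$phase[idx] <- phase_at(age, params)
  pop$dna_content[idx] <- dna_content_at(age, params)
  pop$arrested[idx] <- TRUE
  sig <- marker_totals_at(age, params)
  for (ch in names(sig)) pop[[ch]][idx] <- sig[[ch]]

  mcm_override <- switch(sc,
    confluent = gm[["mcm3"]] * 2^stats::runif(k, -4.5, -0.5),
    set8_sirna = rep(params$mcm_curve[["g1s_peak"]], k),
    suv420h1_sirna = ,
    palbociclib_1um = rep(params$mcm_curve[["early_plateau"]], k),
    NULL)
  if (!is.null(mcm_override)) {
    pop$sig_mcm2[idx] <- mcm_override
    pop$sig_mcm3[idx] <- mcm_override
  }
  me1_override <- switch(sc,
    confluent = gm[["h4k20me1"]] * 2^stats::runif(k, -3, 0),
    set8_sirna = gm[["h4k20me1"]] * 2^stats::runif(k, -6, -4),
    suv420h1_sirna = rep(params$h4k20_curve[["me1_peak"]], k),
    NULL)
  if (!is.null(me1_override)) pop$sig_h4k20me1[idx] <- me1_override
  if (sc == "suv420h1_sirna") {
    pop$sig_h4k20me2[idx] <- params$h4k20_curve[["me23_floor"]]
    pop$sig_h4k20me3[idx] <- params$h4k20_curve[["me23_floor"]]
  }
  pop
}

#' Apply an EdU pulse to a population
#'
#' Each cell incorporates label at `edu_rate` for the time it spends in S
#' phase during the window `[age, age + pulse_h]`; cells never in S during the
#' window stay unlabeled.  Arrested cells do not progress: G1-arrested cells
#' incorporate nothing, S-arrested (hydroxyurea) cells incorporate for the
#' whole pulse.
#'
#' @param population A `cc_population`.
#' @param pulse_h Pulse length in hours (> 0); the experiments emulated here
#'   use a 30-min (0.5 h) pulse.
#' @param window `"forward"`: the window is `[age, age + pulse_h]` (label the
#'   cohort at pulse start, then chase).  `"centered"`: the window is
#'   `[age - pulse_h/2, age + pulse_h/2]`, i.e. the recorded ages time-stamp
#'   the middle of the pulse; used for fixed-at-pulse-end samples, where it
#'   makes the labeling smear symmetric between the phases flanking S.
#' @return The population with `edu_label` (and the EdU channel total
#'   `sig_edu`) updated.
#' @export
apply_pulse_edu <- function(population, pulse_h,
                            window = c("forward", "centered")) {
  params <- attr(population, "params")
  stopifnot(inherits(population, "cc_population"), !is.null(params))
  if (pulse_h <= 0) stop("`pulse_h` must be positive")
  window <- match.arg(window)

  b <- phase_boundaries(params)
  s0 <- b[["G1_high"]]
  s1 <- b[["S"]]
  t_total <- params$total_cycle_h
  a <- population$age_h
  lo <- if (window == "forward") a else a - pulse_h / 2
  hi <- lo + pulse_h
  w1 <- pmax(pmin(hi, s1) - pmax(lo, s0), 0)
  # wrap across division in either direction (relevant when S borders the
  # cycle ends)
  w_next <- pmax(pmin(hi - t_total, s1) - s0, 0)
  w_prev <- pmax(pmin(hi, s1 - t_total) - pmax(lo, s0 - t_total), 0)
  overlap <- w1 + w_next + w_prev
  overlap[population$arrested] <-
    ifelse(population$phase[population$arrested] == "S", pulse_h, 0)

  population$edu_label <- population$edu_label + params$edu_rate * overlap
  population$sig_edu <- population$edu_label
  population
}

#' Advance a population through a chase period
#'
#' Ages every cycling cell by `dt_h`; cells crossing the end of the cycle
#' divide, and both daughters are retained: DNA content resets to 1, the EdU
#' label halves per division, `generation` increments, and the marker totals
#' are recomputed from the new age.  Daughters inherit the staining factors of
#' their mother.  Arrested cells do not advance.
#'
#' @param population A `cc_population`.
#' @param dt_h Chase duration in hours (>= 0; 0 is the identity).
#' @return The advanced population (possibly with more rows than the input).
#' @export
advance_chase <- function(population, dt_h) {
  params <- attr(population, "params")
  stopifnot(inherits(population, "cc_population"), !is.null(params))
  if (dt_h < 0) stop("`dt_h` must be >= 0")
  if (dt_h == 0) return(population)

  t_total <- params$total_cycle_h
  cyc <- !population$arrested
  raw <- population$age_h + ifelse(cyc, dt_h, 0)
  ndiv <- ifelse(cyc, raw %/% t_total, 0)
  new_age <- ifelse(cyc, raw %% t_total, population$age_h)

  pop <- population
  pop$age_h <- new_age
  pop$generation <- pop$generation + as.integer(ndiv)
  pop$edu_label <- pop$edu_label / 2^ndiv

  rep_idx <- rep.int(seq_len(nrow(pop)), 2^ndiv)
  pop <- pop[rep_idx, ]
  pop$cell_id <- seq_len(nrow(pop))

  upd <- !pop$arrested
  pop$phase[upd] <- phase_at(pop$age_h[upd], params)
  pop$dna_content[upd] <- dna_content_at(pop$age_h[upd], params)
  sig <- marker_totals_at(pop$age_h[upd], params)
  for (ch in names(sig)) pop[[ch]][upd] <- sig[[ch]]
  pop$sig_edu <- pop$edu_label
  structure(pop, params = params, class = class(population))
}
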