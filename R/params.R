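#' Parameters of a simulated cell population
#'
#' Bundles the cell-cycle structure and marker dynamics of a synthetic
#' population: phase durations, piecewise-linear marker curves (chromatin-bound
#' MCM, H4K20 methylation states, Cdt1), EdU incorporation rate, staining
#' noise, and the biological scenario the population emulates.
#'
#' Phase durations may be zero (degenerate occupancy) but not negative, and
#' must sum to `total_cycle_h`.  All amplitudes are arbitrary fluorescence
#' units ("a.u.", camera counts after rendering).
#'
#' The default MCM amplitudes and ramp start are calibrated so that, for an
#' asynchronous population with the default durations and staining noise, the
#' hTERT-RPE1 low/high-MCM gate (log2 = 0.5 relative to the analyzed-
#' population mean) splits G1 exactly at the `G1_low`/`G1_high` boundary
#' (unbiased low-MCM occupancy); see the methods vignette for the
#' calibration.
#'
#' @param total_cycle_h Total cell-cycle length T in hours.
#' @param phase_durations_h Named numeric: hours spent in `G1_low`, `G1_high`,
#'   `S`, `G2`, `M`; non-negative, summing to `total_cycle_h`.
#' @param n_cells Number of cells to simulate.
#' @param mcm_curve Named numeric `early_plateau`, `g1s_peak`, `g2_floor`
#'   (a.u.): chromatin-bound MCM total per nucleus on the early-G1 plateau, at
#'   the G1/S peak, and on the G2 floor.
#' @param mcm_ramp_start_h Hour (within G1) at which the MCM loading ramp
#'   towards the G1/S peak begins.
#' @param h4k20_curve Named numeric `me1_peak`, `me1_floor`, `me23_floor`,
#'   `me23_peak` (a.u.): H4K20me1 declines from `me1_peak` (start of G1) to
#'   `me1_floor` (G1/S); H4K20me2/3 rises complementarily.
#' @param cdt1_curve Named numeric `g1_floor`, `g1s_peak`, `s_floor` (a.u.):
#'   Cdt1 rises through G1 and is degraded at S entry.
#' @param hoechst_unit Hoechst total per 1x genome equivalent (a.u.).
#' @param edu_rate EdU incorporated per hour of S-phase synthesis (a.u./h).
#' @param noise_sigma_log SD (natural-log scale) of the multiplicative
#'   log-normal cell-to-cell staining noise on marker channels.
#' @param dna_noise_sigma_log SD (natural-log scale) of the multiplicative
#'   noise on the Hoechst/DNA channel; DNA-content CVs of image cytometry are
#'   far tighter than antibody staining CVs.
#' @param soluble_mcm_pool Soluble (chromatin-unbound) MCM per cell (a.u.),
#'   added to the MCM channels when rendering with direct fixation.
#' @param age_distribution `"uniform"` (occupancy proportional to duration, the
#'   assumption of the duration estimator) or `"exponential_growth"`
#'   (demographic age density (2 log 2 / T) 2^(-a/T)).
#' @param age_sampling `"stratified"` (seeded systematic sample of the age
#'   distribution, so occupancy matches durations at any n) or `"iid"`.
#' @param scenario One of `"growth"`, `"confluent"`, `"set8_sirna"`,
#'   `"suv420h1_sirna"`, `"palbociclib_1um"`, `"palbociclib_150nm"`,
#'   `"hydroxyurea"`.
#' @param arrest_fraction Fraction of cells actually arrested in the
#'   non-growth scenarios; the remainder keep cycling (escapers).
#' @param seed Integer seed; every randomized step is deterministic given it.
#'
#' @return A list of class `cc_population_params`.
#' @export
population_params <- function(total_cycle_h = 22.5,
                              phase_durations_h = c(G1_low = 8.1, G1_high = 3.0,
                                                    S = 7.9, G2 = 2.5, M = 1.0),
                              n_cells = 400,
                              mcm_curve = c(early_plateau = 70000,
                                            g1s_peak = 320000,
                                            g2_floor = 30000),
                              mcm_ramp_start_h = 4.55,
                              h4k20_curve = c(me1_peak = 150000,
                                              me1_floor = 40000,
                                              me23_floor = 30000,
                                              me23_peak = 120000),
                              cdt1_curve = c(g1_floor = 20000,
                                             g1s_peak = 300000,
                                             s_floor = 10000),
                              hoechst_unit = 50000,
                              edu_rate = 10000,
                              noise_sigma_log = 0.15,
                              dna_noise_sigma_log = 0.025,
                              soluble_mcm_pool = 250000,
                              age_distribution = c("uniform", "exponential_growth"),
                              age_sampling = c("stratified", "iid"),
                              scenario = c("growth", "confluent", "set8_sirna",
                                           "suv420h1_sirna", "palbociclib_1um",
                                           "palbociclib_150nm", "hydroxyurea"),
                              arrest_fraction = 0.95,
                              seed = 1L) {
  age_distribution <- match.arg(age_distribution)
  age_sampling <- match.arg(age_sampling)
  scenario <- match.arg(scenario)

  req <- c("G1_low", "G1_high", "S", "G2", "M")
  if (!all(req %in% names(phase_durations_h))) {
    stop("`phase_durations_h` must name all of: ", paste(req, collapse = ", "))
  }
  phase_durations_h <- phase_durations_h[req]
  if (any(phase_durations_h < 0)) {
    stop("phase durations must be non-negative")
  }
  if (abs(sum(phase_durations_h) - total_cycle_h) > 1e-8 * max(1, total_cycle_h)) {
    stop("phase durations must sum to `total_cycle_h` (",
         sum(phase_durations_h), " != ", total_cycle_h, ")")
  }
  if (total_cycle_h <= 0) stop("`total_cycle_h` must be positive")
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (noise_sigma_log < 0 || dna_noise_sigma_log < 0) {
    stop("noise sigmas must be >= 0")
  }
  if (any(c(mcm_curve, h4k20_curve, cdt1_curve, hoechst_unit,
            edu_rate, soluble_mcm_pool) < 0)) {
    stop("curve amplitudes must be >= 0")
  }
  if (arrest_fraction < 0 || arrest_fraction > 1) {
    stop("`arrest_fraction` must be in [0, 1]")
  }

  structure(list(
    total_cycle_h = total_cycle_h,
    phase_durations_h = phase_durations_h,
    n_cells = as.integer(n_cells),
    mcm_curve = mcm_curve,
    mcm_ramp_start_h = mcm_ramp_start_h,
    h4k20_curve = h4k20_curve,
    cdt1_curve = cdt1_curve,
    hoechst_unit = hoechst_unit,
    edu_rate = edu_rate,
    noise_sigma_log = noise_sigma_log,
    dna_noise_sigma_log = dna_noise_sigma_log,
    soluble_mcm_pool = soluble_mcm_pool,
    age_distribution = age_distribution,
    age_sampling = age_sampling,
    scenario = scenario,
    arrest_fraction = arrest_fraction,
    seed = as.integer(seed)
  ), class = "cc_population_params")
}

#' Parameters of the image renderer
#'
#' @param image_shape Integer `(rows, cols)` in pixels, or `NULL` to size the
#'   image automatically from the population.
#' @param nucleus_radius_px Named numeric `mean`, `sd`: base nucleus radius in
#'   pixels for a 1x genome equivalent.  The drawn radius additionally scales
#'   with `dna_content^(1/3)` (nuclear volume tracks genome content; projected
#'   area then scales as `dna^(2/3)`).
#' @param min_separation_px Minimum gap in pixels between nucleus borders.
#' @param background_level Camera background offset per channel (a.u.); a
#'   single value is recycled across channels.
#' @param read_noise_sigma SD of the additive Gaussian pixel read noise (a.u.).
#' @param m_phase_shrink_factor Area factor (< 1) applied to M-phase cells:
#'   condensed chromosomes occupy a smaller, proportionally brighter footprint.
#' @param seed Integer seed for placement and pixel noise.
#'
#' @return A list of class `cc_render_params`.
#' @export
render_params <- function(image_shape = NULL,
                          nucleus_radius_px = c(mean = 9, sd = 0.5),
                          min_separation_px = 4,
                          background_level = 50,
                          read_noise_sigma = 2,
                          m_phase_shrink_factor = 0.4,
                          seed = 1L) {
  if (!is.null(image_shape)) {
    stopifnot(length(image_shape) == 2, all(image_shape >= 8))
  }
  stopifnot(all(c("mean", "sd") %in% names(nucleus_radius_px)),
            nucleus_radius_px[["mean"]] > 0, nucleus_radius_px[["sd"]] >= 0)
  if (any(background_level < 0)) stop("`background_level` must be >= 0")
  if (read_noise_sigma < 0) stop("`read_noise_sigma` must be >= 0")
  if (m_phase_shrink_factor <= 0 || m_phase_shrink_factor >= 1) {
    stop("`m_phase_shrink_factor` must be in (0, 1)")
  }
  structure(list(
    image_shape = if (is.null(image_shape)) NULL else as.integer(image_shape),
    nucleus_radius_px = nucleus_radius_px,
    min_separation_px = min_separation_px,
    background_level = background_level,
    read_noise_sigma = read_noise_sigma,
    m_phase_shrink_factor = m_phase_shrink_factor,
    seed = as.integer(seed)
  ), class = "cc_render_params")
}

#' Analysis configuration
#'
#' Collects the knobs of the measurement-to-record pipeline: segmentation area
#' limits, M-phase exclusion heuristics, normalization parameters, channel
#' roles and the gating configuration.
#'
#' @param gating A [gating_config()].
#' @param k Order-statistic rank anchoring the Hoechst scale: the k-th lowest
#'   and k-th highest Hoechst sums map to 1 and 2.  The extreme nuclei
#'   themselves are often outliers, hence an interior rank.
#' @param floor_log2 Clamp for log2 mean-relative values (keeps EdU-negative,
#'   zero-sum nuclei finite and below every printed gate).
#' @param min_area_px,max_area_px Connected components outside this area range
#'   are discarded as debris/clumps.
#' @param m_area_quantile,m_hoechst_factor M-phase exclusion heuristic: flag
#'   objects below this area quantile whose mean Hoechst exceeds
#'   `m_hoechst_factor` times the population median (condensed chromosomes are
#'   small and bright).
#' @param mcm_channel,edu_channel Channel names carrying the MCM marker used
#'   for the low/high G1 split and the EdU signal used for S gating.
#' @param subsample_n,subsample_seed Fixed-N plotting sample (panels in this
#'   workflow show 400-450 cells); normalization and gating always run on the
#'   full non-M population before sampling.
#' @return A list of class `cc_analysis_config`.
#' @export
analysis_config <- function(gating = gating_config(),
                            k = 10L,
                            floor_log2 = -10,
                            min_area_px = 50,
                            max_area_px = 2500,
                            m_area_quantile = 0.1,
                            m_hoechst_factor = 1.8,
                            mcm_channel = "mcm3",
                            edu_channel = "edu",
                            subsample_n = 400L,
                            subsample_seed = 1L) {
  stopifnot(k >= 1, min_area_px < max_area_px,
            m_area_quantile > 0, m_area_quantile < 1, m_hoechst_factor > 0)
  structure(list(
    gating = gating, k = as.integer(k), floor_log2 = floor_log2,
    min_area_px = min_area_px, max_area_px = max_area_px,
    m_area_quantile = m_area_quantile, m_hoechst_factor = m_hoechst_factor,
    mcm_channel = mcm_channel, edu_channel = edu_channel,
    subsample_n = as.integer(subsample_n),
    subsample_seed = as.integer(subsample_seed)
  ), class = "cc_analysis_config")
}

#' Read/write an analysis configuration as YAML
#'
#' @param config An object created by [analysis_config()].
#' @param path File path.
#' @return `write_analysis_config` returns `path` invisibly;
#'   `read_analysis_config` returns a `cc_analysis_config`.
#' @export
write_analysis_config <- function(config, path) {
  stopifnot(inherits(config, "cc_analysis_config"))
  x <- unclass(config)
  x$gating <- unclass(x$gating)
  x$gating$named_gates <- lapply(x$gating$named_gates, as.data.frame)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_analysis_config
#' @export
read_analysis_config <- function(path) {
  x <- yaml::read_yaml(path)
  gates <- lapply(x$gating$named_gates, function(g) {
    tibble::tibble(channel = as.character(unlist(g$channel)),
                   cmp = as.character(unlist(g$cmp)),
                   threshold = as.numeric(unlist(g$threshold)))
  })
  g <- x$gating
  gating <- gating_config(cell_line = g$cell_line,
                          mcm_high_log2 = g$mcm_high_log2,
                          hoechst_g1_max = g$hoechst_g1_max,
                          hoechst_g2_min = g$hoechst_g2_min,
                          log2_edu_s_min = g$log2_edu_s_min,
                          named_gates = gates)
  analysis_config(gating = gating, k = x$k, floor_log2 = x$floor_log2,
                  min_area_px = x$min_area_px, max_area_px = x$max_area_px,
                  m_area_quantile = x$m_area_quantile,
                  m_hoechst_factor = x$m_hoechst_factor,
                  mcm_channel = x$mcm_channel, edu_channel = x$edu_channel,
                  subsample_n = x$subsample_n, subsample_seed = x$subsample_seed)
}
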