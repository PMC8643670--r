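#!/usr/bin/env Rscript
# G1/S-arrest scenarios: confluent contact inhibition, Set8 and Suv420h1
# knockdowns, palbociclib, and hydroxyurea, each analyzed against a
# growth-phase control batch (control-referenced normalization, as in
# control-siRNA experiments).

suppressMessages(library(cytocycle))

out_dir <- "results"
chans <- c("hoechst", "edu", "mcm2", "h4k20me1", "h4k20me2")
cfg <- analysis_config(mcm_channel = "mcm2")

ctrl <- run_simulated_experiment(population_params(n_cells = 400, seed = 108),
                                 render_params(seed = 109), cfg,
                                 channels = chans)

scenarios <- c("confluent", "set8_sirna", "suv420h1_sirna",
               "palbociclib_1um", "palbociclib_150nm", "hydroxyurea")
rows <- list()
for (sc in scenarios) {
  res <- run_simulated_experiment(
    population_params(n_cells = 400, seed = 110, scenario = sc),
    render_params(seed = 111), cfg, channels = chans,
    reference = ctrl$analysis)
  r <- res$analysis$records
  rows[[sc]] <- data.frame(
    scenario = sc,
    g1_pct = round(100 * mean(r$phase == "G1"), 1),
    edu_pos_pct = round(100 * mean(r$edu > -3), 1),
    mcm2_high_pct = round(100 * mean(r$mcm2 > -0.5), 1),
    me1_depleted_pct = round(100 * mean(r$h4k20me1 < -3), 1),
    median_hoechst = round(stats::median(r$hoechst_norm), 2))
  if (sc == "set8_sirna") {
    p <- plot_single_cell(r, "h4k20me1", overlay = c(edu_positive = "orange"))
    ggplot2::ggsave(file.path(out_dir, "set8_h4k20me1.png"), p,
                    width = 4, height = 3.2, dpi = 150)
  }
}
tab <- do.call(rbind, rows)
print(tab, row.names = FALSE)
utils::write.csv(tab, file.path(out_dir, "arrest_scenarios.csv"),
                 row.names = FALSE)

cat("\nConfluent and Suv420h1/palbociclib arrests hold G1 cells at low-to-\n")
cat("moderate chromatin MCM (single-hexamer-like), while Set8 knockdown\n")
cat("arrests G1 cells at peak MCM with H4K20me1 depleted below -3; the\n")
cat("hydroxyurea arrest is EdU-positive at early-S DNA content.\n")
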