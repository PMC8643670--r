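#!/usr/bin/env Rscript
# Estimate per-phase durations: fit the doubling time from a growth curve,
# convert gated cell counts into hours per phase, and compare the recovered
# durations with the simulator's ground truth.

suppressMessages(library(cytocycle))

out_dir <- "results"

# doubling time from a 5-day growth curve (counts every 24 h)
gc <- simulate_growth_curve(22.5, times_h = seq(0, 120, 24), n0 = 5e3,
                            noise_sigma_log = 0.02, seed = 103)
utils::write.csv(gc, file.path(out_dir, "growth_curve.csv"), row.names = FALSE)
fit <- fit_doubling_time(gc)
print(fit)

# gated counts from the full experiment at a denser n for stable fractions
res <- run_simulated_experiment(population_params(n_cells = 2000, seed = 104),
                                render_params(seed = 105))
counts <- phase_counts(res$analysis)
dur <- estimate_phase_durations(counts, fit$doubling_time_h)
print(dur)

truth <- c(G1_low = 8.1, G1_high = 3.0, S = 7.9, G2 = 2.5, M = 1.0)
comp <- data.frame(phase = names(truth), truth_h = unname(truth),
                   estimated_h = round(unname(dur$durations_h[names(truth)]), 2))
comp$rel_error_pct <- round(100 * (comp$estimated_h / comp$truth_h - 1), 1)
print(comp, row.names = FALSE)
utils::write.csv(comp, file.path(out_dir, "phase_durations.csv"),
                 row.names = FALSE)
jsonlite::write_json(
  list(doubling_time_h = fit$doubling_time_h,
       counts = as.list(counts),
       durations_h = as.list(round(dur$durations_h, 3))),
  file.path(out_dir, "phase_durations.json"), auto_unbox = TRUE, digits = NA)

ggplot2::ggsave(file.path(out_dir, "phase_durations.png"),
                plot_phase_durations(dur), width = 4.5, height = 3, dpi = 150)
cat("The low-MCM G1 state is the longest G1 segment; its duration tracks the\n")
cat("printed 8-9 h range for fast-cycling lines at this doubling time.\n")
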