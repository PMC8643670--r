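#!/usr/bin/env Rscript
# Pulse-chase time course: label S-phase cells with a 30-min EdU pulse at
# 0 h, chase up to 24 h, and follow the labeled cohort (the orange dots)
# through G2/M into G1 and back into S.

suppressMessages(library(cytocycle))

out_dir <- "results"
pc <- run_pulse_chase(population_params(n_cells = 450, seed = 106),
                      render_params(seed = 107),
                      chase_h = c(0, 4, 8, 12, 16, 20, 24))
utils::write.csv(pc$cohort, file.path(out_dir, "pulse_chase_cohort.csv"),
                 row.names = FALSE)
w <- tidyr::pivot_wider(pc$cohort[, c("chase_h", "phase", "fraction")],
                        names_from = phase, values_from = fraction)
cat("Labeled-cohort phase fractions by chase time (DNA-content bands after 0 h):\n")
print(as.data.frame(round(w, 3)), row.names = FALSE)

modal <- vapply(split(pc$cohort, pc$cohort$chase_h),
                function(d) d$phase[which.max(d$fraction)], "")
cat("\nModal cohort phase over the chase:",
    paste(sprintf("%sh:%s", names(modal), modal), collapse = "  "), "\n")
cat("The cohort moves S -> G2 -> G1, re-enters S around 16-20 h, and by\n")
cat("~24 h sits back at mid-range DNA content like the 0 h pattern,\n")
cat("consistent with a ~22.5 h doubling time.\n")

# the 8-h panel marks early-G1 cells: the MCM level of the labeled cohort
# there anchors the low/high-MCM threshold
an8 <- pc$analyses[["8"]]
cohort_mcm <- an8$records$mcm3[an8$cohort_mask & an8$records$phase == "G1"]
cat(sprintf("\n8-h cohort (early G1): median log2(Mcm3) = %.2f (threshold 0.5)\n",
            stats::median(cohort_mcm)))

for (t in c(0, 8, 16)) {
  an <- pc$analyses[[as.character(t)]]
  rec <- an$records
  rec$orange <- an$cohort_mask
  p <- plot_single_cell(rec, "mcm3", overlay = c(edu_positive = "orange"))
  ggplot2::ggsave(file.path(out_dir, sprintf("pulse_chase_mcm3_%02dh.png", t)),
                  p, width = 4, height = 3.2, dpi = 150)
}
cat("Wrote pulse_chase_cohort.csv and Mcm3 panels at 0/8/16 h.\n")
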