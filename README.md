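# cytocycle

Single-cell plot analysis of cell-cycle marker dynamics from multicolor
immunofluorescence images, in R.

## The problem

Chromatin loading of the replicative MCM helicase (Mcm2–7), histone H4K20
methylation states, and DNA synthesis can all be read out per nucleus from
multichannel fluorescence images. *Single-cell plot analysis* turns such
images into per-cell scatter plots — each nucleus's marker intensity against
its DNA content — and uses printed threshold gates to define cell-cycle
subpopulations. Combined with a growth-curve doubling time, the gated counts
become per-phase durations:

- **Measurement.** Nuclei are segmented by automatic (Otsu) thresholding of
  the Hoechst channel after background subtraction; for every nucleus and
  channel the *sum intensity* (mean intensity × nuclear area) is recorded.
  M-phase figures (condensed chromosomes: small, bright) are excluded.
- **Scales.** Hoechst sums are mapped affinely so that the 10th-lowest and
  10th-highest nuclei sit at 1 and 2 (G1 and G2 DNA content); every other
  channel is divided by its population mean and plotted on log2.
- **Gates.** G1: Hoechst < 1.125 and log2(EdU) < −3; S: log2(EdU) > −3;
  G2: Hoechst > 1.7 and log2(EdU) < −3. G1 is subdivided into *low-* and
  *high-MCM* states at a per-cell-line log2(MCM) threshold (0.5 for
  hTERT-RPE1; 0.3 HeLa; 0.7 U2OS; 1.0 MRC5; 1.5 IMR90).
- **Durations.** duration(phase) = count(phase) / total × T, with T the
  doubling time fitted by least squares on log2 counts.

Because no raw micrographs are available to rerun, the package ships a fully
seeded synthetic image-cytometry generator — per-phase DNA content, EdU
pulse-chase with cohort tracking through divisions, piecewise-linear
chromatin-MCM / H4K20me1/me2/3 / Cdt1 dynamics, pre-extraction vs direct
fixation, and arrest scenarios (confluent, Set8/Suv420h1 siRNA, palbociclib,
hydroxyurea) — so every pipeline stage is verifiable against ground truth.
It is intended for methodologists who want a tested reference implementation
of the analysis, and for benchmarking gating/duration estimators against
known truth.

## Worked example

Simulate a 450-cell asynchronous population with hTERT-RPE1-like phase
structure (G1_low 8.1, G1_high 3.0, S 7.9, G2 2.5, M 1.0 h; T = 22.5 h),
pulse 30 min of EdU, render, and run the measurement pipeline:

```r
library(cytocycle)
res <- run_simulated_experiment(population_params(n_cells = 2000, seed = 104),
                                render_params(seed = 105))
print(res$durations)
```

```
Phase durations (T = 22.50 h, n = 2000):
  G1_low         710 cells   35.5%    7.99 h
  G1_high        255 cells   12.8%    2.87 h
  S              742 cells   37.1%    8.35 h
  G2             202 cells   10.1%    2.27 h
  M               89 cells    4.5%    1.00 h
  unclassified     2 cells    0.1%  (no duration)
```

The recovered durations sit within ±10% of the generator's truth; the
residual biases on the phases flanking S are a property of the estimator
itself (a 30-min pulse labels cells that leave or enter S during it; see the
methods vignette). The low-MCM G1 duration, 36% × 22.5 h ≈ 8 h, is the
longest G1 segment — the "halting" state of G1 progression.

The numbered scripts under `analysis/` narrate the full workflow and write
tables/figures under `results/`:

```sh
Rscript analysis/01_simulate_growth.R     # population + TIFF stack + truth
Rscript analysis/02_quantify_and_gate.R   # nuclei, records, single-cell plots
Rscript analysis/03_phase_durations.R     # doubling time + duration table
Rscript analysis/04_pulse_chase.R         # 0-24 h cohort tracking
Rscript analysis/05_arrest_scenarios.R    # G1/S-arrest gate signatures
```

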