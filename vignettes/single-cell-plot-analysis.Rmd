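---
title: "Single-cell plot analysis: model, simulator design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell plot analysis: model, simulator design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cytocycle)
```

This vignette is the package's account of the science it implements: the
measurement model of single-cell plot analysis, what the synthetic generator
emulates (and deliberately does not), how its defaults were calibrated, and
the numerical conventions that make the pipeline deterministic and testable.

## The measurement model

One multichannel field yields, per nucleus, a vector of *sum intensities*
(mean background-subtracted intensity × nuclear area), one per channel.
Two scales make these comparable across cells and experiments:

* **DNA content (linear).** Hoechst sums are mapped affinely so the
  k-th-smallest sum is 1 and the k-th-largest is 2 (`k = 10` by default):
  G1 cells land near 1, G2 near 2, S in between. An interior rank is used
  because the single most extreme nuclei are often debris, doublets, or
  apoptotic. Values beyond the anchors are *not* clipped; the map is
  strictly monotone and invariant to rescaling all sums by a constant.
* **log2 mean-relative (markers).** Each other channel is divided by its
  arithmetic population mean, then log2-transformed. Ratios below
  `2^-10` are clamped to −10 so that genuinely zero nuclei (EdU-negative
  cells) stay finite and far below every gate in use.

Phases come from printed, strict-inequality gates: S is log2(EdU) > −3 at
any DNA content; G1 is Hoechst < 1.125 and EdU-negative; G2 is
Hoechst > 1.7 and EdU-negative. The three gates are mutually exclusive by
construction; EdU-negative cells in the 1.125–1.7 band are *unclassified*
and kept in all totals. G1 is subdivided at a per-cell-line log2(MCM)
threshold into low- and high-MCM states; a value exactly at a threshold
satisfies neither strict inequality, so boundary cells fall to
"unclassified" (phases) or "low" (MCM split). M-phase figures are excluded
before any normalization, because condensed chromosomes have a much smaller
area than interphase nuclei and their sums are not comparable; their count
is retained for the duration estimator.

Durations follow from occupancy: for a population in steady state observed
at a random time, the expected fraction of cells in a phase equals that
phase's share of the cycle, so
`duration = count / total × T`, with `T` the doubling time fitted by
ordinary least squares on log2 cell counts over time. Unclassified cells
stay in the denominator and receive no duration (the conservative reading
of "ratio over the total number of cells"); durations then under-sum `T`
exactly by the unclassified mass. `unclassified = "redistribute"` is
available for sensitivity analysis.

## What the generator emulates

`simulate_population()` draws cells on a cycle of five consecutive phases
(`G1_low`, `G1_high`, `S`, `G2`, `M`) with configurable durations (defaults
8.1, 3.0, 7.9, 2.5, 1.0 h; T = 22.5 h, an hTERT-RPE1-like structure).

**Ages.** The duration estimator *assumes* occupancy ∝ duration, i.e. a
uniform age distribution, so uniform is the default. Uniform ages are drawn
by a seeded stratified (systematic) scheme: occupancy then matches the
durations at any population size, so pipeline verification isolates
measurement error from demographic sampling noise; `age_sampling = "iid"`
gives ordinary binomial sampling. A demographically realistic alternative,
`age_distribution = "exponential_growth"` (density `(2 ln 2 / T) 2^(-a/T)`),
over-represents young cells; the estimator's resulting over-count of
early-cycle phases is reproduced and tested as a property, not corrected —
it is a bias of the estimator itself.

**DNA content** is 1 through G1, linear 1→2 across S, 2 through G2/M,
continuous at boundaries.

**Marker curves** are piecewise-linear in age — the minimal shape consistent
with the qualitative dynamics they emulate:

* *Chromatin-bound MCM* (both `mcm2` and `mcm3`): an early-G1 plateau
  (70,000 a.u.), a linear loading ramp beginning at `mcm_ramp_start_h`
  (4.55 h) to a G1/S peak (320,000), linear unloading across S to a G2
  floor (30,000), flat through G2/M.
* *H4K20me1* declines linearly from its peak at the start of G1 (150,000)
  to a floor at G1/S (40,000), flat after; *H4K20me2/3* rises
  complementarily (30,000 → 120,000). Early-G1 cells are thus me1-high and
  late-G1 cells me2/3-high.
* *Cdt1* rises through G1 (20,000 → 300,000) and drops to a low S-phase
  level (10,000) at S entry (degradation at the G1/S transition).
* *Hoechst* is 50,000 × DNA content; *EdU* is whatever the pulse deposited.

**Calibration of the MCM defaults.** The low/high-MCM boundary is
operationally *defined* by the printed threshold (log2 = 0.5 for the
default cell line), so the curve must cross the threshold's intensity value
exactly at the `G1_low`/`G1_high` boundary — otherwise the gate would
systematically misassign early-`G1_high` cells and bias the headline
low-MCM duration. Two noise effects move the effective crossing and were
included in the calibration: mean-normalization under multiplicative
log-normal noise raises the divisor by `exp(sigma^2/2)` (Jensen), and the
concavity of log2(curve) in age makes symmetric intensity noise flip more
cells downward than upward. The ramp start 4.55 h makes the gated low/high
split unbiased under the default staining noise (verified at the truth
level on 8×10^5 cells); the same calibration is what the paper-gap note in
the parameter documentation refers to.

**Noise model.** Each cell carries persistent multiplicative log-normal
staining factors, one per marker channel (`noise_sigma_log = 0.15`,
a ~15% CV typical of immunofluorescence staining) and a much tighter factor
on the Hoechst channel (`dna_noise_sigma_log = 0.025`; DNA-content CVs of
good image cytometry are a few percent — with a broader DNA noise the
printed 1.125/1.7 gates could not work for any method). Factors persist
through a chase and are inherited by daughters (clonal staining
propensity), which keeps `advance_chase()` deterministic. Additive
Gaussian read noise is applied per pixel at render time and rounded to
integer camera counts.

**EdU pulse.** `apply_pulse_edu()` deposits label at `edu_rate` (10,000
a.u./h) for the time the cell's window overlaps S. The default window is
forward (`[age, age + p]`): label the cohort at pulse start, then advance —
the natural composition for a chase series. For pulse-and-fix samples the
pipeline uses the *centered* window (`[age − p/2, age + p/2]`), i.e. the
recorded ages time-stamp the middle of the pulse. Midpoint time-stamping is
the standard convention for a finite labeling window: it splits the
unavoidable boundary smear symmetrically between the phases flanking S
instead of loading it all onto early G2.

**Division.** Cells crossing the end of the cycle divide; both daughters
are kept (the population grows), DNA content resets, the EdU label halves
per division, and marker levels are recomputed from the new age. Label mass
is conserved over a lineage. Arrested cells (below) neither advance nor
divide.

**Arrest scenarios** override the arrested subset (default
`arrest_fraction = 0.95`; the remainder keeps cycling, as real arrests are
never complete) with the qualitative pattern of the perturbation — G1
arrest with low-to-moderate MCM (confluent; log2 −4.5 to −0.5 against the
growth mean), G1 arrest at peak MCM with H4K20me1 depleted below −3
(Set8 knockdown), G1 arrest with me1 retained and me2/3 at floor
(Suv420h1 knockdown), early-G1 arrest on the MCM plateau (1 µM
palbociclib), heterogeneous G1 arrest (150 nM palbociclib), and an
EdU-positive early-S arrest (hydroxyurea). Only qualitatively stated
patterns are encoded; no kinetic rates are invented. Arrest analyses are
normalized against a growth-phase control batch — the control supplies both
the Hoechst anchors and the channel means — mirroring control-siRNA
normalization; this also avoids the degenerate case of anchoring a 1–2
DNA-content scale inside a population that is entirely G1.

**Rendering.** Each nucleus is a disk of integer camera counts whose pixel
sum equals the cell's (noise-factored) total signal *exactly*: every pixel
gets `floor(total/area)` counts and the remainder is spread one count per
pixel. Integer counts make the zero-noise measurement oracle exact and
TIFF round trips bit-faithful (16-bit pages). Nuclear radius is
`N(9, 0.5) × dna^(1/3)` px — volume tracks genome content, so projected
area scales as `dna^(2/3)` and per-pixel Hoechst brightness stays roughly
constant through interphase. M-phase cells keep their total but occupy
`m_phase_shrink_factor = 0.4` of their area, i.e. proportionally brighter —
which is precisely what the small-and-bright exclusion heuristic keys on.
Cells are placed on a seeded jittered grid whose pitch guarantees the
minimum border separation; requesting more cells than the grid holds is an
error that reports the achievable count. Direct fixation adds a soluble
MCM pool (250,000 a.u.) to the MCM channels of every cell, which shrinks
their relative cell-to-cell variation compared with pre-extraction — the
reason pre-extraction is the fixation of choice for chromatin-bound MCM.

## Known bias of the duration estimator

With a 30-min pulse and the printed EdU gate, a cell is EdU-positive
whenever its window overlap with S exceeds
`o* ≈ 0.125 × f_S × p ≈ 1.3 min` (the gate is 2^-3 of the population-mean
EdU, and the mean is ≈ `f_S × rate × p`). Cells that leave or enter S
within the pulse window therefore carry enough label to be gated S:
with the centered window, S annexes ≈ `p/2 − o*` ≈ 0.23 h from each
flanking phase. Relative to the default durations this is ≈ +6% on S and
≈ −8% / −9% on G1_high / G2 — *independent of noise*, because the smear is
set by the protocol (pulse length) and the gate, not by measurement error.
The parameter-recovery tests show exactly this signature; it should be kept
in mind when reading estimated S/G2 durations from any pulse-fix
experiment of this design. The only way to shrink it is a shorter pulse.

At chase times the EdU label marks the cohort rather than current
synthesis, so chase-time phases are read from DNA content alone
(`classify_phase_hoechst()`: G1 below 1.125, G2 above 1.7, mid band = S).

## Numerical conventions

* Coordinates are 0-based `(row, col)`; label 0 is background; connected
  components and hole filling come from EBImage (`bwlabel`, `fillHull`),
  Otsu from `EBImage::otsu` on a 256-level rescaling.
* Segmentation rejects thresholds that merely split unimodal background
  noise: the class-mean separation must exceed 6× the background-class SD
  (Gaussian noise splits reach only ~2–3×). A uniform image yields an
  empty label map with a warning, not an error.
* The background of the Hoechst channel is the median outside its own Otsu
  foreground; marker-channel backgrounds in the pipeline are the median
  outside the *segmented nuclei*, because a channel with almost no
  foreground of its own (EdU in an arrested population) gives Otsu nothing
  to cut and a ~1-count bias would otherwise accumulate over a nucleus
  area into a gate-crossing artifact.
* Per-nucleus means are clamped at ≥ 0 after background subtraction; sums
  are stored as mean × area, so `sum = mean × area` holds exactly as
  stored.
* The M-phase heuristic flags objects below the 0.1 area quantile whose
  mean Hoechst exceeds 1.8× the population median; both knobs are exposed,
  and simulated scenes carry ground-truth M flags for audit.
* Normalization always runs on all non-M nuclei of a batch *before* the
  fixed-N plotting subsample (400–450 cells), so no result depends on the
  sampling seed.
* Every random step (ages, noise factors, placement, read noise,
  subsampling) is governed by an explicit integer seed; identical
  parameters and seed give bit-identical populations, images and tables.

## Verification sizes

The test suite verifies the full pipeline
(simulate → pulse → render → segment → measure → normalize → gate →
estimate) at 5,000 cells under default and zero noise; the rendering/
segmentation oracle on 50 seeded noise-free scenes of 8–20 cells;
normalization against brute-force order-statistic and arithmetic oracles on
100 random vectors; gating against clause-by-clause brute force on 10^4
random records; occupancy against a χ² goodness-of-fit at 10^5 iid cells;
and doubling-time recovery over 200 noisy growth curves. These sizes were
chosen to keep each statistical check's sampling error well below the
tolerance it asserts.

## Limitations

* No optics: no point-spread function, 3D stacks, photobleaching, shading,
  or spectral bleed-through. Segmentation on real images is harder than on
  these renders.
* No declumping: touching nuclei are not split (no watershed); the
  generator enforces separation, and the measurement step would treat a
  real clump as one object (usually removed by the area filter).
* Marker curves are qualitative piecewise-linear shapes with calibrated
  amplitudes, not fitted kinetics; arrest presets encode stated patterns
  only. In particular no mechanistic model of MCM single→double hexamer
  assembly is attempted — the simulator reproduces *levels*, not rates.
* The duration estimator inherits the assumptions above: uniform ages
  (exponential-growth demography biases it), steady state, and the pulse
  smear. Passing tests on simulated data demonstrate the pipeline's
  correctness against its own model, not the fidelity of that model to any
  particular microscope or cell line.
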