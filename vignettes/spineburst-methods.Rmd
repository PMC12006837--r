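---
title: "Quantifying hippocampal plasticity readouts with spineburst"
author: "spineburst maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hippocampal plasticity readouts with spineburst}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineburst)
```

# Scope

Hippocampal slice studies of NMDA-receptor-dependent plasticity typically
read out the same experiment through several complementary channels:
extracellular CA3 recordings scored for epileptiform bursts, two-photon
time-lapse imaging of dendritic spine volume, CA1 field-potential slopes
summarized as LTD magnitude, bulk protein synthesis measured by
^35^S-methionine/cysteine incorporation, and behavioral audiogenic-seizure
incidence. `spineburst` implements each of these quantification chains as
tested, reusable code, together with a synthetic-data generator that
produces inputs with known ground truth so every stage can be validated
without access to raw recordings.

This vignette explains the models and procedures, the parameters that
matter, the choices made where conventions were genuinely open, and what
the synthetic validation does and does not establish.

# Burst detection in CA3 extracellular recordings

The detector follows the standard interictal-event analysis chain:

1. **Filter and decimate.** The raw trace (typically 25 kHz) is band-pass
   filtered at 300--1000 Hz with a 4th-order Butterworth filter applied
   forward and backward (`signal::filtfilt`), then decimated by 10. The
   zero-phase application avoids skewing spike times; its cost is that the
   effective magnitude response is squared. Because the upper band edge
   (1000 Hz) lies below the decimated Nyquist frequency (1250 Hz at
   2.5 kHz), the band-pass itself provides the anti-aliasing. Filtering
   before decimation is therefore the only admissible order.
2. **Threshold spikes.** The spike threshold is `mad_factor` (default 5)
   times the MAD of the filtered trace, and spikes are counted at downward
   crossings of `median - threshold`, with a 2-ms refractory period to
   suppress multiple crossings within one waveform. Extracellular somatic
   spikes are negative-dominant, so only negative-going crossings count. By
   default the MAD carries the Gaussian-consistency constant 1.4826 (as in
   `stats::mad` and in the standard spike-detection practice of estimating
   the noise SD as `median(|x|)/0.6745`), placing the threshold at roughly
   5 SD of the noise. An unscaled MAD (`mad_constant = 1`) would sit at
   ~3.4 SD, where band-limited Gaussian noise alone crosses about once per
   second — enough, once binned, to contaminate the burst statistics of any
   quiet recording; `mad_constant = 1` remains available for comparison.
   A constant trace has MAD 0; that degenerate threshold yields no spikes
   and a warning rather than everything-is-a-spike behavior.
3. **Bin.** Spike times are summed over 100-ms half-open bins `[t, t+0.1)`,
   so a spike exactly on an edge belongs to the later bin.
4. **Sliding-window hysteresis.** A 500-ms window (5 bins) steps one bin at
   a time. A burst opens at the first window whose rate strictly exceeds
   8 Hz and persists through windows at or above 4 Hz; the first window
   strictly below 4 Hz terminates it. The strict inequalities mirror the
   verbs "exceeded" and "fell below"; a window at exactly 8 Hz does not
   open a burst.
5. **Event boundaries.** A window only localizes elevated activity to
   within half a window, so the raw window convention (onset = start of
   the first supra-threshold window, offset = end of the last at/above
   4 Hz) pads every event by up to ~0.4 s per edge: a 1.0-s burst of
   evenly spaced spikes is reported as 1.6 s. Because event *durations*
   (and the 1.5-s short/long classification) are the scientific output,
   the default `edge_method = "spikes"` refines both boundaries to the
   event's spike support: the first and last "occupied" bin inside the
   hysteresis span, where occupied means a bin with at least 2 spikes or
   two consecutive non-empty bins (a single stray background spike cannot
   move a boundary). Any window above 8 Hz necessarily contains such a
   bin, so the refinement is always defined. `edge_method = "window"`
   reproduces the raw convention. Both are deterministic and are verified
   event-for-event against a brute-force window enumerator.
6. **Classification and summary.** An event is long if its duration is at
   least 1.5 s (the boundary value itself counts as long), otherwise
   short. Summaries report counts per class, mean ± SEM duration, and
   events per analyzed minute. The analyzed span is configurable
   (`analysis_span`), e.g. 5--60 min after a baseline period.

The MAD is computed over the full analyzed trace; bursts occupy a few
percent of a typical recording and the MAD is robust to that contamination.
Bursts separated by a single sub-threshold window are *not* merged.

# Synthetic extracellular traces

`simulateTrace()` generates Gaussian noise at the acquisition rate and
inserts a biphasic spike template (negative Gaussian lobe, then a smaller
positive lobe, 1.2 ms total) at Poisson times: a background rate outside
declared burst intervals and a higher rate inside them. Gaussian lobes keep
the template band-limited, so zero-phase filtering adds only ~4% ringing —
sharp-cornered templates ring enough at the 1-kHz band edge to produce
double detections. Defaults are chosen for realism of a disinhibited CA3
slice: 5 µV noise SD, 60 µV spikes (an order of magnitude above the noise,
as for pyramidal-layer electrodes), 0.5 Hz background multi-unit activity,
25 Hz intra-burst rate (comfortably above the 8-Hz onset criterion), and
lognormal burst durations with median ~1.15 s clipped to 0.6--3 s,
mirroring the ~1.2-s mean event durations of disinhibited CA3. The ground
truth records every spike time and burst interval.

The simulation is piecewise-constant-rate by design — the minimal structure
the detector's assumptions require. It does not emulate spike-waveform
diversity, electrode drift, or oscillatory LFP content; validation against
it demonstrates the correctness of the detection logic, not robustness to
every recording artifact.

# Spine volume from time-lapse z-series

Each 4-min timepoint is a z-series; analysis proceeds on 2-D projections:

- **Projection.** Maximum-intensity projection over z by default. The sum
  projection is available (`method = "sum"`) because acquisition
  descriptions sometimes conflate "maximal intensity" and "summed"; for
  well-separated spines both give proportional ROI integrals.
- **Registration.** Integer-pixel translation onto the first timepoint,
  estimated by FFT cross-correlation (searched within `max_shift` pixels,
  default 15). Rotation/affine alignment is out of scope; the plugin-style
  rigid alignment used interactively in imaging pipelines is replaced by
  this in-repo translation estimator, which recovers constant shifts
  exactly on noise-free data.
- **ROI integration and correction.** Per timepoint, each 20 × 20 px ROI is
  summed. The per-pixel background `b(t)` is the mean of 3 background ROIs
  divided by the ROI area; every ROI is corrected as `raw - 400 b(t)`
  (background subtraction applied per pixel over the 400-px ROI). Global
  fluorescence fluctuations are cancelled by `g(t)`, the mean over 4
  reference ROIs of their corrected intensity relative to their own
  baseline mean; spine values are divided by `g(t)`. Two exact invariances
  follow and are tested: multiplying all images at a timepoint by any
  k > 0, or adding a spatially uniform offset, leaves normalized traces
  unchanged in noise-free data. Timepoints with `g(t) <= 0` are flagged
  invalid rather than silently divided.
- **Normalization.** Corrected spine values are expressed as percent of
  their mean over all baseline timepoints (the baseline mean is 100% by
  construction). The alternative of normalizing to only the last 10
  baseline minutes matters little for stable baselines and is subsumed by
  the drift QC below.
- **Drift QC.** An OLS line is fitted to the normalized baseline values
  (the first 30 min; at least 3 points). The drift is the absolute fitted
  change across the baseline relative to the mean fitted level, in
  percent; sessions above 7% fail QC and are excluded from summaries. The
  "fitted endpoints over fitted mean" definition makes the rule exact on
  noise-free lines: a 100→110 baseline is 9.52% (fails), 100→105 is 4.88%
  (passes).
- **Summaries.** Shrinkage is reported as mean normalized volume in an
  analysis window (default 50--60 min after induction), averaged first
  across spines within an experiment, then mean ± SEM across experiments
  (N = experiments/animals). Spine density is count per unit dendrite
  length, reported per 10 µm by default; the unit is an explicit parameter
  because reported densities do not always state it.

`simulateSpineStacks()` renders a dendrite ridge plus 3-D Gaussian spine
blobs whose integrated intensities step to `shrink_fraction` (default 0.8)
at a set timepoint, under global exponential bleaching (multiplicative, the
exact structure the 4-location reference correction is designed to remove),
integer translation jitter, and optional Poisson shot noise. Defaults keep
the emulated acquisition geometry (512 × 512 × 15 voxels every 4 min, 15
spines); validation runs use smaller frames (e.g. 256 × 64 × 5 with 6
spines) so 50-seed sweeps stay fast — the estimator operates per-ROI, so
frame size does not change its statistics. The default integrated blob
intensity (20000 photons) puts per-ROI shot noise near 1%, a realistic
photon budget for bright GFP spines; ground truth stores true relative
volumes, centers and jitters. The nominal pixel size is 0.1 µm and is
metadata only: all outputs are relative volumes, so the value is immaterial.

The generator does not emulate spine appearance/disappearance, dendrite
drift in z, or detector nonlinearity; tests against it validate the
measurement chain (registration, correction, normalization, QC), not
biological segmentation.

# fEPSP slope and LTD magnitude

The initial slope of the field EPSP indexes synaptic strength. Per sweep:

1. the stimulus artifact is blanked for 1 ms after the stimulus;
2. the peak negativity is located within a 30-ms search window, and sweeps
   whose deflection does not exceed 4 × the pre-stimulus SD are flagged
   missing rather than fitted;
3. the slope is the least-squares slope of voltage against time over the
   samples between 20% and 80% of peak negativity on the initial falling
   phase. The 20--80% convention is the field standard for avoiding both
   the fiber volley region and the curvature near the peak; the fractions
   are configurable, and the same convention is used on both sides of any
   synthetic comparison. The sign is preserved (negative for an fEPSP).

Slopes are normalized to the mean over a baseline window (by convention
the last 10 min of baseline) and expressed in percent, so LTD magnitude is
simply the mean normalized slope over a post-induction window — 50--60 min
after induction by default, or the last 10 min of the recording relative
to a pre-drug baseline for the agonist-induced variant; both are window
parameters, not separate code paths. Percent block of a pharmacologically
isolated response is `(1 - drug/control) × 100` on response amplitude
(whether a study blocks on amplitude or slope is rarely stated; amplitude
is the default and the quantity is a plain ratio either way).

`simulateFepspSession()` builds one sweep per 30 s: a stimulus artifact
plus a difference-of-exponentials waveform (2 ms rise, 8 ms decay, 2 ms
synaptic delay) scaled by a strength series that steps from 1 to
`depression_fraction` at induction, under multiplicative lognormal sweep
noise with unit mean. Because the waveform scales linearly, the measured
slope ratio equals the programmed strength ratio exactly in noise-free
runs; the measured slope itself agrees with the analytic waveform's
least-squares slope to within 2% at 10-kHz sampling.

# Metabolic labeling

Incorporation is the triplicate-mean CPM divided by protein (mg). The
inter-experiment correction divides each rate by the activity of its
labeling-mix aliquot and expresses it as percent of the mean dose-corrected
rate over all slices in the batch, making each batch mean exactly 100.
Division by dose and by batch mean commute, so the unstated order is
innocuous. A `anchor_group` option rescales so a chosen group (e.g. WT)
averages 100 instead of the all-slice mean, matching the alternative
figure convention. Triplicates are aggregated by their mean; their SD
remains available in the raw columns for QC.

# Statistics layer

- **Outlier rule**: one pass; mean and sample SD computed on the full
  input; values strictly beyond ±2 SD dropped; boundary values retained.
  The rule is applied once to raw group values before testing (re-applying
  it with recomputed statistics is deliberately not the default).
- **mean ± SEM** with N the number of animals/experiments; SEM undefined
  (flagged `NA`) for n = 1.
- **Student's t**: pooled-variance two-sample t (not Welch) for unpaired
  data — the convention implied when legends say "unpaired t test" — and a
  one-sample t on differences when paired. Both-groups-constant with equal
  means returns p = 1 by convention. Computation delegates to
  `stats::t.test(var.equal = TRUE)`.
- **One-way ANOVA** via `stats::aov`, with Bonferroni post hoc pairwise
  pooled t-tests (raw p × number of comparisons, capped at 1). All group
  means identical gives F = 0, p = 1 (guarded against the 0/0 case).
  Repeated-measures two-way ANOVA is out of scope.
- **Fisher's exact test**: the two-sided p-value is the sum, over all
  tables with the observed margins, of hypergeometric point probabilities
  not exceeding that of the observed table (ties included), computed by
  enumeration with log-factorials. This point-probability rule is the one
  that reproduces the reported seizure-incidence p-values (0.0009 and
  0.018) at printed precision; it agrees with a no-logarithm brute-force
  enumerator to 1e-12 and with `stats::fisher.test`, which serves as an
  independent cross-check in the tests, never as the implementation.
  Degenerate tables (an all-zero row or column) return p = 1.

`simulateAgsCohort()` draws one Bernoulli outcome per animal with per-group
(genotype × treatment) incidence probabilities; the default group structure
uses the reported incidences (2/15, 9/11, 5/16) as probabilities, with the
Glyx-13-treated WT group at n = 15 (its n is not reported; matching the
WT-saline group is the natural choice).

# Pipeline, determinism and problem sizes

`runPipeline()` takes a nested config (R list or YAML) with per-stage
blocks; unknown keys are rejected anywhere in the tree, and detector
parameters are sanity-checked (e.g. `on_rate` must exceed `off_rate`)
before any stage runs. Stages execute in dependency order, write their
outputs (CSV/TIFF/JSON), and a manifest records the package version, seed,
config hash and MD5 checksum of every file. All randomness flows through
per-call seeds derived from the run seed — generators restore the global
RNG state — so a rerun with the same config and seed is byte-identical,
which the tests assert on the manifest bytes. `makeFixtures()` writes the
canonical small test dataset, including a seizure cohort whose per-group
counts equal the reported incidences verbatim.

Problem sizes used in the validation suite are chosen to keep a full run
fast while leaving no estimator data-starved: 20 ten-minute 25-kHz traces
for burst recovery; 200 random binned-count minutes for the brute-force
equivalence check; 50 stack series (256 × 64 × 5, 6 spines, 25 timepoints)
for volume recovery; 20 sessions for LTD recovery; 10,000 simulated null
tables for the Fisher type-I check.

# Known limitations

- Registration is integer-translation only; rotation or non-rigid motion
  biases ROI integrals and is not corrected.
- The burst detector reports a merged event when two true bursts are
  separated by less than one window; no merging/splitting heuristics are
  applied.
- The spike threshold assumes a stationary noise floor across the analyzed
  span (one MAD per recording).
- Synthetic validation establishes correctness of the quantification
  chain under the stated noise models, not performance on pathological
  recordings (electrode artifacts, z-drift, spike-shape variability).
- `measureSlope` assumes a single negative-going response after the
  stimulus; overlapping population spikes are not modeled.
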