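---
title: "Light-adapted ERG cohort analysis: models, simulator and numerical choices"
author: "ergHill"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light-adapted ERG cohort analysis: models, simulator and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the waveform model
behind the simulator, the definitions and numerics of the feature extractor,
the photopic hill model and its fitting, the clustered marginal models, and
the discrimination stage — together with the design choices that were
genuinely open and the reasons for the defaults.

## The data and the analysis chain

A light-adapted flash ERG session yields, per participant, per eye and per
flash strength, one averaged voltage trace sampled on a uniform grid around
stimulus onset. The package represents a cohort as an `ERGCohort` (a
`SummarizedExperiment` whose single assay is the time-by-recording voltage
matrix, in microvolts, with the recording keys and participant covariates in
`colData`). The analysis chain is

1. simulate (`simulateCohort`) or load (`readWaveforms`) a cohort;
2. extract the nine waveform parameters per recording
   (`extractFeatures` / `buildFeatureTable`);
3. compare groups with clustered marginal models plus QIC
   (`fitMarginalModel`, `computeQIC`) and flash-wise rank tests
   (`pairwiseGroupTests`);
4. fit the photopic hill to b-wave luminance-response curves
   (`fitHill`, `fitGroupHills`, `compareHillParams`);
5. quantify discrimination of a group by one feature (`rocWithCutoff`).

`runPipeline` ties the stages together reproducibly; every output carries
the configuration hash and seed.

## Waveform model and synthesis

A light-adapted ERG waveform is modelled as the sum of three smooth pulses:

* **a-wave** — a negative Gaussian, peak near 15 ms, width ~3.5 ms, from
  cone photoreceptor/OFF-bipolar hyperpolarization;
* **b-wave** — a positive gamma-shaped pulse,
  `amp * ((t/peak) * exp(1 - t/peak))^shape` for `t > 0` (shape 6 by
  default, peak near 30 ms), from ON-bipolar depolarization;
* **PhNR** — a broad negative Gaussian near 76 ms from retinal ganglion
  cell and Müller cell activity.

Any smooth unimodal family with these three lobes would serve; this one was
chosen because it has few parameters, reproduces the canonical morphology,
and makes the inverse problem (below) well behaved. White Gaussian
measurement noise is added (the traces being modelled are 60-trial averages,
which whitens residual noise); an AR(1) option exists behind a
configuration flag for sensitivity analyses.

The sampling grid is 2 kHz over −20…150 ms. No device standard fixes these;
they are device-like values chosen so that the pre-stimulus baseline window
and the full PhNR window are always covered and sub-sample timings (such as
a 30.6 ms time-to-peak) are meaningfully representable.

## Calibration: from feature targets to kernels

The simulator is specified in terms of *feature targets* — the group mean
a-amp, a-time, b-amp, b-time, p72, PhNRmin and Tmin at each flash — not in
terms of kernel parameters, because targets are what published group tables
report. `calibrateKernels` inverts the extraction map: it chooses kernel
amplitudes, timings and the PhNR width so that the *full extraction
pipeline applied to the noiseless synthetic waveform* reproduces the
targets. This is a damped fixed-point iteration (each kernel parameter is
nudged by the residual of the feature it chiefly controls) with
per-iteration step caps, search-window clamps, and damping that anneals
from 0.7 to 0.15; convergence is declared when amplitude residuals are
below 0.05 µV and timing residuals below 0.05 ms, and non-convergence is an
error that reports the residuals.

Two regimes deserve note. First, targets whose p72/PhNRmin ratio is far
below 1 while Tmin is close to 72 ms would require a PhNR lobe narrower
than the extraction smoothing bandwidth; such targets are rejected as
infeasible rather than silently missed. Second, sub-microvolt a-wave
targets (the "no detectable a-wave" regime of dim flashes) do not pin their
own timing — the trough is carved mostly by the rising b-wave — so a-time
is treated as a soft target there and the a-kernel timing stays at its
initial value. The corresponding extraction rows are flagged
`a_low_confidence`.

## The packaged group profiles

`defaultGroupProfiles` encodes the study conditions the simulator emulates:

* **b-amp** follows each group's reference photopic hill curve
  (`referenceHillParams`: ADHD `G_b` 14.99, `V_bmax` 38.18; control
  10.08/30.24; ASD 9.33/26.61, with `B²`, `σ_b`, `μ` as tabulated),
  anchored to the reported group means at the flashes where means are
  reported — 37.2/28.2/24.7 µV (ADHD/control/ASD) at 1.204 log
  phot cd·s·m⁻².
* **b-time** is 30.6/30.8/31.2 ms at 1.204 and drifts earlier at dimmer
  flashes at 2 ms per log unit, reflecting the observation that
  time-to-peak gets later as flash strength increases; the slope is a
  package choice, not a published value.
* **p72** is −10.6/−7.3/−7.5 µV at 1.114 and scales with the group's hill
  curve elsewhere; PhNRmin is 15% deeper than p72 with Tmin at 76 ms
  (package choices within physiological ranges).
* **a-amp** grows with flash strength as a saturating function
  `9·I/(I+2)` µV, identical across groups (no group differences were
  reported for it), with a-time drifting slightly earlier at brighter
  flashes.

Between-subject variability enters as a latent amplitude factor
`1 + cv·z` applied to the whole waveform (so amplitudes scale together and
the group mean is preserved exactly in expectation) and a latent rigid time
translation. The coefficients of variation and timing SDs come from the
reported 1.204-flash values (e.g. 10.3/37.2 for ADHD b-amp; 1.1 ms for its
b-time). Both latents are shared across a participant's two eyes with
correlation ρ = 0.7, a typical inter-eye correlation for amplitude
measures; ρ is configurable and its effect is tested by a Monte-Carlo
property. Measurement noise is 1.5 µV on the averaged trace. Covariates
(age, sex, ethnicity, iris colour index, electrode vertical level,
medication) are drawn from the cohort demographic table but carry **no
effect on waveforms by default** — the discriminating structure is entirely
the group-by-flash profile — so covariate effects found by the marginal
model under default simulation are false positives by construction, which
is exactly what the calibration tests exploit. Effects can be injected for
power studies.

What the simulator does *not* emulate: blinks and artifacts, trial-level
averaging mechanics, electrode impedance drift, pupil size, or any
dark-adapted responses. Passing tests therefore demonstrate the
correctness and calibration of the *analysis machinery*, not device-level
realism of the waveforms.

## Feature extraction numerics

Per recording, with default windows: baseline = mean voltage over
−20…−2 ms; a-trough searched in 5…25 ms; b-peak searched from the located
a-trough to 55 ms; PhNR minimum in 55…95 ms; p72 read at exactly 72 ms
(linear interpolation of the raw trace). `a_amp` is stored as a positive
magnitude, PhNR measures as signed (negative-going) values, so the ratio
denominator `b_amp − a_amp` equals the baseline-referenced b-wave peak —
the physiologically sensible reading of the ratio definitions. The search
windows are not standardized anywhere and are configurable.

Sub-sample extrema use a two-stage estimator chosen for its bias
properties under noise:

1. the *location* is the vertex of a parabola fitted to a lightly smoothed
   copy of the trace (Gaussian smoother, SD 2 ms; fit half-width 3.5 ms)
   around the discrete extremum — a smooth functional of the data, so noise
   adds timing jitter but essentially no bias;
2. the *amplitude* is a parabola fitted to the **raw** trace (half-width
   1.5 ms) evaluated **at that fixed time** — linear in the data and
   therefore unbiased under zero-mean noise, and immune to the smoothing
   attenuation.

The naive alternative — take the noisy argmax and read the maximum — is
biased upward by the expected maximum of noise over the search window;
measured on the default configuration that bias is several tenths of a
microvolt for amplitudes and ~0.2 ms for timings, which would corrupt
group-mean recovery. With the two-stage estimator the measured biases are
≲0.15 µV and ≲0.01 ms. Deterministic shifts introduced by smoothing a
skewed peak are absorbed by calibration, which runs the same pipeline on
the noiseless waveform. Ties in discrete extrema resolve toward the earlier
sample; if the fitted PhNR minimum exceeds the value at 72 ms (possible
only through noise), the minimum is clamped to the 72 ms value, preserving
the minimum property `p72 ≥ PhNRmin`.

## Photopic hill fitting

`fitHill` minimizes residual sum of squares over the five parameters with
Levenberg–Marquardt under positivity bounds (`μ` constrained to the
observed intensity range), from a fixed 32-point start grid
(`G_b` ∈ {5, 15}, `B²` ∈ {0.3, 1}, `V_bmax` ∈ {20, 40}, `σ_b` ∈ {0.3, 1},
`μ` ∈ {1.5, 3}) plus one data-driven start; the best start wins and
multi-start stops early once an essentially perfect fit (rss < 1e−10) is
found. On noiseless nine-point curves the generating parameters are
recovered to well below 0.1% — the round-trip identifiability property the
tests enforce. The curve is fitted on *linear* intensity converted from log
flash strengths, which is what makes the tabulated pairing of `μ` ≈ 2.5
with log(μ) ≈ 0.4 consistent. The ISCEV LA3 flash is excluded from hill
curves because it is delivered on a different background.

Group comparison of hill parameters is run at two levels, because a single
fit per group provides no degrees of freedom for inference: per-participant
fits (eyes averaged per flash) feed a one-way ANOVA (`compareHillParams`),
while the group-mean fit with its asymptotic standard errors is reported
descriptively. Whether published "±" values on hill parameters are fit SEs
or between-participant SEs is generally ambiguous; the package reports
both and asserts neither.

## Clustered marginal models

`fitMarginalModel` implements Gaussian GEE with participant clusters:
estimating equations iterated with an exchangeable (or independence)
working correlation, moment estimation of the exchangeable parameter,
and a sandwich covariance. No GEE estimation backend is assumed; the
estimator reduces exactly to OLS for singleton clusters, which is one of
the independent oracles in the tests (the other is the cluster-robust
covariance from an established sandwich implementation).

Two small-sample defences are defaults rather than options, because the
smallest group in the emulated design contributes only 15 clusters:

* the **Mancl–DeRouen bias-corrected** meat (residuals inflated by
  `(I − H_i)^{-1}` per cluster), and
* an **F reference** for multi-df Wald statistics:
  `W·(K − q + 1)/(K·q)` is referred to `F(q, K − q + 1)` with `K` clusters
  and `q` contrast df, instead of referring `W` to χ²(q).

With the plain χ² reference the 18-df flash-by-group test rejects a true
null far above nominal level at these cluster counts; with the corrected
default it is near-nominal at α = 0.005 for balanced designs of ~45
clusters per group, which is the design used by the calibration tests (the
severely unbalanced 15-cluster case remains anticonservative for 18-df
contrasts — a known limitation of sandwich-based Wald tests that no simple
correction removes; single-df contrasts are well calibrated throughout).
Flash strength is modelled as a 10-level categorical factor, so the
interaction carries (10−1)×(3−1) = 18 df.

QIC follows the standard quasi-likelihood construction under the
independence model: `QIC = −2·Q(β̂; I) + 2·tr(Ω̂_I V̂_R)` with the Gaussian
quasi-likelihood, the independence model-based information `X'X/φ̂`, and
the robust covariance of the fitted model. It is verified against a
brute-force evaluation on a small table and behaves as a selection
criterion (the generating mean structure wins the majority of replicates
in simulation).

Pairwise comparisons are Wilcoxon rank-sum tests per group pair per flash
on participant-level eye-averaged values — the rank tests must not
double-count eyes, while the GEE handles the eye clustering explicitly.
The specific nonparametric procedure behind published "multiple pairwise
comparisons" is rarely stated; pairwise Wilcoxon with Holm adjustment was
chosen as distribution-free, standard and conservative, and both the
adjustment method and the adjustment family (all tested pairs, the
default, versus per-flash) are configurable. Exact p-values are used for
small tie-free samples via the standard exact rule. The significance level
throughout defaults to α = 0.005.

## Discrimination

`rocWithCutoff` scores participants (eyes averaged) at one flash,
auto-detects orientation from the class means, computes the empirical ROC
over all distinct-score midpoint thresholds, the AUC by the rank
formulation (equal to the trapezoidal area, with ties at half weight), and
an operating cut-off by Youden's J (a closest-to-top-left criterion is
selectable). Published empirical AUCs from raw cohort data are not
numerically reproducible from summary statistics alone: the binormal
closed form from the reported 1.204-flash means and SDs,
Φ(12.5/√(10.3² + 8.9²)) ≈ 0.82, is itself below the reported empirical
0.88, so the calibrated simulation is asserted to reproduce the
discrimination only qualitatively (AUC ≥ 0.8 for ADHD versus ASD on
eye-averaged scores, where the two-eye averaging raises the effective
separation above the single-eye binormal value). This is stated here
deliberately: it is a statement about what summary-statistic calibration
can and cannot reproduce, not a defect of the fitting.

## Problem sizes in the tests

The test suite simulates one default cohort (131 participants × 2 eyes ×
10 flashes) and reuses it across test files; the statistical calibration
uses 300 replicates of a balanced 45/45/45-cluster feature-level
simulation for size and coverage, 100 replicates for QIC selection, and
500 eyes per group for group-mean recovery (matching the acceptance
script). These sizes were chosen to make Monte-Carlo bands tight enough to
be meaningful (3 binomial SEs around nominal rates) while keeping the
suite comfortably fast; the feature-level simulator
(`simulateClusteredFeatures`) exists precisely so that calibration studies
need not synthesize waveforms.

## Known limitations

* The simulator's flash-strength dependence between anchored flashes is a
  modelling choice (hill-curve interpolation); real per-flash group means
  may deviate from it.
* Covariates carry no waveform effects by default, so the package cannot
  by itself validate covariate-adjustment behaviour against real data.
* Robust 18-df Wald tests with very few clusters in one group remain
  anticonservative even with bias correction; interpret the interaction
  test accordingly in severely unbalanced designs.
* Medication before/after sessions are supported structurally (paired
  sessions with zero true effect by default) but the specialised robust
  linear-model estimator sometimes used for such contrasts is out of
  scope; the marginal-model machinery with a before/after interaction is
  the supported route.
* No artifact rejection or trial-level processing: inputs are assumed to
  be clean averaged traces.
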