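# ergHill

Light-adapted flash electroretinogram (ERG) cohort analysis: waveform
parameterization, photopic hill modelling, clustered group comparison and
ROC-based discrimination — together with a calibrated synthetic-cohort
simulator so the full pipeline is testable end to end without access to raw
recordings.

## Who this is for

Researchers analysing light-adapted flash-series ERGs across diagnostic
groups (for example ADHD, ASD and typically developing controls), where each
participant contributes repeated measures from both eyes across a series of
flash strengths, and where the scientific questions are (i) which waveform
parameters separate the groups, (ii) how the b-wave luminance-response curve
differs between groups, and (iii) how well a single parameter discriminates
one group from the rest.

## What it computes

**Waveform parameters** (per recording, from a time/voltage trace): a-wave
amplitude and time-to-peak, b-wave amplitude (a-trough to b-peak) and
time-to-peak, the photopic negative response (PhNR) amplitude at 72 ms
(`p72`), the PhNR minimum within 55–95 ms (`PhNRmin`) and its time (`Tmin`),
and the two ratios `p-ratio = p72 / (b-amp − a-amp)` and
`w-ratio = PhNRmin / (b-amp − a-amp)`.

**Photopic hill**: the b-wave amplitude versus linear flash strength *I*
(phot cd·s·m⁻²) is modelled as a log-Gaussian OFF-pathway component plus a
saturating hyperbolic ON-pathway component,

    y(I) = G_b (I/μ)^(ln(μ/I)/B²) + V_bmax · I / (I + σ_b)

with maximal Gaussian amplitude `G_b`, Gaussian width `B²`, maximal
saturated amplitude `V_bmax`, semi-saturation strength `σ_b` and peak flash
strength `μ`. The first term equals `G_b·exp(−ln²(I/μ)/B²)`. Fitting is
multi-start Levenberg–Marquardt least squares (`fitHill`).

**Group comparison**: Gaussian generalized estimating equations (GEE) with
participant clusters, exchangeable or independence working correlation,
bias-corrected sandwich covariance and F-referenced Wald tests
(`fitMarginalModel`), with the flash-by-group interaction (`FS:G`, 18 df for
ten flashes and three groups) as the discriminating term and the Pan (2001)
QIC for model assessment. Flash-wise pairwise Wilcoxon rank-sum tests with
Holm adjustment (`pairwiseGroupTests`) and a Spearman feature–phenotype
correlation matrix (`correlationNetwork`) complete the stage.

**Discrimination**: empirical ROC of a feature at one flash with the rank
(Mann–Whitney) AUC, Youden-optimal cut-off, sensitivity and specificity
(`rocWithCutoff`).

**Simulation**: `simulateCohort(defaultSimConfig())` generates a cohort of
15 ADHD / 59 control / 57 ASD participants, two eyes each, at nine
randomized flash strengths (−0.367…1.204 log phot cd·s·m⁻²) plus the ISCEV
LA3 standard flash, with group feature profiles calibrated so that noiseless
extraction reproduces the packaged group targets (for example an ADHD b-wave
amplitude of 37.2 µV at the 1.204 flash), demographic covariates, clustered
two-eye latent factors and measurement noise. Cohorts are
`SummarizedExperiment`-derived `ERGCohort` objects.

## Worked example

```r
library(ergHill)

cohort <- simulateCohort(defaultSimConfig(seed = 1))
cohort
#> ERGCohort with 2620 recordings
#>   time grid: -20 to 150 ms, dt = 0.5 ms (341 samples)
#>   participants: 131 | groups: ADHD 15, ASD 57, CTL 59
#>   flashes (log phot cd.s.m^-2): -0.367, -0.119, 0.114, 0.398, 0.477,
#>   0.602, 0.799, 0.949, 1.114, 1.204

features <- buildFeatureTable(cohort)
top <- features[abs(features$log_flash - 1.204) < 1e-9, ]
round(sapply(split(top$b_amp, top$group), mean), 1)
#> ADHD  ASD  CTL
#> 37.3 24.4 30.8

fit <- fitMarginalModel(features, dependent = "b_amp")
subset(waldTable(fit), term == "FS:G")
#>    term df df2 statistic            p
#> 10 FS:G 18 114  293.7835 2.128942e-21

hills <- fitGroupHills(features, level = "group")
round(t(sapply(hills, coef)), 2)
#>        G_b   B2 V_bmax sigma_b   mu log10_mu
#> ADHD 15.22 1.10  38.32    0.83 2.52     0.40
#> ASD   9.54 1.09  25.34    0.62 2.72     0.44
#> CTL  10.94 0.72  32.45    0.67 2.52     0.40

roc <- rocWithCutoff(features, dependent = "b_amp", flash = 1.204,
                     positive = "ADHD", negative = "ASD")
roc
#> ROC: positive = ADHD (higher-is-positive)
#>   AUC = 0.864 | cutoff = 30.6 | sensitivity = 0.80 | specificity = 0.79
```

The group mean b-wave amplitudes at the brightest flash recover the
calibrated targets (elevated in ADHD, reduced in ASD relative to controls);
the 18-df flash-by-group interaction is strongly significant for b-wave
amplitude; the group-level photopic hill fits order the maximal saturated
amplitude as ADHD > control > ASD; and b-wave amplitude at the 1.204 flash
discriminates ADHD from ASD with AUC ≈ 0.86 at a cut-off of ≈ 31 µV in this
simulated cohort.

`runPipeline(pipelineConfig(), outDir = "out")` executes the whole chain
(simulate/load → extract → GEE + QIC → pairwise tests → hill fits → ROC) and
writes CSV/JSON artifacts plus a provenance-stamped `report.json`. A thin
command-line wrapper is installed at `inst/scripts/erg-hill.R`.

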