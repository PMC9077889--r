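# Shared fixtures, built in code and memoized across test files.

.fixtures <- new.env(parent = emptyenv())

# Default-condition cohort and feature table (simulated once per test run).
defaultCohortFixture <- function() {
  if (!exists("cohort", envir = .fixtures)) {
    assign("cohort", simulateCohort(defaultSimConfig(seed = 42L)),
           envir = .fixtures)
  }
  get("cohort", envir = .fixtures)
}

defaultFeatureTableFixture <- function() {
  if (!exists("ft", envir = .fixtures)) {
    assign("ft", buildFeatureTable(defaultCohortFixture()), envir = .fixtures)
  }
  get("ft", envir = .fixtures)
}

# Small toy waveform: sum of well-separated Gaussian lobes on the standard
# grid, with known analytic extrema.
toyTime <- function(dt = 0.5) seq(-20, 150, by = dt)

toyWaveform <- function(time = toyTime(),
                        trough = c(amp = -10, at = 15, w = 3),
                        peak = c(amp = 25, at = 32, w = 4),
                        phnr = c(amp = -8, at = 70,
                                 w = 2 / sqrt(2 * log(8 / 7.5)))) {
  trough[["amp"]] * exp(-(time - trough[["at"]])^2 / (2 * trough[["w"]]^2)) +
    peak[["amp"]] * exp(-(time - peak[["at"]])^2 / (2 * peak[["w"]]^2)) +
    phnr[["amp"]] * exp(-(time - phnr[["at"]])^2 / (2 * phnr[["w"]]^2))
}

# Tiny two-group feature table for rank-test unit tests.
miniFeatureTable <- function(vals1, vals2, flash = 1.204,
                             groups = c("A", "B")) {
  do.call(rbind, lapply(seq_along(c(vals1, vals2)), function(i) {
    v <- c(vals1, vals2)[i]
    g <- if (i <= length(vals1)) groups[1] else groups[2]
    data.frame(participant_id = sprintf("%s%02d", g, i), group = g,
               eye = "left", session = "baseline", log_flash = flash,
               b_amp = v)
  }))
}
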