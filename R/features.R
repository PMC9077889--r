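# Waveform parameterization: a-wave, b-wave and PhNR measures per recording.

#' Feature-extraction windows
#'
#' Search windows (ms, relative to flash onset) for the waveform parameters.
#' The PhNR window defaults to [55, 95] ms and the fixed-time PhNR sample to
#' 72 ms. The a-trough and b-peak search windows are not standardized and can
#' be overridden. `smooth_sd_ms` is the standard deviation of the Gaussian
#' smoother used only to *locate* extrema (amplitudes and sub-sample timings
#' are then refined by a local least-squares parabola on the raw trace over
#' `refine_halfwidth_ms`).
#'
#' @param baseline window for the pre-stimulus baseline mean.
#' @param a_trough a-wave trough search window.
#' @param b_peak_end latest time considered for the b-wave peak (the window
#'   starts at the located a-trough).
#' @param phnr PhNR minimum search window.
#' @param p72_time fixed PhNR sampling time.
#' @param smooth_sd_ms extremum-location smoothing bandwidth.
#' @param loc_halfwidth_ms half-width of the timing parabola fitted on the
#'   smoothed trace.
#' @param refine_halfwidth_ms half-width of the amplitude parabola fitted on
#'   the raw trace.
#' @return list of class `FeatureWindows`.
#' @export
featureWindows <- function(baseline = c(-20, -2), a_trough = c(5, 25),
                           b_peak_end = 55, phnr = c(55, 95), p72_time = 72,
                           smooth_sd_ms = 2, loc_halfwidth_ms = 3.5,
                           refine_halfwidth_ms = 1.5) {
  w <- list(baseline = as.numeric(baseline), a_trough = as.numeric(a_trough),
            b_peak_end = as.numeric(b_peak_end), phnr = as.numeric(phnr),
            p72_time = as.numeric(p72_time), smooth_sd_ms = smooth_sd_ms,
            loc_halfwidth_ms = loc_halfwidth_ms,
            refine_halfwidth_ms = refine_halfwidth_ms)
  stopifnot(diff(w$baseline) > 0, diff(w$a_trough) > 0, diff(w$phnr) > 0,
            w$smooth_sd_ms >= 0, w$refine_halfwidth_ms > 0)
  if (w$p72_time < w$phnr[1] || w$p72_time > w$phnr[2])
    stop("p72_time must lie inside the PhNR window")
  if (w$b_peak_end <= w$a_trough[1])
    stop("b_peak_end must exceed the start of the a-trough window")
  class(w) <- c("FeatureWindows", "list")
  w
}

# Gaussian FIR smoother applied column-wise with edge replication.
.gaussSmooth <- function(mat, sd_samples) {
  if (sd_samples <= 0) return(mat)
  half <- max(1L, ceiling(3 * sd_samples))
  k <- stats::dnorm(seq(-half, half), sd = sd_samples)
  k <- k / sum(k)
  pad_top <- mat[rep(1L, half), , drop = FALSE]
  pad_bot <- mat[rep(nrow(mat), half), , drop = FALSE]
  padded <- rbind(pad_top, mat, pad_bot)
  sm <- stats::filter(padded, k, sides = 2)
  out <- sm[(half + 1):(half + nrow(mat)), , drop = FALSE]
  matrix(out, nrow = nrow(mat), dimnames = dimnames(mat))
}

# Local least-squares parabola: coefficients around sample `idx`.
.quadFit <- function(time, y, idx, hw) {
  i0 <- max(1L, idx - hw)
  i1 <- min(length(time), idx + hw)
  x <- time[i0:i1] - time[idx]
  cf <- tryCatch(qr.coef(qr(cbind(1, x, x^2)), y[i0:i1]),
                 error = function(e) rep(NA_real_, 3))
  list(cf = cf, t0 = time[idx])
}

# Sub-sample extremum refinement. The *time* is the vertex of a parabola
# fitted to the lightly smoothed trace (a smooth functional of the data, so
# measurement noise adds jitter but essentially no bias); the *amplitude* is
# a parabola fitted to the raw trace evaluated at that fixed time, which is
# linear in the data and therefore unbiased under zero-mean noise. Ties and
# degenerate fits fall back to the discrete sample (earlier time wins via
# which.min/which.max).
.refineVertex <- function(time, raw, smooth, idx, lo, hi, hw_s, hw_r, minimize) {
  dt <- time[2] - time[1]
  fs <- .quadFit(time, smooth, idx, max(1L, round(hw_s / dt)))
  cf <- fs$cf
  sign_ok <- is.finite(cf[3]) && abs(cf[3]) > 1e-12 &&
    ((minimize && cf[3] > 0) || (!minimize && cf[3] < 0))
  t_star <- if (sign_ok && abs(-cf[2] / (2 * cf[3])) <= hw_s)
    fs$t0 - cf[2] / (2 * cf[3]) else fs$t0
  t_star <- min(max(t_star, lo), hi)
  idx2 <- which.min(abs(time - t_star))
  fr <- .quadFit(time, raw, idx2, max(1L, round(hw_r / dt)))
  cr <- fr$cf
  if (anyNA(cr)) return(c(t_star, raw[idx2]))
  x <- t_star - fr$t0
  c(t_star, cr[1] + cr[2] * x + cr[3] * x^2)
}

# which.min/which.max with ties broken toward the earlier sample
.argext <- function(x, minimize) {
  if (minimize) which.min(x) else which.max(x)
}

.extractOne <- function(time, raw, smooth, w) {
  base_idx <- time >= w$baseline[1] & time <= w$baseline[2]
  baseline <- mean(raw[base_idx])

  # a-wave trough
  ia_win <- which(time >= w$a_trough[1] & time <= w$a_trough[2])
  ia <- ia_win[.argext(smooth[ia_win], TRUE)]
  av <- .refineVertex(time, raw, smooth, ia, w$a_trough[1], w$a_trough[2],
                      w$loc_halfwidth_ms, w$refine_halfwidth_ms,
                      minimize = TRUE)
  a_time <- av[1]; a_volt <- av[2]
  a_low_conf <- (min(smooth[ia_win]) - baseline) > -1
  a_amp <- max(0, baseline - a_volt)

  # b-wave peak, searched after the located trough
  ib_win <- which(time > a_time & time <= w$b_peak_end)
  if (!length(ib_win)) ib_win <- which(time <= w$b_peak_end & time > w$a_trough[1])
  ib <- ib_win[.argext(smooth[ib_win], FALSE)]
  bv <- .refineVertex(time, raw, smooth, ib, a_time, w$b_peak_end,
                      w$loc_halfwidth_ms, w$refine_halfwidth_ms,
                      minimize = FALSE)
  b_time <- bv[1]; b_volt <- bv[2]
  b_amp <- max(0, b_volt - a_volt)

  # PhNR: fixed-time p72 and windowed minimum
  p72 <- stats::approx(time, raw, xout = w$p72_time)$y - baseline
  ip_win <- which(time >= w$phnr[1] & time <= w$phnr[2])
  ip <- ip_win[.argext(smooth[ip_win], TRUE)]
  pv <- .refineVertex(time, raw, smooth, ip, w$phnr[1], w$phnr[2],
                      w$loc_halfwidth_ms, w$refine_halfwidth_ms,
                      minimize = TRUE)
  t_min <- pv[1]; phnr_min <- pv[2] - baseline
  if (phnr_min > p72) {  # window minimum cannot exceed the value at 72 ms
    phnr_min <- p72
    t_min <- w$p72_time
  }

  denom <- b_amp - a_amp
  ratios_defined <- is.finite(denom) && denom > 0
  c(a_amp = a_amp, a_time = a_time, b_amp = b_amp, b_time = b_time,
    p72 = p72, phnr_min = phnr_min, t_min = t_min,
    p_ratio = if (ratios_defined) p72 / denom else NA_real_,
    w_ratio = if (ratios_defined) phnr_min / denom else NA_real_,
    a_low_confidence = as.numeric(a_low_conf),
    ratios_defined = as.numeric(ratios_defined))
}

.checkCoverage <- function(time, w) {
  if (min(time) > w$baseline[1] || max(time) < w$phnr[2])
    stop(sprintf(
      "epoch [%g, %g] ms does not cover the required windows (baseline from %g ms, PhNR to %g ms)",
      min(time), max(time), w$baseline[1], w$phnr[2]))
}

#' Extract ERG waveform parameters
#'
#' Computes the nine standard light-adapted ERG waveform parameters per
#' recording: a-wave amplitude (`a_amp`, baseline-to-trough magnitude, uV) and
#' time-to-peak (`a_time`, ms); b-wave amplitude (`b_amp`, trough-to-peak, uV)
#' and time-to-peak (`b_time`); the PhNR amplitude at 72 ms (`p72`, signed,
#' baseline-referenced); the PhNR windowed minimum (`phnr_min`, signed) and
#' its time (`t_min`); and the two ratios `p_ratio = p72 / (b_amp - a_amp)`
#' and `w_ratio = phnr_min / (b_amp - a_amp)`. With the positive-magnitude
#' convention for `a_amp`, the ratio denominator equals the
#' baseline-referenced b-wave peak.
#'
#' Extrema are located on a lightly smoothed copy of the trace and then
#' refined to sub-sample precision by a local least-squares parabola on the
#' raw trace (ties broken toward the earlier time). For dim flashes with no
#' detectable a-wave (trough shallower than 1 uV below baseline) the trough is
#' still taken at the window minimum, `a_amp` is clamped at >= 0 and the row is
#' flagged `a_low_confidence`. A flat trace yields zero amplitudes with the
#' ratios flagged undefined (`ratios_defined = 0`, ratios `NA`).
#'
#' @param x an [ERGCohort], or a numeric voltage vector.
#' @param windows a [featureWindows()] list.
#' @param time sample times in ms (numeric-vector method only).
#' @param ... unused.
#' @return one-row-per-recording `data.frame` of features (plus the recording
#'   keys for the `ERGCohort` method).
#' @examples
#' tt <- seq(-20, 150, by = 0.5)
#' v <- 30 * exp(-(tt - 32)^2 / 50) * (tt > 0)
#' extractFeatures(v, time = tt)
#' @export
setGeneric("extractFeatures",
           function(x, windows = featureWindows(), ...)
             standardGeneric("extractFeatures"))

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "numeric", function(x, windows = featureWindows(),
                                                 time, ...) {
  stopifnot(length(time) == length(x))
  .checkCoverage(time, windows)
  dt <- time[2] - time[1]
  m <- matrix(x, ncol = 1)
  sm <- .gaussSmooth(m, windows$smooth_sd_ms / dt)
  as.data.frame(as.list(.extractOne(time, x, sm[, 1], windows)))
})

#' @rdname extractFeatures
#' @export
setMethod("extractFeatures", "ERGCohort", function(x, windows = featureWindows(), ...) {
  time <- timeGrid(x)
  .checkCoverage(time, windows)
  dt <- time[2] - time[1]
  V <- voltageMatrix(x)
  S <- .gaussSmooth(V, windows$smooth_sd_ms / dt)
  feats <- t(vapply(seq_len(ncol(V)),
                    function(j) .extractOne(time, V[, j], S[, j], windows),
                    numeric(11)))
  keys <- as.data.frame(SummarizedExperiment::colData(x))[,
    c("participant_id", "eye", "session", "log_flash"), drop = FALSE]
  rownames(keys) <- NULL
  cbind(keys, as.data.frame(feats))
})

#' Build the per-recording feature table
#'
#' Runs [extractFeatures()] over every recording of a cohort and joins the
#' participant covariates, producing the analysis table consumed by the
#' marginal-model, pairwise, photopic-hill and ROC stages: one row per
#' (participant, eye, flash, session).
#'
#' @param cohort an [ERGCohort].
#' @param windows a [featureWindows()] list.
#' @return data.frame of features joined with covariates.
#' @export
buildFeatureTable <- function(cohort, windows = featureWindows()) {
  stopifnot(is(cohort, "ERGCohort"))
  if (ncol(cohort) == 0) {
    featcols <- c("a_amp", "a_time", "b_amp", "b_time", "p72", "phnr_min",
                  "t_min", "p_ratio", "w_ratio", "a_low_confidence",
                  "ratios_defined")
    ft <- as.data.frame(setNames(rep(list(numeric(0)), length(featcols)),
                                 featcols))
    keys <- data.frame(participant_id = character(0), eye = character(0),
                       session = character(0), log_flash = numeric(0))
    cov0 <- participantData(cohort)[0, , drop = FALSE]
    extra <- setdiff(colnames(cov0), c(colnames(keys), featcols))
    return(cbind(keys, ft, cov0[rep(1, 0), extra, drop = FALSE]))
  }
  ft <- extractFeatures(cohort, windows)
  covs <- participantData(cohort)
  missing <- setdiff(unique(ft$participant_id), covs$participant_id)
  if (length(missing))
    stop("no covariates for participant(s): ", paste(missing, collapse = ", "))
  out <- merge(ft, covs, by = "participant_id", sort = FALSE)
  key <- paste(out$participant_id, out$eye, out$log_flash, out$session)
  if (anyDuplicated(key))
    stop("duplicated (participant, eye, flash, session) rows in feature table")
  out
}
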