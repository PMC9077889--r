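#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats coef vcov approx aov ar anova as.formula complete.cases
#'   cor cor.test lm median model.matrix na.omit optimize p.adjust pnorm
#'   qnorm quantile rbinom rnorm runif sd setNames terms var wilcox.test
#'   residuals fitted pchisq pf predict
#' @importFrom utils head modifyList read.csv tail
NULL

#' Cohort of light-adapted ERG recordings
#'
#' `ERGCohort` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' collection of flash ERG waveforms on a common uniform time grid. The single
#' assay, `"voltage"`, is a time-by-recording matrix in microvolts; `rowData`
#' carries the time grid (`time_ms`, milliseconds relative to flash onset) and
#' `colData` one row per recording with the identifying keys
#' (`participant_id`, `eye`, `session`, `log_flash`) plus participant
#' covariates (group, age, sex, ethnicity, iris colour index, electrode
#' vertical distance, medication). Protocol and simulation provenance live in
#' `metadata()`.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @export
setClass("ERGCohort", contains = "SummarizedExperiment")

.validERGCohort <- function(object) {
  msg <- character()
  if (!"voltage" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'voltage' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!"time_ms" %in% colnames(rd)) {
    msg <- c(msg, "rowData must contain 'time_ms'")
  } else {
    tt <- rd$time_ms
    if (length(tt) > 1) {
      dt <- diff(tt)
      if (any(dt <= 0)) msg <- c(msg, "time_ms must be strictly increasing")
      if (diff(range(dt)) > 1e-6) msg <- c(msg, "time_ms must be a uniform grid")
    }
    if (min(tt) > -10) msg <- c(msg, "epoch must include a pre-stimulus segment (>= 10 ms before 0)")
    if (max(tt) < 95) msg <- c(msg, "epoch must extend to at least 95 ms (PhNR window)")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("participant_id", "eye", "session", "log_flash", "group")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks required columns: ", paste(miss, collapse = ", ")))
  if (length(msg)) msg else TRUE
}
setValidity("ERGCohort", .validERGCohort)

#' @describeIn ERGCohort compact display of grid, recordings and groups.
#' @param object an `ERGCohort`.
#' @export
setMethod("show", "ERGCohort", function(object) {
  tt <- timeGrid(object)
  cd <- SummarizedExperiment::colData(object)
  cat("ERGCohort with", ncol(object), "recordings\n")
  cat(sprintf("  time grid: %g to %g ms, dt = %g ms (%d samples)\n",
              min(tt), max(tt), if (length(tt) > 1) tt[2] - tt[1] else NA_real_,
              length(tt)))
  cat("  participants:", length(unique(cd$participant_id)),
      "| groups:", paste(names(table(cd$group[!duplicated(cd$participant_id)])),
                         table(cd$group[!duplicated(cd$participant_id)]),
                         collapse = ", "), "\n")
  cat("  flashes (log phot cd.s.m^-2):",
      paste(sort(unique(round(cd$log_flash, 3))), collapse = ", "), "\n")
})

#' @rdname ERGCohort
#' @aliases timeGrid
#' @param x an `ERGCohort`.
#' @return `timeGrid()`: numeric vector of sample times (ms).
#' @export
setGeneric("timeGrid", function(x) standardGeneric("timeGrid"))

#' @rdname ERGCohort
#' @export
setMethod("timeGrid", "ERGCohort", function(x)
  SummarizedExperiment::rowData(x)$time_ms)

#' @rdname ERGCohort
#' @return `voltageMatrix()`: the time-by-recording voltage matrix (uV).
#' @export
setGeneric("voltageMatrix", function(x) standardGeneric("voltageMatrix"))

#' @rdname ERGCohort
#' @export
setMethod("voltageMatrix", "ERGCohort", function(x)
  SummarizedExperiment::assay(x, "voltage"))

#' @rdname ERGCohort
#' @return `participantData()`: one-row-per-participant data.frame of covariates.
#' @export
setGeneric("participantData", function(x) standardGeneric("participantData"))

#' @rdname ERGCohort
#' @export
setMethod("participantData", "ERGCohort", function(x) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  keep <- setdiff(colnames(cd), c("eye", "session", "log_flash", "is_iscev_la3"))
  out <- cd[!duplicated(cd$participant_id), keep, drop = FALSE]
  rownames(out) <- NULL
  out
})

#' Photopic hill fit
#'
#' Result of a five-parameter photopic hill fit: the log-Gaussian (OFF-pathway)
#' plus saturating hyperbolic (ON-pathway) luminance-response model for b-wave
#' amplitude. Parameters are `G_b` (maximal Gaussian amplitude, uV), `B2`
#' (squared width of the Gaussian on the log-intensity axis), `V_bmax`
#' (maximal saturated amplitude, uV), `sigma_b` (semi-saturation strength,
#' phot cd.s.m^-2) and `mu` (peak flash strength, phot cd.s.m^-2).
#'
#' @slot params named numeric of the five parameters.
#' @slot se asymptotic standard errors (may be NA when unavailable).
#' @slot rss residual sum of squares (uV^2).
#' @slot converged logical.
#' @slot nStartsUsed number of optimiser starts attempted.
#' @slot data data.frame with columns `I` (linear flash strength) and `y` (uV).
#' @export
setClass("HillFit", representation(
  params = "numeric", se = "numeric", rss = "numeric",
  converged = "logical", nStartsUsed = "integer", data = "data.frame"))

#' @describeIn HillFit display parameters, SEs and fit diagnostics.
#' @param object a `HillFit`.
#' @export
setMethod("show", "HillFit", function(object) {
  cat("Photopic hill fit (", nrow(object@data), " points, ",
      if (object@converged) "converged" else "NOT converged",
      ", ", object@nStartsUsed, " starts, rss = ",
      format(object@rss, digits = 4), ")\n", sep = "")
  tab <- rbind(estimate = object@params, se = object@se)
  print(round(tab, 4))
  cat("log10(mu) =", round(log10(object@params[["mu"]]), 3), "\n")
})

#' @describeIn HillFit fitted parameter vector (includes derived `log10_mu`).
#' @export
setMethod("coef", "HillFit", function(object)
  c(object@params, log10_mu = log10(unname(object@params["mu"]))))

#' @rdname HillFit
#' @param x a `HillFit`.
#' @return `fittedCurve()`: data.frame of `I`, observed `y` and fitted `yhat`.
#' @export
setGeneric("fittedCurve", function(x) standardGeneric("fittedCurve"))

#' @rdname HillFit
#' @export
setMethod("fittedCurve", "HillFit", function(x) {
  d <- x@data
  d$yhat <- hillEval(x@params, d$I)
  d
})

#' Marginal (GEE) model fit
#'
#' Gaussian marginal regression for clustered ERG features estimated by
#' generalized estimating equations with an exchangeable or independence
#' working correlation, robust (sandwich) covariance clustered by participant,
#' per-term Wald tests and the Pan (2001) quasi-information criterion (QIC).
#'
#' @slot coefficients named numeric vector.
#' @slot vcovRobust robust (sandwich) covariance of the coefficients.
#' @slot vcovNaive model-based covariance.
#' @slot wald data.frame: term, df, chi-square statistic, p value.
#' @slot qic numeric QIC value.
#' @slot alphaHat estimated exchangeable correlation (0 under independence).
#' @slot phi estimated dispersion.
#' @slot nClusters integer.
#' @slot converged logical.
#' @slot call captured call details (dependent, terms, working correlation).
#' @export
setClass("MarginalFit", representation(
  coefficients = "numeric", vcovRobust = "matrix", vcovNaive = "matrix",
  wald = "data.frame", qic = "numeric", alphaHat = "numeric", phi = "numeric",
  nClusters = "integer", converged = "logical", call = "list"))

#' @describeIn MarginalFit display the Wald table and QIC.
#' @param object a `MarginalFit`.
#' @export
setMethod("show", "MarginalFit", function(object) {
  cat("Marginal (GEE) model: ", object@call$dependent, " ~ ",
      paste(object@call$terms, collapse = " + "), "\n", sep = "")
  cat(sprintf("  %d clusters | working correlation: %s (alpha = %.3f) | QIC = %.2f\n",
              object@nClusters, object@call$workingCorrelation,
              object@alphaHat, object@qic))
  w <- object@wald
  w$p <- format.pval(w$p, digits = 3)
  print(w, row.names = FALSE)
})

#' @describeIn MarginalFit coefficient vector.
#' @export
setMethod("coef", "MarginalFit", function(object) object@coefficients)

#' @describeIn MarginalFit robust (sandwich) covariance matrix.
#' @export
setMethod("vcov", "MarginalFit", function(object) object@vcovRobust)

#' @rdname MarginalFit
#' @param x a `MarginalFit`.
#' @return `waldTable()`: data.frame with one row per model term.
#' @export
setGeneric("waldTable", function(x) standardGeneric("waldTable"))

#' @rdname MarginalFit
#' @export
setMethod("waldTable", "MarginalFit", function(x) x@wald)

#' @rdname MarginalFit
#' @return `qic()`: the quasi-information criterion of the fit.
#' @export
setGeneric("qic", function(x) standardGeneric("qic"))

#' @rdname MarginalFit
#' @export
setMethod("qic", "MarginalFit", function(x) x@qic)

#' ROC analysis result
#'
#' Empirical ROC curve for discriminating a positive diagnostic group from
#' negative groups by a single ERG feature, with the rank (Mann-Whitney) AUC,
#' a Youden-optimal operating cut-off and its sensitivity/specificity.
#'
#' @slot auc area under the ROC curve.
#' @slot cutoff operating threshold, in feature units.
#' @slot sensitivity,specificity proportions at the cut-off.
#' @slot curve data.frame of (threshold, fpr, tpr) along the curve.
#' @slot positiveLabel label of the positive class.
#' @slot orientation `"higher-is-positive"` or `"lower-is-positive"`.
#' @export
setClass("ROCResult", representation(
  auc = "numeric", cutoff = "numeric", sensitivity = "numeric",
  specificity = "numeric", curve = "data.frame", positiveLabel = "character",
  orientation = "character"))

#' @describeIn ROCResult display AUC and operating point.
#' @param object a `ROCResult`.
#' @export
setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROC: positive = %s (%s)\n", object@positiveLabel,
              object@orientation))
  cat(sprintf("  AUC = %.3f | cutoff = %.3g | sensitivity = %.2f | specificity = %.2f\n",
              object@auc, object@cutoff, object@sensitivity, object@specificity))
})
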