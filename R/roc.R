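# ROC discrimination of diagnostic groups by a single ERG feature.

#' Rank (Mann-Whitney) AUC
#'
#' Area under the empirical ROC curve computed by the rank formulation:
#' the proportion of (positive, negative) pairs in which the positive scores
#' higher, with ties counted half. Identical to the trapezoidal area under
#' the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive by convention).
#' @param labels logical or 0/1 vector; TRUE/1 marks the positive class.
#' @return AUC in `[0, 1]`.
#' @examples
#' aucRank(c(3, 5, 1, 2, 4), c(TRUE, TRUE, FALSE, FALSE, FALSE))
#' @export
aucRank <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be non-empty")
  rk <- rank(scores)  # midranks handle ties with half weight
  (sum(rk[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Empirical ROC curve: thresholds at midpoints between distinct scores
# (plus +/-Inf sentinels); classification rule is score >= threshold.
.empiricalRoc <- function(scores, labels) {
  s <- sort(unique(scores))
  thr <- c(Inf, rev(if (length(s) > 1) (s[-1] + s[-length(s)]) / 2 else numeric(0)),
           -Inf)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  tpr <- vapply(thr, function(th) sum(scores[labels] >= th) / n_pos, 0)
  fpr <- vapply(thr, function(th) sum(scores[!labels] >= th) / n_neg, 0)
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

.trapezoidAuc <- function(curve) {
  o <- order(curve$fpr, curve$tpr)
  f <- curve$fpr[o]; t <- curve$tpr[o]
  sum(diff(f) * (head(t, -1) + tail(t, -1)) / 2)
}

#' ROC analysis of a feature at one flash strength
#'
#' Discriminates a positive diagnostic group from one or more negative groups
#' by a single ERG feature at a chosen flash, on participant-level
#' eye-averaged scores. The empirical ROC is computed over all distinct
#' thresholds, the AUC by the rank formulation, and the operating cut-off by
#' Youden's J (maximal sensitivity + specificity - 1; the
#' `"closest-topleft"` criterion minimises the distance to the (0, 1)
#' corner instead). Orientation is auto-detected from the class means: if the
#' positive group scores lower on average, the rule `score <= cutoff` is
#' positive, and the reported curve refers to the negated scores.
#'
#' @param table feature table ([buildFeatureTable()]).
#' @param dependent feature column.
#' @param flash log flash strength.
#' @param positive positive group label (e.g. `"ADHD"`).
#' @param negative character vector of negative group labels.
#' @param criterion cut-off criterion: `"youden"` or `"closest-topleft"`.
#' @return a [ROCResult-class].
#' @export
rocWithCutoff <- function(table, dependent = "b_amp", flash = 1.204,
                          positive = "ADHD", negative = c("CTL", "ASD"),
                          criterion = c("youden", "closest-topleft")) {
  criterion <- match.arg(criterion)
  agg <- .eyeAverage(table, dependent, flash)
  agg <- agg[agg$group %in% c(positive, negative), , drop = FALSE]
  if (!any(agg$group == positive) || !any(agg$group %in% negative))
    stop("positive and negative groups must both be present at flash ", flash)
  scores <- agg[[dependent]]
  labels <- agg$group == positive
  if (length(unique(scores)) < 2)
    stop("degenerate ROC: fewer than 2 distinct scores")

  higher_pos <- mean(scores[labels]) >= mean(scores[!labels])
  s <- if (higher_pos) scores else -scores
  curve <- .empiricalRoc(s, labels)
  auc <- aucRank(s, labels)
  j <- switch(criterion,
              youden = which.max(curve$tpr - curve$fpr),
              `closest-topleft` = which.min(curve$fpr^2 + (1 - curve$tpr)^2))
  thr <- curve$threshold[j]
  cutoff <- if (higher_pos) thr else -thr
  new("ROCResult", auc = auc, cutoff = cutoff,
      sensitivity = curve$tpr[j], specificity = 1 - curve$fpr[j],
      curve = curve, positiveLabel = positive,
      orientation = if (higher_pos) "higher-is-positive" else "lower-is-positive")
}
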