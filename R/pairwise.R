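# Nonparametric pairwise group comparisons per flash, and the
# feature-phenotype rank-correlation matrix.

.eyeAverage <- function(table, dependent, flash = NULL) {
  tab <- table
  if (!is.null(flash))
    tab <- tab[abs(tab$log_flash - flash) < 1e-9, , drop = FALSE]
  if (!nrow(tab)) return(tab[, c("participant_id", "group"), drop = FALSE])
  agg <- stats::aggregate(tab[[dependent]],
                          by = list(participant_id = tab$participant_id,
                                    group = tab$group,
                                    log_flash = tab$log_flash),
                          FUN = mean, na.rm = TRUE)
  names(agg)[4] <- dependent
  agg
}

#' Pairwise rank-sum group comparisons per flash
#'
#' For each flash strength and each pair of groups, a two-sided Wilcoxon
#' rank-sum test on participant-level eye-averaged feature values (eyes are
#' averaged so clusters are not double-counted). Exact p-values are used for
#' small tie-free samples (the `stats::wilcox.test` exact rule), the normal
#' approximation otherwise. P-values are adjusted across all tested
#' (flash, pair) combinations; the adjustment family and method are
#' configurable.
#'
#' @param table feature table ([buildFeatureTable()]).
#' @param dependent feature column name.
#' @param flashes log flash strengths to test (default: all in the table).
#' @param alpha significance level for the flags (default 0.005).
#' @param adjust multiplicity adjustment method (see [stats::p.adjust()]).
#' @param family `"all"` adjusts across every tested pair and flash;
#'   `"per-flash"` adjusts within each flash only.
#' @return data.frame: log_flash, group1, group2, n1, n2, statistic, p,
#'   p_adj, significant.
#' @export
pairwiseGroupTests <- function(table, dependent = "b_amp", flashes = NULL,
                               alpha = 0.005, adjust = "holm",
                               family = c("all", "per-flash")) {
  family <- match.arg(family)
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(flashes)) flashes <- sort(unique(table$log_flash))
  rows <- list()
  for (fs in flashes) {
    agg <- .eyeAverage(table, dependent, fs)
    groups <- sort(unique(as.character(agg$group)))
    if (length(groups) < 2)
      stop("need >= 2 groups with observations at flash ", fs)
    for (i in seq_len(length(groups) - 1)) for (j in (i + 1):length(groups)) {
      x <- agg[[dependent]][agg$group == groups[i]]
      z <- agg[[dependent]][agg$group == groups[j]]
      if (!length(x) || !length(z))
        stop("empty group at flash ", fs)
      wt <- suppressWarnings(wilcox.test(x, z, exact = NULL))
      rows[[length(rows) + 1L]] <- data.frame(
        log_flash = fs, group1 = groups[i], group2 = groups[j],
        n1 = length(x), n2 = length(z),
        statistic = unname(wt$statistic), p = wt$p.value)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- if (family == "all") p.adjust(out$p, method = adjust) else
    ave(out$p, out$log_flash, FUN = function(p) p.adjust(p, method = adjust))
  out$significant <- out$p_adj < alpha
  out
}

#' Feature-phenotype rank correlation matrix
#'
#' Spearman correlations between participant-level ERG features (eye- and
#' flash-averaged, or at a single flash) and phenotype/covariate columns,
#' with p-values and a significance flag. Constant columns yield an
#' `NA`-flagged entry rather than an error.
#'
#' @param table feature table with phenotype columns joined.
#' @param phenotypes character vector of phenotype column names.
#' @param features character vector of feature columns (defaults to the nine
#'   waveform parameters).
#' @param flash optional single log flash strength to restrict to.
#' @param alpha flag level (default 0.005).
#' @return data.frame: feature, phenotype, rho, p, n, significant (NA rho
#'   rows are flagged `undefined`).
#' @export
correlationNetwork <- function(table, phenotypes,
                               features = c("a_amp", "a_time", "b_amp",
                                            "b_time", "p72", "phnr_min",
                                            "t_min", "p_ratio", "w_ratio"),
                               flash = NULL, alpha = 0.005) {
  tab <- table
  if (!is.null(flash))
    tab <- tab[abs(tab$log_flash - flash) < 1e-9, , drop = FALSE]
  miss <- setdiff(c(phenotypes, features), colnames(tab))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  # participant-level summaries
  agg <- stats::aggregate(tab[, features, drop = FALSE],
                          by = list(participant_id = tab$participant_id),
                          FUN = mean, na.rm = TRUE)
  ph <- tab[!duplicated(tab$participant_id),
            c("participant_id", phenotypes), drop = FALSE]
  m <- merge(agg, ph, by = "participant_id")
  rows <- list()
  for (f in features) for (p in phenotypes) {
    ok <- is.finite(m[[f]]) & is.finite(suppressWarnings(as.numeric(m[[p]])))
    x <- m[[f]][ok]; z <- as.numeric(m[[p]])[ok]
    if (sum(ok) < 3 || sd(x) == 0 || sd(z) == 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, phenotype = p, rho = NA_real_, p = NA_real_,
        n = sum(ok), significant = NA, undefined = TRUE)
      next
    }
    ct <- suppressWarnings(cor.test(x, z, method = "spearman"))
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, phenotype = p, rho = unname(ct$estimate),
      p = ct$p.value, n = sum(ok), significant = ct$p.value < alpha,
      undefined = FALSE)
  }
  do.call(rbind, rows)
}
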