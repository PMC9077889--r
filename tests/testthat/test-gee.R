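# Oracles: with one observation per cluster and independence working
# correlation the GEE reduces to OLS, and the classic sandwich to the
# cluster-robust HC0 covariance, both available independently.

singletonTable <- function(n = 60, seed = 2) {
  set.seed(seed)
  data.frame(participant_id = sprintf("P%03d", seq_len(n)),
             group = sample(c("ADHD", "CTL", "ASD"), n, replace = TRUE),
             eye = "left", log_flash = 1.204,
             age = runif(n, 6, 25),
             y = rnorm(n, 30, 8))
}

test_that("with singleton clusters the estimator reduces to least squares", {
  tab <- singletonTable()
  fit <- fitMarginalModel(tab, dependent = "y", terms = c("G", "A"),
                          workingCorrelation = "independence",
                          sandwichType = "classic")
  ref <- lm(y ~ G + A, data = data.frame(y = tab$y, G = factor(tab$group),
                                         A = tab$age))
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-8)
  skip_if_not_installed("sandwich")
  vc <- sandwich::vcovCL(ref, cluster = tab$participant_id, type = "HC0",
                         cadjust = FALSE)
  expect_equal(unname(vcov(fit)), unname(vc), tolerance = 1e-6)
})

test_that("exchangeable and independence estimates agree on balanced data", {
  set.seed(4)
  tab <- simulateClusteredFeatures(nPerGroup = c(ADHD = 20, CTL = 20, ASD = 20),
                                   covariates = FALSE)
  f1 <- fitMarginalModel(tab, dependent = "y", terms = c("FS", "G"),
                         workingCorrelation = "exchangeable")
  f2 <- fitMarginalModel(tab, dependent = "y", terms = c("FS", "G"),
                         workingCorrelation = "independence")
  expect_equal(coef(f1), coef(f2), tolerance = 1e-6)
  expect_equal(f2@alphaHat, 0)
})

test_that("the exchangeable correlation estimate is consistent", {
  set.seed(6)
  tab <- simulateClusteredFeatures(nPerGroup = c(ADHD = 40, CTL = 40, ASD = 40),
                                   icc = 0.5, covariates = FALSE)
  fit <- fitMarginalModel(tab, dependent = "y", terms = c("FS", "G"))
  expect_lt(abs(fit@alphaHat - 0.5), 0.1)
  tab0 <- simulateClusteredFeatures(nPerGroup = c(ADHD = 40, CTL = 40, ASD = 40),
                                    icc = 0, covariates = FALSE)
  fit0 <- fitMarginalModel(tab0, dependent = "y", terms = c("FS", "G"))
  expect_lt(fit0@alphaHat, 0.06)
})

test_that("interaction degrees of freedom follow the factor levels", {
  ft <- defaultFeatureTableFixture()
  fit <- fitMarginalModel(ft, dependent = "b_amp")
  w <- waldTable(fit)
  expect_equal(w$df[w$term == "FS:G"], (10 - 1) * (3 - 1))
  expect_equal(w$df[w$term == "FS"], 9)
  expect_equal(w$df2[w$term == "FS:G"], fit@nClusters - 18 + 1)
  expect_true(all(w$p >= 0 & w$p <= 1))
  expect_true(all(sqrt(diag(vcov(fit))) >= 0))
  expect_equal(fit@nClusters, 131L)
})

test_that("the calibrated group separation is detected in b-wave amplitude", {
  ft <- defaultFeatureTableFixture()
  fit <- fitMarginalModel(ft, dependent = "b_amp")
  w <- waldTable(fit)
  expect_lt(w$p[w$term == "FS:G"], 0.005)
})

test_that("rank-deficient designs fail loudly naming the aliased term", {
  tab <- singletonTable()
  tab$iris <- 1.2  # constant column aliases the intercept
  expect_error(fitMarginalModel(tab, dependent = "y", terms = c("G", "iris")),
               "aliased.*iris")
})

test_that("a single cluster is rejected", {
  tab <- singletonTable(n = 20)
  tab$participant_id <- "P001"
  expect_error(fitMarginalModel(tab, dependent = "y", terms = c("A")),
               "clusters")
})

test_that("QIC is deterministic and matches a brute-force evaluation", {
  tab <- singletonTable(n = 10, seed = 9)
  fit1 <- fitMarginalModel(tab, dependent = "y", terms = c("A"),
                           workingCorrelation = "independence",
                           sandwichType = "classic")
  fit2 <- fitMarginalModel(tab, dependent = "y", terms = c("A"),
                           workingCorrelation = "independence",
                           sandwichType = "classic")
  expect_identical(computeQIC(fit1), computeQIC(fit2))

  # brute force from first principles: OLS residuals, Gaussian
  # quasi-likelihood, independence information, HC0 sandwich
  X <- cbind(1, tab$age)
  beta <- solve(crossprod(X), crossprod(X, tab$y))
  r <- tab$y - X %*% beta
  phi <- sum(r^2) / (nrow(X) - 2)
  quasi <- -sum(r^2) / (2 * phi)
  A <- crossprod(X) / phi
  meat <- matrix(0, 2, 2)
  for (i in seq_len(nrow(X))) {
    u <- X[i, ] * r[i] / phi
    meat <- meat + tcrossprod(u)
  }
  Vr <- solve(A) %*% meat %*% solve(A)
  qic_manual <- -2 * quasi + 2 * sum(diag(A %*% Vr))
  expect_equal(computeQIC(fit1), qic_manual, tolerance = 1e-8)
})

test_that("unknown terms and missing columns are reported", {
  tab <- singletonTable()
  expect_error(fitMarginalModel(tab, dependent = "y", terms = c("XX")),
               "unknown")
  expect_error(fitMarginalModel(tab, dependent = "b_amp", terms = c("G")),
               "lacks")
})
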