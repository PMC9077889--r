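refp <- referenceHillParams()
ctl <- unlist(refp[refp$group == "CTL", -1])
adhd <- unlist(refp[refp$group == "ADHD", -1])
nineI <- 10^defaultFlashProtocol(include_la3 = FALSE)$log_strength

test_that("the Gaussian component equals G_b at the peak flash strength", {
  for (g in seq_len(nrow(refp))) {
    p <- unlist(refp[g, -1])
    gauss <- hillEval(p, p[["mu"]]) -
      p[["V_bmax"]] * p[["mu"]] / (p[["mu"]] + p[["sigma_b"]])
    expect_equal(gauss, p[["G_b"]], tolerance = 1e-12)
  }
})

test_that("hand evaluation of the control curve at its peak is reproduced", {
  expect_equal(hillEval(ctl, 2.49), 10.08 + 30.24 * 2.49 / 3.19,
               tolerance = 1e-3)
  expect_equal(hillEval(ctl, 2.49), 33.68, tolerance = 1e-2)
})

test_that("the response vanishes as flash strength goes to zero", {
  expect_lt(hillEval(ctl, 1e-10), 1e-6)
  expect_error(hillEval(ctl, 0), "positive")
  expect_error(hillEval(ctl, -1), "positive")
})

test_that("the printed power form equals the log-Gaussian form", {
  set.seed(8)
  for (i in 1:50) {
    I <- 10^runif(1, -1, 1.5); mu <- runif(1, 0.5, 5); B2 <- runif(1, 0.1, 3)
    power_form <- (I / mu)^(log(mu / I) / B2)
    gauss_form <- exp(-log(I / mu)^2 / B2)
    expect_equal(power_form, gauss_form, tolerance = 1e-12)
  }
})

test_that("the Gaussian component is symmetric in log intensity about mu", {
  p <- adhd
  p[["V_bmax"]] <- 0
  for (d in c(0.3, 0.9)) {
    expect_equal(hillEval(p, p[["mu"]] * exp(d)),
                 hillEval(p, p[["mu"]] * exp(-d)), tolerance = 1e-12)
  }
})

test_that("the saturating component increases strictly and is bounded", {
  p <- ctl; p[["G_b"]] <- 0
  I <- sort(10^seq(-2, 3, length.out = 50))
  y <- hillEval(p, I)
  expect_true(all(diff(y) > 0))
  expect_true(all(y < p[["V_bmax"]]))
})

test_that("noiseless nine-point curves refit to the generating parameters", {
  for (g in seq_len(nrow(refp))) {
    p <- unlist(refp[g, -1])
    fit <- fitHill(nineI, hillEval(p, nineI))
    expect_true(fit@converged)
    expect_lt(fit@rss, 1e-8)
    for (nm in names(p))
      expect_equal(fit@params[[nm]], p[[nm]], tolerance = 1e-3)
  }
})

test_that("derived log10(mu) matches the tabulated values", {
  fits <- lapply(seq_len(nrow(refp)), function(g) {
    p <- unlist(refp[g, -1])
    coef(fitHill(nineI, hillEval(p, nineI)))[["log10_mu"]]
  })
  expect_equal(round(fits[[1]], 3), 0.412)
  expect_equal(round(fits[[2]], 3), 0.396)
  expect_equal(round(fits[[3]], 3), 0.413)
})

test_that("random valid parameter sets are identifiable from nine points", {
  set.seed(15)
  for (i in 1:5) {
    p <- c(G_b = runif(1, 4, 20), B2 = runif(1, 0.3, 1.5),
           V_bmax = runif(1, 15, 45), sigma_b = runif(1, 0.3, 1.2),
           mu = runif(1, 1.2, 4))
    fit <- fitHill(nineI, hillEval(p, nineI))
    for (nm in names(p))
      expect_equal(fit@params[[nm]], p[[nm]], tolerance = 1e-3)
  }
})

test_that("under-determined curves are rejected", {
  expect_error(fitHill(nineI[1:4], hillEval(ctl, nineI[1:4])),
               "insufficient")
  expect_error(fitHill(rep(nineI[1], 9), rep(10, 9)), "insufficient")
})

test_that("group-level hill fits recover the configured amplitude ordering", {
  ft <- defaultFeatureTableFixture()
  fits <- fitGroupHills(ft, level = "group")
  expect_named(fits, c("ADHD", "ASD", "CTL"), ignore.order = TRUE)
  v <- vapply(fits, function(f) f@params[["V_bmax"]], numeric(1))
  expect_gt(v[["ADHD"]], v[["CTL"]])
  expect_gt(v[["CTL"]], v[["ASD"]])
})

test_that("a noiseless single-participant curve is recovered per participant", {
  y <- hillEval(adhd, nineI)
  tab <- data.frame(participant_id = "P1", group = "ADHD", eye = "left",
                    session = "baseline",
                    log_flash = log10(nineI), b_amp = y)
  fits <- fitGroupHills(tab, level = "participant")
  expect_length(fits, 1)
  expect_equal(fits$P1@params[["V_bmax"]], adhd[["V_bmax"]], tolerance = 1e-3)
  expect_identical(fitGroupHills(tab[0, ], level = "group"),
                   structure(list(), skipped = character(0)))
})

test_that("parameter comparison detects separated groups and flags bad input", {
  mkfit <- function(v) new("HillFit",
                           params = c(G_b = 10, B2 = 0.8, V_bmax = v,
                                      sigma_b = 0.7, mu = 2.5),
                           se = rep(NA_real_, 5), rss = 0, converged = TRUE,
                           nStartsUsed = 1L, data = data.frame())
  set.seed(3)
  fits <- c(lapply(rnorm(12, 30, 1), mkfit), lapply(rnorm(12, 35, 1), mkfit),
            lapply(rnorm(12, 25, 1), mkfit))
  names(fits) <- sprintf("P%02d", seq_along(fits))
  attr(fits, "group") <- setNames(rep(c("CTL", "ADHD", "ASD"), each = 12),
                                  names(fits))
  res <- compareHillParams(fits, "V_bmax")
  expect_lt(res$p, 0.005)
  expect_equal(res$df[1], 2)
  one <- fits[1:12]
  attr(one, "group") <- attr(fits, "group")[1:12]
  expect_error(compareHillParams(one, "V_bmax"), "2 groups")
  two <- fits[1:13]
  attr(two, "group") <- attr(fits, "group")[1:13]
  expect_error(compareHillParams(two, "V_bmax"), "fits")
})

test_that("the null distribution of the parameter comparison is calibrated", {
  mkfit <- function(v) new("HillFit",
                           params = c(G_b = 10, B2 = 0.8, V_bmax = v,
                                      sigma_b = 0.7, mu = 2.5),
                           se = rep(NA_real_, 5), rss = 0, converged = TRUE,
                           nStartsUsed = 1L, data = data.frame())
  set.seed(91)
  nrep <- 300
  rej <- logical(nrep)
  for (r in seq_len(nrep)) {
    fits <- lapply(rnorm(45, 30, 3), mkfit)
    names(fits) <- sprintf("P%02d", seq_along(fits))
    attr(fits, "group") <- setNames(rep(c("CTL", "ADHD", "ASD"), each = 15),
                                    names(fits))
    rej[r] <- compareHillParams(fits, "V_bmax")$p < 0.005
  }
  expect_lt(mean(rej), 0.005 + 3 * sqrt(0.005 * 0.995 / nrep))
})
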