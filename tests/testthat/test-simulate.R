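tt <- toyTime()

test_that("waveform synthesis is the kernel sum with optional seeded noise", {
  k0 <- kernelSet(a = list(amp = 0, peak = 15, width = 3.5),
                  b = list(amp = 0, peak = 30, shape = 6),
                  phnr = list(amp = 0, peak = 76, width = 8))
  expect_equal(synthesizeWaveform(k0, tt), rep(0, length(tt)))
  set.seed(5); v1 <- synthesizeWaveform(kernelSet(), tt, noise_sd = 2)
  set.seed(5); v2 <- synthesizeWaveform(kernelSet(), tt, noise_sd = 2)
  expect_identical(v1, v2)
  expect_false(identical(v1, synthesizeWaveform(kernelSet(), tt, noise_sd = 2)))
})

test_that("kernel validity is enforced", {
  expect_error(kernelSet(a = list(amp = -8, peak = 40, width = 3.5)), "peak")
  expect_error(kernelSet(b = list(amp = 30, peak = 30, shape = -1)), "positive")
  expect_error(kernelSet(a = list(amp = 2, peak = 15, width = 3)), "sign")
})

test_that("a pure b-wave kernel yields its amplitude as the extracted b-amp", {
  k <- kernelSet(a = list(amp = 0, peak = 15, width = 3.5),
                 b = list(amp = 30, peak = 30, shape = 6),
                 phnr = list(amp = 0, peak = 76, width = 8))
  f <- extractFeatures(synthesizeWaveform(k, tt), time = tt)
  expect_equal(f$b_amp, 30, tolerance = 0.3 / 30)
})

test_that("calibration reproduces reported ADHD feature targets", {
  k <- calibrateKernels(list(b_amp = 37.2, b_time = 30.6, p72 = -10.6),
                        time = tt)
  got <- attr(k, "achieved")
  expect_true(attr(k, "converged"))
  expect_equal(got$b_amp, 37.2, tolerance = 0.02)
  expect_equal(got$b_time, 30.6, tolerance = 0.5 / 30.6)
  expect_equal(got$p72, -10.6, tolerance = 0.05)
})

test_that("calibration is a fixed point of the extraction map", {
  k0 <- kernelSet(a = list(amp = -16, peak = 15.5, width = 3.5),
                  b = list(amp = 34, peak = 31, shape = 6),
                  phnr = list(amp = -11, peak = 76, width = 8))
  f0 <- extractFeatures(synthesizeWaveform(k0, tt), time = tt)
  k1 <- calibrateKernels(as.list(f0[c("a_amp", "a_time", "b_amp", "b_time",
                                      "p72", "phnr_min", "t_min")]),
                         time = tt)
  f1 <- attr(k1, "achieved")
  for (col in c("a_amp", "b_amp", "p72", "phnr_min"))
    expect_equal(f1[[col]], f0[[col]], tolerance = 0.08)
  for (col in c("a_time", "b_time", "t_min"))
    expect_equal(f1[[col]], f0[[col]], tolerance = 0.08)
})

test_that("shallow dim-flash a-wave targets still calibrate", {
  # sub-microvolt troughs do not pin their own timing; a-time is soft there
  f0 <- extractFeatures(synthesizeWaveform(kernelSet(), tt), time = tt)
  expect_lt(f0$a_amp, 1)
  k <- calibrateKernels(as.list(f0[c("a_amp", "a_time", "b_amp", "b_time",
                                     "p72", "phnr_min", "t_min")]),
                        time = tt)
  got <- attr(k, "achieved")
  expect_equal(got$a_amp, f0$a_amp, tolerance = 0.08)
  expect_equal(got$b_amp, f0$b_amp, tolerance = 0.08)
  expect_equal(got$b_time, f0$b_time, tolerance = 0.08)
})

test_that("infeasible calibration targets are rejected", {
  expect_error(calibrateKernels(list(b_amp = -5), time = tt), "infeasible")
  expect_error(calibrateKernels(list(b_amp = 30, t_min = 120), time = tt),
               "PhNR window")
  expect_error(calibrateKernels(list(b_amp = 30, p72 = -5, phnr_min = -2),
                                time = tt), "phnr_min")
})

test_that("calibration converges over a range of feasible targets", {
  set.seed(21)
  for (i in 1:10) {
    tg <- list(a_amp = runif(1, 1, 9), a_time = runif(1, 13, 17),
               b_amp = runif(1, 12, 45), b_time = runif(1, 27, 33),
               p72 = -runif(1, 2, 12), t_min = runif(1, 74.5, 80))
    tg$phnr_min <- tg$p72 * 1.15
    k <- calibrateKernels(tg, time = tt)
    expect_true(attr(k, "converged"))
    got <- attr(k, "achieved")
    expect_equal(got$b_amp, tg$b_amp, tolerance = 0.06)
    expect_equal(got$b_time, tg$b_time, tolerance = 0.06)
  }
})

test_that("the default cohort has the configured size and structure", {
  co <- defaultCohortFixture()
  pd <- participantData(co)
  expect_equal(nrow(pd), 131)
  expect_equal(as.vector(table(pd$group)[c("ADHD", "CTL", "ASD")]),
               c(15, 59, 57))
  expect_equal(ncol(co), 131 * 2 * 10)
  expect_true(validObject(co))
  expect_true(all(pd$age > 0))
  expect_true(all(pd$iris > 0))
  expect_true(all(pd$electrode_vert_mm >= 0))
})

test_that("identical configuration and seed give byte-identical cohorts", {
  cfg <- defaultSimConfig(nPerGroup = c(ADHD = 3, CTL = 3, ASD = 3),
                          protocol = defaultFlashProtocol()[8:10, ],
                          seed = 77)
  c1 <- simulateCohort(cfg)
  c2 <- simulateCohort(cfg)
  expect_identical(voltageMatrix(c1), voltageMatrix(c2))
  expect_identical(as.data.frame(SummarizedExperiment::colData(c1)),
                   as.data.frame(SummarizedExperiment::colData(c2)))
})

test_that("within-participant eye correlation matches the configured rho", {
  cfg <- defaultSimConfig(nPerGroup = c(ADHD = 0, CTL = 400, ASD = 0),
                          protocol = defaultFlashProtocol()[10, ],
                          noiseSd = 0, seed = 33)
  ft <- buildFeatureTable(simulateCohort(cfg))
  wide <- reshape(ft[, c("participant_id", "eye", "b_amp")],
                  idvar = "participant_id", timevar = "eye",
                  direction = "wide")
  r <- cor(wide$b_amp.left, wide$b_amp.right)
  se <- (1 - 0.7^2) / sqrt(nrow(wide))
  expect_lt(abs(r - 0.7), 3 * se + 0.02)
})

test_that("pre-stimulus voltage standard deviation matches the noise level", {
  cfg <- defaultSimConfig(nPerGroup = c(ADHD = 0, CTL = 40, ASD = 0),
                          protocol = defaultFlashProtocol()[10, ],
                          noiseSd = 1.5, seed = 34)
  co <- simulateCohort(cfg)
  pre <- voltageMatrix(co)[timeGrid(co) < -2, ]
  sds <- apply(pre, 2, sd)
  se <- 1.5 / sqrt(2 * (nrow(pre) - 1))
  expect_lt(abs(mean(sds) - 1.5), 3 * se / sqrt(ncol(pre)) + 0.02)
})

test_that("group profiles anchor to the reported means and hill curves", {
  prof <- defaultGroupProfiles()
  at <- function(g, fs, col) prof[prof$group == g &
                                    abs(prof$log_flash - fs) < 1e-9, col]
  expect_equal(at("ADHD", 1.204, "b_amp"), 37.2)
  expect_equal(at("CTL", 1.204, "b_amp"), 28.2)
  expect_equal(at("ASD", 1.204, "b_amp"), 24.7)
  expect_equal(at("ADHD", 1.204, "b_time"), 30.6)
  expect_equal(at("ADHD", 1.114, "p72"), -10.6)
  # elsewhere b-amp follows the group's reference hill curve
  hp <- unlist(referenceHillParams()[1, -1])
  expect_equal(at("ADHD", 0.602, "b_amp"), hillEval(hp, 10^0.602))
  # b-time drifts later with flash strength
  bt <- prof[prof$group == "ASD", ]
  expect_true(all(diff(bt$b_time[order(bt$log_flash)]) > 0))
  # a-amp grows monotonically with strength
  aa <- prof[prof$group == "CTL", ]
  expect_true(all(diff(aa$a_amp[order(aa$log_flash)]) > 0))
})
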