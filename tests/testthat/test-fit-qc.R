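# Modulus fitting and curve quality control.

test_that("noiseless curves recover the true modulus essentially exactly,
          matching the closed-form inversion at every sample", {
  for (E in c(171, 250, 1250)) {
    fit <- analyzeCurve(simulateForceCurve(E = E, noiseSD = 0))
    expect_identical(qcStatus(fit), "pass")
    expect_lt(abs(modulus(fit) - E) / E, 1e-4)
    expect_equal(linearity(fit), 1, tolerance = 1e-9)
  }
  # per-sample oracle equivalence: E from each (delta, F) pair
  fc <- simulateForceCurve(E = 250, noiseSD = 0)
  cb <- correctBaseline(fc)
  ind <- toIndentation(cb, z0 = findContactPoint(cb)$z0)
  keep <- indentation(ind) > 0.1
  Epts <- 3 * (force(ind)[keep] * 1e-9) /
    (4 * sqrt(18.64e-6) * (indentation(ind)[keep] * 1e-6)^1.5)
  expect_equal(Epts, rep(250, sum(keep)), tolerance = 1e-6)
})

test_that("stiff curves that stop short of the evaluation depth are fitted
          shallow, not discarded", {
  fit <- analyzeCurve(simulateForceCurve(E = 1250, noiseSD = 0))
  expect_true(fit@shallow)
  expect_identical(qcStatus(fit), "pass")
  expect_lt(abs(modulus(fit) - 1250) / 1250, 1e-4)
})

test_that("the single-point estimate agrees with the regression estimate on
          clean curves", {
  fit <- analyzeCurve(simulateForceCurve(E = 300, noiseSD = 0))
  expect_equal(fit@EaSinglePoint, modulus(fit), tolerance = 1e-4)
})

test_that("median modulus over noisy curves stays within 5% of truth", {
  Es <- vapply(1:100, function(s) {
    fit <- analyzeCurve(simulateForceCurve(E = 250, noiseSD = 2, seed = s))
    if (qcStatus(fit) == "pass") modulus(fit) else NA_real_
  }, numeric(1))
  expect_lt(abs(median(Es, na.rm = TRUE) - 250) / 250, 0.05)
})

test_that("pure noise around zero is failed", {
  z <- seq(0, 10, by = 0.01)
  set.seed(42)
  noise <- rawCurve(z, rnorm(length(z), 0, 2))
  fit <- analyzeCurve(noise)
  expect_identical(qcStatus(fit), "failed")
})

test_that("labelled slip and drift artifacts are failed with informative
          reasons", {
  slip <- analyzeCurve(simulateForceCurve(E = 400, failureMode = "slip",
                                          noiseSD = 2, seed = 13))
  expect_identical(qcStatus(slip), "failed")
  expect_true(qcReason(slip) %in% c("slip", "nonlinearity"))
  drift <- analyzeCurve(simulateForceCurve(E = 400, failureMode = "drift",
                                           noiseSD = 2, seed = 13))
  expect_identical(qcStatus(drift), "failed")
})

test_that("curves with fewer than 10 contact samples fail as
          insufficient_data", {
  z <- seq(0, 10, by = 0.1)
  d <- ifelse(z < 9.8, 0, (z - 9.8) * 500)
  fit <- fitModulus(toIndentation(rawCurve(z, d), z0 = 9.8))
  expect_identical(qcStatus(fit), "failed")
  expect_identical(qcReason(fit), "insufficient_data")
})

test_that("miscalibration propagates linearly: scaling k scales E_a", {
  fc <- simulateForceCurve(E = 300, k = 0.03, noiseSD = 0)
  cb <- correctBaseline(fc)
  z0 <- findContactPoint(cb)$z0
  base <- fitModulus(toIndentation(cb, z0 = z0))
  wrong <- new("CantileverCalibration", k = 0.06,
               method = "thermal_equipartition", temperature = 295,
               nSamples = 1000, variance = kB * 295 / 0.06)
  scaled <- fitModulus(toIndentation(cb, calibration = wrong, z0 = z0))
  expect_equal(modulus(scaled) / modulus(base), 2, tolerance = 1e-3)
})

test_that("QC discriminates slip from clean curves at default thresholds", {
  nSlip <- sum(vapply(1:60, function(s) {
    qcStatus(analyzeCurve(simulateForceCurve(E = 300, failureMode = "slip",
                                             noiseSD = 2, seed = s))) ==
      "failed"
  }, logical(1)))
  nClean <- sum(vapply(1:60, function(s) {
    qcStatus(analyzeCurve(simulateForceCurve(E = 300, noiseSD = 2,
                                             seed = 6000 + s))) == "failed"
  }, logical(1)))
  expect_gte(nSlip / 60, 0.95)
  expect_lte(nClean / 60, 0.05)
})
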