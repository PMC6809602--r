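# Baseline correction, contact-point detection, indentation conversion.

test_that("a pure linear baseline is removed exactly", {
  fc <- simulateForceCurve(E = 500, z0 = 5, noiseSD = 0,
                           baselineSlope = 0.5)
  cb <- correctBaseline(fc)
  app <- segmentLabels(cb) == "approach"
  pre <- zPosition(cb)[app] < 5
  expect_lt(max(abs(deflection(cb)[app][pre])), 1e-9)
})

test_that("baseline correction is a no-op on an already clean curve", {
  fc <- simulateForceCurve(E = 500, z0 = 5, noiseSD = 0)
  cb <- correctBaseline(fc)
  expect_lt(max(abs(deflection(cb) - deflection(fc))), 1e-12)
})

test_that("a tilted curve recovers the same modulus as its untilted twin", {
  plain <- analyzeCurve(simulateForceCurve(E = 400, noiseSD = 0))
  tilted <- analyzeCurve(simulateForceCurve(E = 400, noiseSD = 0,
                                            baselineSlope = 1.5))
  expect_lt(abs(modulus(tilted) - modulus(plain)) / modulus(plain), 0.01)
})

test_that("baseline correction refuses curves shorter than the fit window", {
  short <- rawCurve(z = seq(0, 0.4, by = 0.01), d = rep(0, 41))
  expect_error(correctBaseline(short), "at least 50")
})

test_that("the contact point of a noiseless curve is recovered to within
          one sampling step", {
  for (z0 in c(3, 5, 8)) {
    fc <- simulateForceCurve(E = 300, z0 = z0, dz = 0.01, noiseSD = 0)
    cp <- findContactPoint(fc)  # curve is already baseline-free
    expect_equal(cp$status, "ok")
    expect_lte(abs(cp$z0 - z0), 0.01 + 1e-9)
  }
})

test_that("an all-zero deflection curve reports no contact", {
  flat <- rawCurve(z = seq(0, 10, by = 0.01), d = rep(0, 1001))
  expect_identical(findContactPoint(flat)$status, "no_contact")
  fit <- analyzeCurve(flat)
  expect_identical(qcStatus(fit), "failed")
  expect_identical(qcReason(fit), "no_contact")
})

test_that("median contact-point error stays below five sampling steps at
          1 nm noise", {
  errs <- vapply(1:100, function(s) {
    fc <- simulateForceCurve(E = 300, z0 = 5, dz = 0.01, noiseSD = 1,
                             seed = s)
    cp <- findContactPoint(correctBaseline(fc))
    abs(cp$z0 - 5)
  }, numeric(1))
  expect_lt(median(errs), 5 * 0.01)
})

test_that("force is spring constant times deflection", {
  z <- seq(0, 10, by = 0.01)
  d <- c(rep(0, 500), seq(0, 100, length.out = 501))
  fc <- rawCurve(z, d, k = 0.05)
  ind <- toIndentation(fc, z0 = 5)
  expect_equal(max(force(ind)), 0.05 * 100)  # 100 nm at 0.05 N/m -> 5 nN
})

test_that("a rigid surface yields near-zero indentation throughout contact", {
  z <- seq(0, 10, by = 0.01)
  d <- ifelse(z < 5, 0, (z - 5) * 1000)  # nm rises one-for-one with z (um)
  fc <- rawCurve(z, d)
  ind <- toIndentation(fc, z0 = 5)
  expect_lt(max(abs(indentation(ind))), 1e-9)
})

test_that("processed (delta, F) pairs satisfy the generator's ground-truth
          Hertz relation", {
  fc <- simulateForceCurve(E = 777, z0 = 5, noiseSD = 0)
  cb <- correctBaseline(fc)
  ind <- toIndentation(cb, z0 = findContactPoint(cb)$z0)
  keep <- indentation(ind) > 0.05  # avoid 0/0 at contact onset
  expect_equal(force(ind)[keep],
               oracleHertzForce_nN(777, 18.64, indentation(ind)[keep]),
               tolerance = 1e-6)
})

test_that("indentation is non-decreasing along a noiseless contact region", {
  fc <- simulateForceCurve(E = 250, noiseSD = 0)
  cb <- correctBaseline(fc)
  ind <- toIndentation(cb, z0 = findContactPoint(cb)$z0)
  expect_true(all(diff(indentation(ind)) >= -1e-12))
})

test_that("an external calibration substitutes for probe metadata", {
  fc <- simulateForceCurve(E = 300, noiseSD = 0)
  fc@springConstant <- NA_real_
  cb <- correctBaseline(fc)
  z0 <- findContactPoint(cb)$z0
  expect_error(toIndentation(cb, z0 = z0), "spring constant")
  cal <- new("CantileverCalibration", k = 0.03,
             method = "thermal_equipartition", temperature = 295,
             nSamples = 1000, variance = kB * 295 / 0.03)
  ind <- toIndentation(cb, calibration = cal, z0 = z0)
  expect_equal(springConstant(ind), 0.03)
})
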