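# Synthetic force curves, thermal series, and tissue fields.

test_that("noiseless curves satisfy the closed-form Hertz inversion at the
          final approach sample", {
  for (E in c(171, 1250)) {
    fc <- simulateForceCurve(E = E, noiseSD = 0)
    app <- segmentLabels(fc) == "approach"
    dFinal <- deflection(fc)[app][sum(app)]
    FFinal <- springConstant(fc) * dFinal       # nN = (N/m) * nm
    expect_equal(groundTruth(fc)$deltaFinal,
                 oracleDelta_um(FFinal, E, probeRadius(fc)),
                 tolerance = 1e-6)
  }
})

test_that("approach stops at the trigger and never overshoots by more than
          one sampling step's force increment", {
  fc <- simulateForceCurve(E = 800, noiseSD = 0, dz = 0.01, Fmax = 10)
  app <- segmentLabels(fc) == "approach"
  F <- springConstant(fc) * deflection(fc)[app]
  expect_true(max(F) >= 10)
  stepInc <- max(diff(F))
  expect_lte(max(F) - 10, stepInc + 1e-9)
  expect_true(all(F[-length(F)] < 10))
})

test_that("deflection is exactly zero before contact for a clean spec", {
  fc <- simulateForceCurve(E = 500, z0 = 5, noiseSD = 0, baselineSlope = 0)
  app <- segmentLabels(fc) == "approach"
  pre <- zPosition(fc)[app] < 5
  expect_true(all(deflection(fc)[app][pre] == 0))
})

test_that("identical spec and seed give bit-identical curves", {
  a <- simulateForceCurve(E = 250, noiseSD = 2, seed = 7)
  b <- simulateForceCurve(E = 250, noiseSD = 2, seed = 7)
  expect_identical(deflection(a), deflection(b))
  expect_identical(zPosition(a), zPosition(b))
  c <- simulateForceCurve(E = 250, noiseSD = 2, seed = 8)
  expect_false(identical(deflection(a), deflection(c)))
})

test_that("unreachable trigger errors name the limiting parameter", {
  expect_error(simulateForceCurve(E = 10, zRange = 8, z0 = 5),
               "zRange")
  expect_error(simulateForceCurve(E = 250, z0 = 20, zRange = 15),
               "z0")
})

test_that("thermal series has the equipartition variance and zero mean", {
  relErr <- vapply(1:20, function(s) {
    ts <- simulateThermalSeries(k = 0.03, temperature = 298, n = 1e4,
                                seed = s)
    v <- var(ts@samples * 1e-9)
    abs(v - kB * 298 / 0.03) / (kB * 298 / 0.03)
  }, numeric(1))
  expect_lt(median(relErr), 0.05)
  ts <- simulateThermalSeries(k = 0.03, temperature = 298, n = 1e5, seed = 1)
  expect_lt(abs(mean(ts@samples)) / sd(ts@samples), 0.02)
  expect_identical(simulateThermalSeries(0.05, n = 2000, seed = 3)@samples,
                   simulateThermalSeries(0.05, n = 2000, seed = 3)@samples)
  expect_error(simulateThermalSeries(0.05, temperature = -1), "positive")
  expect_error(simulateThermalSeries(0.05, n = 10), "1000")
})

test_that("tissue fields have one cell per grid square with the requested
          geometry", {
  fld <- simulateTissueField(extent = c(100, 100), cellSize = 20, seed = 1)
  expect_identical(dim(fld$truth), c(5L, 5L))
  expect_length(fld$curves, 25)
  expect_error(simulateTissueField(extent = c(10, 10), cellSize = 20),
               "extent")
})

test_that("degenerate background (logsd = 0, no inclusions) gives a
          constant field", {
  fld <- simulateTissueField(extent = c(60, 60), backgroundMedian = 300,
                             backgroundLogSD = 0, seed = 2)
  expect_true(all(fld$truth == 300))
})

test_that("inclusion override matches the geometric count of cell centers
          inside inclusions", {
  inc <- data.frame(x = 30, y = 30, radius = 25, E = 5000)
  fld <- simulateTissueField(extent = c(100, 100), backgroundMedian = 171,
                             backgroundLogSD = 0, inclusions = inc,
                             seed = 3)
  centers <- fld$centers
  inside <- (centers$x - 30)^2 + (centers$y - 30)^2 <= 25^2
  expect_equal(mean(fld$truth > 1000), mean(inside))
})

test_that("failProb marks cells whose curves carry the slip artifact", {
  fld <- simulateTissueField(extent = c(100, 100), failProb = 0.3, seed = 4)
  modes <- vapply(fld$curves, function(c) groundTruth(c)$failureMode,
                  character(1))
  expect_identical(sum(modes == "slip"), sum(fld$failed))
})
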