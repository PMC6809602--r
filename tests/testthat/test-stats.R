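# Aggregation, normality screen, nonparametric tests, dilution regression.

test_that("sample medians follow the midpoint-of-two convention", {
  expect_equal(modulus(summarizeSample(c(1, 2, 3))), 2)
  expect_equal(modulus(summarizeSample(c(1, 2, 3, 4))), 2.5)
  expect_error(summarizeSample(numeric(0)), "at least 1")
})

test_that("sampling medians concentrate around the lognormal median", {
  meds <- vapply(1:50, function(s) {
    withr::with_seed(s, modulus(summarizeSample(rlnorm(100, log(171), 0.86))))
  }, numeric(1))
  expect_lt(abs(median(meds) - 171) / 171, 0.15)
})

test_that("tissue summaries are the arithmetic mean of sample medians", {
  ss <- lapply(list(100, 200, 300), summarizeSample, tissue = "placenta")
  ts <- summarizeTissue(ss)
  expect_equal(modulus(ts), 200)
  expect_equal(ts@N, 3)
  one <- summarizeTissue(list(summarizeSample(c(5, 7, 9), tissue = "matrigel")))
  expect_equal(modulus(one), 7)
  gen <- lapply(c(1200, 1300, 1250, 1250, 1250), summarizeSample,
                tissue = "decidua_basalis")
  expect_equal(modulus(summarizeTissue(gen)), 1250)
  mixed <- list(summarizeSample(1:3, tissue = "placenta"),
                summarizeSample(1:3, tissue = "endometrium"))
  expect_error(summarizeTissue(mixed), "mix")
})

test_that("D'Agostino-Pearson K2 matches the reference implementation", {
  # frozen from scipy.stats.normaltest
  sq <- (1:30)^2
  r <- dagostinoPearsonTest(sq)
  expect_equal(r@statistic, 3.8582005415682414, tolerance = 1e-10)
  expect_equal(pValue(r), 0.14527885132570745, tolerance = 1e-10)
  sines <- sin(1:50)
  r2 <- dagostinoPearsonTest(sines)
  expect_equal(r2@statistic, 43.26765816707633, tolerance = 1e-10)
  expect_true(isSignificant(r2))
  expect_error(dagostinoPearsonTest(1:10), "20")
})

test_that("the normality screen keeps Gaussian data and rejects the
          lognormal moduli", {
  gauss <- withr::with_seed(1, rnorm(200))
  expect_false(isSignificant(dagostinoPearsonTest(gauss)))
  logn <- withr::with_seed(1, rlnorm(200, log(171), 0.86))
  expect_true(isSignificant(dagostinoPearsonTest(logn)))
})

test_that("Mann-Whitney on {1,2,3} vs {4,5,6} gives the enumerated exact
          two-sided p of 0.1", {
  r <- runComparison(list(a = 1:3, b = 4:6))
  expect_equal(pValue(r), 0.1, tolerance = 1e-12)
  expect_true(r@statistic %in% c(0, 9))  # one-sided U = 0 (or its mirror)
  expect_false(isSignificant(r))
  expect_true(r@details$exact)
})

test_that("two-sided p is invariant under group label swap", {
  x <- c(10.2, 15.1, 9.8, 12.7, 20.3, 11.1)
  y <- c(30.5, 25.2, 41.7, 28.8, 33.3)
  expect_equal(pValue(runComparison(list(a = x, b = y))),
               pValue(runComparison(list(b = y, a = x))))
})

test_that("identical groups are maximally non-significant", {
  x <- c(1, 2, 3, 4, 5)
  r <- runComparison(list(a = x, b = x))
  expect_gte(pValue(r), 0.99)
  expect_false(isSignificant(r))
})

test_that("undersized groups are refused with the minimum stated", {
  expect_error(runComparison(list(a = 1:2, b = 4:6)), "at least 3")
})

test_that("the paired signed-rank test requires equal lengths and detects a
          consistent shift", {
  expect_error(runComparison(list(a = 1:4, b = 1:5),
                             test = "wilcoxon_signed_rank"),
               "equal")
  x <- c(5, 7, 9, 11, 13, 15, 17, 19)
  r <- runComparison(list(before = x, after = x + 3),
                     test = "wilcoxon_signed_rank")
  expect_true(isSignificant(r))
})

test_that("Kruskal-Wallis/Dunn matches hand-derived z on untied groups", {
  r <- runComparison(list(a = 1:3, b = 4:6, c = 7:9),
                     test = "kruskal_wallis_dunn")
  # pooled ranks 1..9, mean ranks 2/5/8, sigma^2 = 9*10/12 = 7.5:
  # z_ab = -3 / sqrt(7.5 * 2/3) = -3/sqrt(5); z_ac = -6/sqrt(5)
  pw <- r@pairwise
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "b"], -3 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(pw$z[pw$group1 == "a" & pw$group2 == "c"], -6 / sqrt(5),
               tolerance = 1e-12)
  expect_equal(pw$p, 2 * pnorm(-abs(pw$z)), tolerance = 1e-12)
  expect_equal(pw$p_adjusted, p.adjust(pw$p, "holm"), tolerance = 1e-12)
  expect_equal(r@statistic,
               kruskal.test(list(1:3, 4:6, 7:9))$statistic[[1]])
})

test_that("Dunn comparisons separate well-separated tissues after Holm
          adjustment", {
  g <- withr::with_seed(4, list(
    basalis = rlnorm(40, log(1250), 0.86),
    parietalis = rlnorm(40, log(171), 0.86),
    endometrium = rlnorm(40, log(250), 0.86)))
  r <- runComparison(g, test = "kruskal_wallis_dunn")
  expect_true(isSignificant(r))
  pw <- r@pairwise
  pBP <- pw$p_adjusted[pw$group1 == "basalis" & pw$group2 == "parietalis"]
  expect_lt(pBP, 0.05)
})

test_that("significance stars follow the figure-caption convention", {
  expect_identical(significanceStars(2e-5), "****")
  expect_identical(significanceStars(5e-4), "***")
  expect_identical(significanceStars(0.004), "**")
  expect_identical(significanceStars(0.04), "*")
  expect_identical(significanceStars(0.2), "ns")
})

test_that("exact points on the printed dilution line are recovered
          perfectly", {
  x <- c(40, 60, 80, 100)
  f <- fitDilutionRegression(x, 4.5 * x - 111.3)
  expect_equal(f@slope, 4.5, tolerance = 1e-12)
  expect_equal(f@intercept, -111.3, tolerance = 1e-12)
  expect_equal(f@rSquared, 1, tolerance = 1e-12)
})

test_that("degenerate dilution inputs are handled", {
  expect_error(fitDilutionRegression(c(40, 40, 40), c(1, 2, 3)), "distinct")
  f <- fitDilutionRegression(c(40, 60, 80), c(5, 5, 5))
  expect_identical(f@slope, 0)
  expect_identical(f@rSquared, 0)
})

test_that("shifting concentrations shifts only the intercept", {
  x <- c(40, 60, 80, 100)
  y <- withr::with_seed(2, 4.5 * x - 111.3 + rnorm(4, 0, 10))
  f1 <- fitDilutionRegression(x, y)
  f2 <- fitDilutionRegression(x + 10, y)
  expect_equal(f2@slope, f1@slope, tolerance = 1e-10)
  expect_equal(f2@intercept, f1@intercept - 10 * f1@slope, tolerance = 1e-9)
})

test_that("the dilution slope is recovered from noisy batches", {
  slopes <- vapply(1:50, function(s) {
    withr::with_seed(s, {
      x <- rep(c(40, 60, 80, 100), times = 5)  # 5 batches x 4 dilutions
      y <- 4.5 * x - 111.3 + rnorm(length(x), 0, 30)
      fitDilutionRegression(x, y)@slope
    })
  }, numeric(1))
  expect_true(all(abs(slopes - 4.5) < 1.0))
})
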