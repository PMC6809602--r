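# Aggregation and comparison layer: per-sample medians, per-tissue mean of
# medians, D'Agostino-Pearson normality screen, nonparametric tests, and
# the hydrogel dilution regression.
#
# Standard tests go through stats:: (wilcox.test, kruskal.test, p.adjust,
# lm). The D'Agostino-Pearson omnibus test and Dunn's post-hoc are
# implemented here because no installed package provides them.

.tissueLabels <- c("decidua_basalis", "decidua_parietalis", "endometrium",
                   "placenta", "matrigel")

#' Summarise one sample: median of its passing measurements
#'
#' The per-sample estimator of the workflow: the median of all passing
#' modulus measurements taken on one patient sample (robust to the skewed,
#' heavy-tailed distributions tissue indentation produces). Even-length
#' samples use the midpoint-of-two convention.
#'
#' @param points numeric vector of passing E_a measurements (Pa).
#' @param sampleId sample identifier.
#' @param tissue tissue label.
#' @return A [SampleSummary-class].
#' @examples
#' modulus(summarizeSample(c(1, 2, 3, 4), "s1", "endometrium"))  # 2.5
#' @export
summarizeSample <- function(points, sampleId = "sample",
                            tissue = "unknown") {
  if (length(points) < 1) stop("a sample needs at least 1 passing measurement")
  if (anyNA(points)) stop("points must not contain NA; drop failed curves first")
  new("SampleSummary", sampleId = as.character(sampleId),
      tissue = as.character(tissue), points = as.numeric(points),
      median = stats::median(points), n = length(points))
}

#' Summarise one tissue: arithmetic mean of its sample medians
#'
#' The per-tissue estimator: each sample contributes its median once, and
#' the tissue value is the arithmetic mean of those medians (so samples
#' with many measurement points do not dominate).
#'
#' @param samples list of [SampleSummary-class] objects, all of one tissue.
#' @return A [TissueSummary-class].
#' @examples
#' ss <- lapply(list(c(100), c(200), c(300)), summarizeSample,
#'              tissue = "placenta")
#' modulus(summarizeTissue(ss))  # 200
#' @export
summarizeTissue <- function(samples) {
  stopifnot(length(samples) >= 1,
            all(vapply(samples, is, logical(1), "SampleSummary")))
  tissues <- vapply(samples, function(s) s@tissue, character(1))
  if (length(unique(tissues)) != 1)
    stop("samples mix tissues (", paste(unique(tissues), collapse = ", "),
         "); summarise one tissue at a time")
  med <- vapply(samples, function(s) s@median, numeric(1))
  new("TissueSummary", tissue = tissues[1], sampleMedians = med,
      meanOfMedians = mean(med), N = length(med),
      nTotal = sum(vapply(samples, function(s) s@n, numeric(1))))
}

# --- D'Agostino-Pearson omnibus normality test -----------------------------
# Skewness transform (D'Agostino 1970) and kurtosis transform
# (Anscombe & Glynn 1983); K2 = Zg1^2 + Zg2^2 ~ chi^2(2) under normality.

.skewnessZ <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  g1 <- mean((x - m)^3) / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  delta * asinh(y / alpha)
}

.kurtosisZ <- function(x) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  b2 <- mean((x - m)^4) / m2^2
  Eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xs <- (b2 - Eb2) / sqrt(vb2)
  sb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sb1 * (2 / sb1 + sqrt(1 + 4 / sb1^2))
  denom <- 1 + xs * sqrt(2 / (A - 4))
  term <- sign(denom) * ((1 - 2 / A) / abs(denom))^(1 / 3)
  (1 - 2 / (9 * A) - term) / sqrt(2 / (9 * A))
}

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the transformed sample skewness and kurtosis into
#' \eqn{K^2 = Z_{g_1}^2 + Z_{g_2}^2}, referred to a chi-squared
#' distribution with 2 df. Used as the normality screen that decides
#' whether nonparametric tests are required.
#'
#' @param x numeric vector, at least 20 observations.
#' @param alpha significance level.
#' @return A [GroupComparison-class] with `test = "dagostino_pearson"`;
#'   a small p-value means the data are inconsistent with normality.
#' @examples
#' dagostinoPearsonTest(rlnorm(50))  # lognormal data: rejects normality
#' @export
dagostinoPearsonTest <- function(x, alpha = 0.05) {
  if (length(x) < 20)
    stop("the D'Agostino-Pearson test needs at least 20 observations")
  if (stats::var(x) == 0) stop("constant data cannot be tested for normality")
  K2 <- .skewnessZ(x)^2 + .kurtosisZ(x)^2
  p <- stats::pchisq(K2, df = 2, lower.tail = FALSE)
  new("GroupComparison", test = "dagostino_pearson", groups = "x",
      statistic = K2, pValue = p, alpha = alpha, significant = p < alpha,
      details = list(n = length(x)))
}

# --- Dunn's post-hoc for Kruskal-Wallis ------------------------------------

.dunnPairwise <- function(values, groups, adjust = "holm") {
  g <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, g, mean)
  ni <- tapply(r, g, length)
  ties <- table(values)
  C <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - C
  lev <- levels(g)
  combs <- utils::combn(lev, 2)
  z <- apply(combs, 2, function(pr) {
    (Rbar[pr[1]] - Rbar[pr[2]]) /
      sqrt(s2 * (1 / ni[pr[1]] + 1 / ni[pr[2]]))
  })
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(group1 = combs[1, ], group2 = combs[2, ],
             z = as.numeric(z), p = as.numeric(p),
             p_adjusted = stats::p.adjust(p, method = adjust),
             row.names = NULL)
}

#' Nonparametric group comparisons
#'
#' Runs the comparison layer's tests on one or more groups of per-point or
#' per-sample moduli:
#' \describe{
#'   \item{`mann_whitney`}{two independent groups; exact two-sided p when
#'     the combined size is at most `exactMax` (default 20) and there are
#'     no ties, normal approximation with tie and continuity correction
#'     otherwise.}
#'   \item{`wilcoxon_signed_rank`}{two paired groups of equal length.}
#'   \item{`kruskal_wallis_dunn`}{three or more groups: Kruskal-Wallis
#'     omnibus test followed by Dunn's pairwise z comparisons with
#'     multiplicity adjustment (`adjust`, default Holm).}
#'   \item{`dagostino_pearson`}{single group normality screen.}
#' }
#'
#' @param groups named list of numeric vectors; every group needs at least
#'   3 observations.
#' @param test one of the labels above.
#' @param paired for two-group tests: use the signed-rank pairing.
#' @param alpha significance level (default 0.05).
#' @param adjust p-adjustment method for Dunn's comparisons (see
#'   [stats::p.adjust()]).
#' @param exactMax largest combined size for which the Mann-Whitney p is
#'   computed exactly.
#' @return A [GroupComparison-class]; for Kruskal-Wallis the `pairwise`
#'   slot holds the Dunn table.
#' @examples
#' runComparison(list(a = c(1, 2, 3), b = c(4, 5, 6)))  # exact p = 0.1
#' @export
runComparison <- function(groups,
                          test = c("mann_whitney", "wilcoxon_signed_rank",
                                   "kruskal_wallis_dunn", "dagostino_pearson"),
                          paired = FALSE, alpha = 0.05, adjust = "holm",
                          exactMax = 20) {
  test <- match.arg(test)
  stopifnot(is.list(groups), length(groups) >= 1)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  if (paired && test == "mann_whitney") test <- "wilcoxon_signed_rank"
  ns <- lengths(groups)
  if (any(ns < 3))
    stop("every group needs at least 3 observations (got ",
         paste(ns, collapse = ", "), ")")

  if (test == "dagostino_pearson") {
    if (length(groups) != 1)
      stop("the normality screen takes exactly one group")
    out <- dagostinoPearsonTest(groups[[1]], alpha = alpha)
    out@groups <- names(groups)
    return(out)
  }

  if (test %in% c("mann_whitney", "wilcoxon_signed_rank")) {
    if (length(groups) != 2) stop(test, " compares exactly two groups")
    x <- groups[[1]]; y <- groups[[2]]
    if (test == "wilcoxon_signed_rank") {
      if (length(x) != length(y))
        stop("paired test requires equal group lengths")
      ht <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
      details <- list(paired = TRUE)
    } else {
      hasTies <- anyDuplicated(c(x, y)) > 0
      exact <- (length(x) + length(y) <= exactMax) && !hasTies
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = TRUE))
      details <- list(exact = exact, ties = hasTies)
    }
    p <- min(1, ht$p.value)
    return(new("GroupComparison", test = test, groups = names(groups),
               statistic = unname(ht$statistic), pValue = p, alpha = alpha,
               significant = p < alpha, details = details))
  }

  # kruskal_wallis_dunn
  if (length(groups) < 3)
    stop("kruskal_wallis_dunn needs at least three groups")
  values <- unlist(groups, use.names = FALSE)
  glab <- rep(names(groups), ns)
  ht <- stats::kruskal.test(values, factor(glab))
  pw <- .dunnPairwise(values, glab, adjust = adjust)
  p <- min(1, ht$p.value)
  new("GroupComparison", test = test, groups = names(groups),
      statistic = unname(ht$statistic), pValue = p, alpha = alpha,
      significant = p < alpha, pairwise = pw,
      details = list(adjust = adjust, df = unname(ht$parameter)))
}

#' Significance stars for plot annotation
#'
#' Maps a p-value to the star convention used in biomechanics figures:
#' `****` p < 0.0001, `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' `ns` otherwise.
#'
#' @param p p-value.
#' @return A character string.
#' @export
significanceStars <- function(p) {
  if (is.na(p)) return("")
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Linear regression of hydrogel stiffness on dilution
#'
#' Ordinary least squares of the per-batch median modulus on the hydrogel
#' concentration (% v/v), as used to characterise a Matrigel dilution
#' series: E_a = slope * concentration + intercept.
#'
#' @param concentration concentration values (%).
#' @param modulus per-batch median moduli (Pa), same length.
#' @return A [DilutionFit-class].
#' @examples
#' x <- c(40, 60, 80, 100)
#' fitDilutionRegression(x, 4.5 * x - 111.3)  # exact recovery, R^2 = 1
#' @export
fitDilutionRegression <- function(concentration, modulus) {
  stopifnot(length(concentration) == length(modulus))
  if (length(unique(concentration)) < 3)
    stop("at least 3 distinct concentrations are required")
  pts <- data.frame(concentration = concentration, median = modulus)
  if (stats::var(modulus) == 0)
    return(new("DilutionFit", points = pts, slope = 0,
               intercept = modulus[1], rSquared = 0))
  fit <- stats::lm(modulus ~ concentration)
  co <- stats::coef(fit)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((modulus - mean(modulus))^2)
  new("DilutionFit", points = pts, slope = unname(co[2]),
      intercept = unname(co[1]), rSquared = min(max(r2, 0), 1))
}
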