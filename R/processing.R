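# Raw curve -> force-indentation curve: baseline correction, contact-point
# detection, deflection-to-force conversion, indentation computation.
# Only the approach segment is analysed; the retract (acquired fast, with
# adhesion and viscoelastic artifacts) is carried for format fidelity only.

.approachIdx <- function(curve) which(curve@segment == "approach")

#' Remove the optical baseline from a raw force curve
#'
#' Fits a straight line by least squares to the leading non-contact part of
#' the approach segment (default: the first 50% of the approach z-travel,
#' where a trigger-limited curve is still off the surface) and subtracts it
#' from the deflection channel of the whole record. The fitted coefficients
#' are recorded in the `baseline` slot (accumulating over repeated calls).
#'
#' @param curve a [ForceCurve-class] whose approach segment has at least 50
#'   samples.
#' @param windowFraction fraction of the approach z-travel used for the fit
#'   (0 < windowFraction < 1).
#' @return The corrected [ForceCurve-class].
#' @examples
#' fc <- simulateForceCurve(E = 500, baselineSlope = 0.5, noiseSD = 0)
#' correctBaseline(fc)
#' @export
correctBaseline <- function(curve, windowFraction = 0.5) {
  stopifnot(is(curve, "ForceCurve"))
  if (windowFraction <= 0 || windowFraction >= 1)
    stop("windowFraction must lie in (0, 1)")
  app <- .approachIdx(curve)
  if (length(app) < 50)
    stop("approach segment has ", length(app),
         " samples; at least 50 are required to fit a baseline")
  zApp <- curve@z[app]
  zCut <- min(zApp) + windowFraction * (max(zApp) - min(zApp))
  win <- app[zApp <= zCut]
  if (length(win) < 2)
    stop("baseline fit window contains fewer than 2 samples")
  co <- stats::coef(stats::lm.fit(cbind(1, curve@z[win]), curve@d[win]))
  curve@d <- curve@d - (co[1] + co[2] * curve@z)
  prev <- curve@baseline
  curve@baseline <- if (anyNA(prev)) unname(co) else prev + unname(co)
  curve
}

#' Detect the contact point of a baseline-corrected curve
#'
#' Two-regime piecewise fit: for each candidate contact point \eqn{z_0} on
#' the sample grid, the deflection is modelled as zero before contact and
#' Hertz-shaped (proportional to \eqn{\delta^{3/2}} with
#' \eqn{\delta = (z - z_0) - d}) after; \eqn{z_0} minimises the total
#' squared residual. The search is coarse-to-fine over the approach
#' samples, so the cost stays near-linear in curve length.
#'
#' A curve whose maximum deflection does not exceed five times the baseline
#' noise is reported as `"no_contact"` rather than fitted.
#'
#' @param curve a baseline-corrected [ForceCurve-class].
#' @return A list: `z0` (um, `NA` when no contact), `index` (approach sample
#'   index of the contact point), `status` (`"ok"` or `"no_contact"`),
#'   `noiseSD` (baseline deflection noise estimate, nm).
#' @examples
#' fc <- simulateForceCurve(E = 500, z0 = 5, noiseSD = 0)
#' findContactPoint(correctBaseline(fc))$z0  # ~5 um
#' @export
findContactPoint <- function(curve) {
  stopifnot(is(curve, "ForceCurve"))
  app <- .approachIdx(curve)
  z <- curve@z[app]
  d <- curve@d[app]
  n <- length(z)
  zSpan <- max(z) - min(z)
  noiseWin <- d[z <= min(z) + 0.25 * zSpan]
  noiseSD <- if (length(noiseWin) > 3) stats::sd(noiseWin) else 0

  if (max(d) < max(5 * noiseSD, 1e-6))
    return(list(z0 = NA_real_, index = NA_integer_, status = "no_contact",
                noiseSD = noiseSD))

  d_um <- d * 1e-3  # deflection in um for the separation correction
  cumSS <- cumsum(d^2)
  cost <- function(i) {
    post <- seq(i + 1, n)
    delta <- pmax((z[post] - z[i]) - d_um[post], 0)
    x <- delta^1.5
    sxx <- sum(x^2)
    m <- if (sxx > 0) sum(d[post] * x) / sxx else 0
    cumSS[i] + sum((d[post] - m * x)^2)
  }
  upper <- n - 5L
  if (upper < 1L) upper <- 1L
  step <- max(1L, floor(n / 200))
  coarse <- unique(c(seq(1L, upper, by = step), upper))
  cc <- vapply(coarse, cost, numeric(1))
  best <- coarse[which.min(cc)]
  fine <- seq(max(1L, best - 2L * step), min(upper, best + 2L * step))
  fc <- vapply(fine, cost, numeric(1))
  iBest <- fine[which.min(fc)]
  list(z0 = z[iBest], index = iBest, status = "ok", noiseSD = noiseSD)
}

#' Convert a raw curve to a force-indentation curve
#'
#' Applies the calibration and contact point: force \eqn{F = k d}, and the
#' deflection-corrected tip-sample indentation
#' \eqn{\delta = (z - z_0) - d} (the cantilever's own deflection is
#' subtracted from the piezo travel). Approach samples before contact are
#' kept separately for baseline quality control; contact-region samples
#' with \eqn{\delta < 0} are dropped.
#'
#' @param curve a baseline-corrected [ForceCurve-class].
#' @param calibration optional [CantileverCalibration-class]; when missing,
#'   the curve's own `springConstant` metadata is used.
#' @param z0 contact point (um), e.g. from [findContactPoint()].
#' @return An [IndentationCurve-class].
#' @examples
#' fc <- correctBaseline(simulateForceCurve(E = 500, noiseSD = 0))
#' cp <- findContactPoint(fc)
#' toIndentation(fc, z0 = cp$z0)
#' @export
toIndentation <- function(curve, calibration = NULL, z0) {
  stopifnot(is(curve, "ForceCurve"))
  k <- if (!is.null(calibration)) {
    stopifnot(is(calibration, "CantileverCalibration"))
    calibration@k
  } else curve@springConstant
  if (is.na(k))
    stop("no spring constant available: supply a CantileverCalibration ",
         "or a curve with calibrated probe metadata")
  app <- .approachIdx(curve)
  z <- curve@z[app]
  d <- curve@d[app]
  if (z0 < min(z) || z0 > max(z))
    stop("contact point z0 = ", z0, " um lies outside the approach z range")

  F_nN <- k * d           # k [N/m] * d [nm] -> F [nN]
  pre <- z < z0
  delta <- (z - z0) - d * 1e-3
  keep <- !pre & delta >= 0
  noiseF <- if (sum(pre) > 3) stats::sd(F_nN[pre]) else NA_real_
  new("IndentationCurve",
      delta = delta[keep], force = F_nN[keep], z0 = z0,
      baseline = curve@baseline, preContactForce = F_nN[pre],
      noiseForceSD = noiseF, probeRadius = curve@probeRadius,
      springConstant = k, position = curve@position,
      groundTruth = curve@groundTruth)
}
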