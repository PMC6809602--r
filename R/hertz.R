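# Hertzian modulus estimation, contact-mechanics validity, and curve QC.

#' Contact-mechanics validity report
#'
#' Computes the contact radius \eqn{a = \sqrt{R \delta}}, the compressive
#' strain scale \eqn{\epsilon = 0.2 a / R}, and the half-space ratio
#' \eqn{a / h} at the evaluation depth. The half-space condition is
#' \eqn{a/h < 0.1}. Soft biological materials begin to deviate from linear
#' elasticity at strains of roughly 0.02; with a ~37 um bead indented 2 um
#' the strain scale is ~0.066, so the strain flag is recorded as
#' information, never used to hard-fail a curve.
#'
#' @param R bead radius (um).
#' @param deltaEval evaluation depth (um).
#' @param h sample thickness (um). Default 5000 um (a 0.5 cm tissue block).
#' @param strainBound strain level recorded as the linear-elastic bound.
#' @return A [ValidityReport-class].
#' @examples
#' checkValidity(R = 18.64, deltaEval = 2)  # a ~6.1 um, contact diameter ~12 um
#' @export
checkValidity <- function(R, deltaEval = 2, h = 5000, strainBound = 0.02) {
  if (R <= 0 || deltaEval < 0 || h <= 0)
    stop("R and h must be positive and deltaEval non-negative")
  a <- sqrt(R * deltaEval)
  strain <- 0.2 * a / R
  ratio <- a / h
  new("ValidityReport", a = a, strain = strain, halfSpaceRatio = ratio,
      h = h, strainOK = strain <= strainBound, halfSpaceOK = ratio < 0.1)
}

.failedFit <- function(reason, deltaEval, validity, position,
                       nPoints = 0, R2 = NA_real_) {
  new("HertzFit", Ea = NA_real_, EaSinglePoint = NA_real_,
      deltaEval = deltaEval, linearityR2 = R2, qc = "failed",
      qcReason = reason, shallow = FALSE, nPoints = nPoints,
      validity = validity, position = position)
}

#' Fit the apparent elastic modulus of a force-indentation curve
#'
#' Linearised Hertz fit: ordinary least squares of force on
#' \eqn{\delta^{3/2}} through the origin, over the window
#' \eqn{\delta \in [0, \delta_\mathrm{eval}]} (default 2 um). The slope
#' \eqn{m} gives \eqn{E_a = \frac{3}{4} m / \sqrt{R}}. The uncentered
#' \eqn{R^2} of this regression is the linearity diagnostic used by
#' [qcCurve()]. A single-point estimate at the evaluation depth is also
#' reported for comparison.
#'
#' Curves that do not reach the evaluation depth (stiff spots under a
#' force trigger) are fitted over the available depth and flagged
#' `shallow`, with a warning.
#'
#' @param ind an [IndentationCurve-class].
#' @param deltaEval evaluation depth (um); default 2.
#' @param h sample thickness (um) for the validity report.
#' @return A [HertzFit-class]. Fewer than 10 contact samples give
#'   `qc = "failed"` with reason `"insufficient_data"`.
#' @examples
#' fc <- correctBaseline(simulateForceCurve(E = 250, noiseSD = 0))
#' cp <- findContactPoint(fc)
#' fit <- fitModulus(toIndentation(fc, z0 = cp$z0))
#' modulus(fit)  # ~250 Pa
#' @export
fitModulus <- function(ind, deltaEval = 2, h = 5000) {
  stopifnot(is(ind, "IndentationCurve"))
  if (deltaEval <= 0) stop("deltaEval must be positive")
  R <- ind@probeRadius
  validity <- checkValidity(R, deltaEval, h)
  keep <- ind@delta <= deltaEval
  delta <- ind@delta[keep]
  F_nN <- ind@force[keep]
  if (length(delta) < 10)
    return(.failedFit("insufficient_data", deltaEval, validity,
                      ind@position, nPoints = length(delta)))
  shallow <- length(ind@delta) == 0 || max(ind@delta) < deltaEval
  if (shallow)
    warning("curve reaches only ", signif(max(ind@delta), 3),
            " um of the ", deltaEval, " um evaluation depth; ",
            "fitting over the available depth (shallow)")

  x <- (delta * .UM)^1.5          # m^(3/2)
  Fn <- F_nN * .NN                # N
  sxx <- sum(x^2)
  sFF <- sum(Fn^2)
  if (sxx == 0 || sFF == 0)
    return(.failedFit("no_contact", deltaEval, validity, ind@position,
                      nPoints = length(delta)))
  m <- sum(Fn * x) / sxx
  if (m <= 0)
    return(.failedFit("nonphysical_slope", deltaEval, validity,
                      ind@position, nPoints = length(delta), R2 = 0))
  Ea <- 0.75 * m / sqrt(R * .UM)
  R2 <- max(0, 1 - sum((Fn - m * x)^2) / sFF)

  dTop <- min(deltaEval, max(delta))
  FTop <- stats::approx(delta, F_nN, xout = dTop, ties = "ordered")$y
  EaSP <- 3 * (FTop * .NN) / (4 * sqrt(R * .UM) * (dTop * .UM)^1.5)

  new("HertzFit", Ea = Ea, EaSinglePoint = EaSP, deltaEval = deltaEval,
      linearityR2 = min(R2, 1), qc = "pass", qcReason = "",
      shallow = shallow, nPoints = length(delta), validity = validity,
      position = ind@position)
}

#' Quality-control a fitted curve
#'
#' Applies the failure rules of the workflow: a measurement fails when the
#' force-indentation record is not the straight line the linearised Hertz
#' model predicts. Concretely a curve is failed when (in order):
#' \itemize{
#'   \item the pre-contact baseline is not flat (RMS pre-contact force
#'     above `driftFractionMax` of the peak force) - `"baseline_drift"`;
#'   \item the force drops discontinuously inside the contact region, the
#'     signature of the probe slipping over the tissue - `"slip"`;
#'   \item the uncentered \eqn{R^2} of force against \eqn{\delta^{3/2}}
#'     falls below `linearityThreshold` (default 0.90) - `"nonlinearity"`.
#' }
#' Failed curves are excluded from maps and statistics but kept as marked
#' cells ("crosses").
#'
#' @param ind the [IndentationCurve-class] that was fitted.
#' @param fit the corresponding [HertzFit-class].
#' @param linearityThreshold minimum linearity R^2 (default 0.90).
#' @param driftFractionMax maximum RMS pre-contact force as a fraction of
#'   the peak force (default 0.02).
#' @return The [HertzFit-class] with `qc`/`qcReason` updated.
#' @export
qcCurve <- function(ind, fit, linearityThreshold = 0.90,
                    driftFractionMax = 0.02) {
  stopifnot(is(ind, "IndentationCurve"), is(fit, "HertzFit"))
  if (fit@qc == "failed") return(fit)
  maxF <- max(c(0, ind@force))

  if (length(ind@preContactForce) >= 10 && maxF > 0) {
    rmsPre <- sqrt(mean(ind@preContactForce^2))
    if (rmsPre > driftFractionMax * maxF) {
      fit@qc <- "failed"; fit@qcReason <- "baseline_drift"
      return(fit)
    }
  }

  if (length(ind@force) >= 2) {
    drop <- max(cummax(ind@force) - ind@force)
    noiseF <- ind@noiseForceSD
    slipTol <- max(0.05 * maxF,
                   if (!is.na(noiseF)) 6 * noiseF else 0, 0.05)
    if (drop > slipTol) {
      fit@qc <- "failed"; fit@qcReason <- "slip"
      return(fit)
    }
  }

  if (is.na(fit@linearityR2) || fit@linearityR2 < linearityThreshold) {
    fit@qc <- "failed"; fit@qcReason <- "nonlinearity"
    return(fit)
  }
  fit
}

#' Run the full single-curve analysis
#'
#' Convenience chain: [correctBaseline()] -> [findContactPoint()] ->
#' [toIndentation()] -> [fitModulus()] -> [qcCurve()]. A curve with no
#' detectable contact returns a failed [HertzFit-class] with reason
#' `"no_contact"` rather than an error.
#'
#' The baseline is fitted in two passes: first over the leading
#' `windowFraction` of the approach travel, then - when the detected
#' contact point shows that window reached into the contact region (long
#' contact on very soft samples) - re-fitted over the pre-contact travel
#' only, and the contact point is re-detected.
#'
#' @param curve a raw [ForceCurve-class].
#' @param calibration optional [CantileverCalibration-class].
#' @param deltaEval evaluation depth (um).
#' @param windowFraction baseline fit window fraction.
#' @param linearityThreshold QC linearity threshold.
#' @param driftFractionMax QC baseline-flatness bound.
#' @param h sample thickness (um) for the validity report.
#' @return A [HertzFit-class] carrying the curve's stage position.
#' @examples
#' fit <- analyzeCurve(simulateForceCurve(E = 171, noiseSD = 2, seed = 3))
#' qcStatus(fit); modulus(fit)
#' @export
analyzeCurve <- function(curve, calibration = NULL, deltaEval = 2,
                         windowFraction = 0.5, linearityThreshold = 0.90,
                         driftFractionMax = 0.02, h = 5000) {
  stopifnot(is(curve, "ForceCurve"))
  corrected <- correctBaseline(curve, windowFraction = windowFraction)
  cp <- findContactPoint(corrected)
  if (cp$status == "ok") {
    app <- curve@z[curve@segment == "approach"]
    travel <- max(app) - min(app)
    fracUsed <- windowFraction
    for (pass in 1:3) {
      frac <- 0.9 * (cp$z0 - min(app)) / travel
      if (frac >= fracUsed || frac <= 0.05) break
      corrected <- correctBaseline(curve, windowFraction = frac)
      cpNew <- findContactPoint(corrected)
      fracUsed <- frac
      if (cpNew$status != "ok") { cp <- cpNew; break }
      converged <- abs(cpNew$z0 - cp$z0) <= 0.01 * travel
      cp <- cpNew
      if (converged) break
    }
  }
  if (cp$status == "no_contact") {
    validity <- checkValidity(curve@probeRadius, deltaEval, h)
    return(.failedFit("no_contact", deltaEval, validity, curve@position))
  }
  ind <- toIndentation(corrected, calibration = calibration, z0 = cp$z0)
  fit <- withCallingHandlers(
    fitModulus(ind, deltaEval = deltaEval, h = h),
    warning = function(w) invokeRestart("muffleWarning"))
  qcCurve(ind, fit, linearityThreshold = linearityThreshold,
          driftFractionMax = driftFractionMax)
}
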