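#' @import methods
NULL

#' ForceCurve: a raw AFM force-displacement record
#'
#' Instrument-level record of one indentation: piezo z-position and cantilever
#' deflection samples for the approach and retract segments, plus probe
#' metadata. z increases toward the sample on approach.
#'
#' @slot z piezo position samples (um).
#' @slot d cantilever deflection samples (nm).
#' @slot segment character, `"approach"` or `"retract"` per sample.
#' @slot probeRadius bead radius R (um).
#' @slot springConstant cantilever spring constant k (N/m); `NA_real_` if
#'   uncalibrated.
#' @slot position stage coordinates (x, y) in um.
#' @slot metadata named list: `approachSpeed`, `retractSpeed` (um/s),
#'   `triggerForce` (nN), `temperature` (K).
#' @slot baseline numeric(2) (intercept nm, slope nm/um) already removed from
#'   `d`; `c(NA, NA)` when uncorrected.
#' @slot groundTruth named list of generator truth (empty for real data).
#' @exportClass ForceCurve
setClass("ForceCurve",
  representation(
    z = "numeric", d = "numeric", segment = "character",
    probeRadius = "numeric", springConstant = "numeric",
    position = "numeric", metadata = "list",
    baseline = "numeric", groundTruth = "list"
  ),
  prototype(
    position = c(0, 0), metadata = list(),
    baseline = c(NA_real_, NA_real_), groundTruth = list(),
    springConstant = NA_real_
  )
)

setValidity("ForceCurve", function(object) {
  msgs <- character()
  if (length(object@z) != length(object@d))
    msgs <- c(msgs, "z and d must have equal length")
  if (length(object@segment) != length(object@z))
    msgs <- c(msgs, "segment must label every sample")
  if (!any(object@segment == "approach"))
    msgs <- c(msgs, "approach segment must be non-empty")
  if (!all(object@segment %in% c("approach", "retract")))
    msgs <- c(msgs, "segment labels must be 'approach' or 'retract'")
  if (length(object@probeRadius) != 1 || object@probeRadius <= 0)
    msgs <- c(msgs, "probeRadius must be a single positive value (um)")
  if (!is.na(object@springConstant) && object@springConstant <= 0)
    msgs <- c(msgs, "springConstant must be positive when set")
  if (length(object@position) != 2)
    msgs <- c(msgs, "position must be (x, y)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ForceCurve", function(object) {
  napp <- sum(object@segment == "approach")
  cat("ForceCurve:", length(object@z), "samples (", napp, "approach,",
      length(object@z) - napp, "retract )\n")
  cat("  probe: R =", object@probeRadius, "um, k =",
      object@springConstant, "N/m\n")
  cat("  position: (", object@position[1], ",", object@position[2], ") um\n")
  if (!is.na(object@baseline[1]))
    cat("  baseline removed: intercept", signif(object@baseline[1], 4),
        "nm, slope", signif(object@baseline[2], 4), "nm/um\n")
  if (length(object@groundTruth))
    cat("  synthetic, E_true =", object@groundTruth$E_true, "Pa\n")
})

#' IndentationCurve: force vs tip-sample indentation
#'
#' The approach segment of a [ForceCurve-class] after calibration, baseline
#' correction, contact-point subtraction and deflection correction:
#' \eqn{F = k d}, \eqn{\delta = (z - z_0) - d}. Only the contact region
#' (\eqn{\delta \ge 0}) is retained in `delta`/`force`; the pre-contact
#' forces are kept separately for quality control.
#'
#' @slot delta indentation samples (um), non-negative, non-decreasing.
#' @slot force force samples (nN).
#' @slot z0 contact point (um).
#' @slot baseline numeric(2) removed baseline (intercept nm, slope nm/um).
#' @slot preContactForce forces before contact (nN), for baseline QC.
#' @slot noiseForceSD baseline force noise estimate (nN).
#' @slot probeRadius bead radius (um).
#' @slot springConstant spring constant used (N/m).
#' @slot position stage coordinates (um).
#' @slot groundTruth generator truth carried through (possibly empty).
#' @exportClass IndentationCurve
setClass("IndentationCurve",
  representation(
    delta = "numeric", force = "numeric", z0 = "numeric",
    baseline = "numeric", preContactForce = "numeric",
    noiseForceSD = "numeric", probeRadius = "numeric",
    springConstant = "numeric", position = "numeric",
    groundTruth = "list"
  ),
  prototype(position = c(0, 0), groundTruth = list(),
            noiseForceSD = NA_real_)
)

setValidity("IndentationCurve", function(object) {
  msgs <- character()
  if (length(object@delta) != length(object@force))
    msgs <- c(msgs, "delta and force must have equal length")
  if (length(object@delta) && min(object@delta) < -1e-12)
    msgs <- c(msgs, "delta must be non-negative in the retained region")
  if (object@probeRadius <= 0 || object@springConstant <= 0)
    msgs <- c(msgs, "probeRadius and springConstant must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "IndentationCurve", function(object) {
  cat("IndentationCurve:", length(object@delta), "contact samples, z0 =",
      signif(object@z0, 5), "um, max delta =",
      signif(max(c(0, object@delta)), 4), "um, max F =",
      signif(max(c(0, object@force)), 4), "nN\n")
})

#' ThermalSeries: free-cantilever thermal deflection record
#'
#' A time series of cantilever deflection fluctuations recorded away from the
#' surface, used by the thermal-noise spring-constant calibration.
#'
#' @slot samples deflection samples (nm).
#' @slot temperature bath temperature (K).
#' @slot sampleRate acquisition rate (Hz).
#' @exportClass ThermalSeries
setClass("ThermalSeries",
  representation(samples = "numeric", temperature = "numeric",
                 sampleRate = "numeric"),
  prototype(sampleRate = 1e5)
)

setValidity("ThermalSeries", function(object) {
  msgs <- character()
  if (length(object@samples) < 1000)
    msgs <- c(msgs, "at least 1000 samples are required for calibration use")
  if (object@temperature <= 0)
    msgs <- c(msgs, "temperature must be positive (K)")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ThermalSeries", function(object) {
  cat("ThermalSeries:", length(object@samples), "samples at",
      object@temperature, "K, rms =",
      signif(stats::sd(object@samples), 3), "nm\n")
})

#' CantileverCalibration: thermal-noise spring constant estimate
#'
#' @slot k spring constant (N/m).
#' @slot method calibration method label.
#' @slot temperature calibration temperature (K).
#' @slot nSamples number of deflection samples used.
#' @slot variance unbiased deflection variance (m^2).
#' @slot correction mode-shape correction factor applied (default 1).
#' @exportClass CantileverCalibration
setClass("CantileverCalibration",
  representation(k = "numeric", method = "character",
                 temperature = "numeric", nSamples = "numeric",
                 variance = "numeric", correction = "numeric"),
  prototype(method = "thermal_equipartition", correction = 1)
)

setValidity("CantileverCalibration", function(object) {
  msgs <- character()
  if (object@k <= 0) msgs <- c(msgs, "k must be positive")
  if (object@variance <= 0) msgs <- c(msgs, "variance must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "CantileverCalibration", function(object) {
  cat("CantileverCalibration:", object@method, "\n")
  cat("  k =", signif(object@k, 4), "N/m from", object@nSamples,
      "samples at", object@temperature, "K\n")
})

#' ValidityReport: Hertzian contact-mechanics validity checks
#'
#' Records the contact radius \eqn{a = \sqrt{R\delta}}, the compressive
#' strain scale \eqn{\epsilon = 0.2 a / R}, and the half-space ratio
#' \eqn{a/h} at the evaluation depth, together with the pass booleans.
#'
#' @slot a contact radius (um).
#' @slot strain dimensionless strain scale 0.2 a / R.
#' @slot halfSpaceRatio a / h.
#' @slot h sample thickness (um).
#' @slot strainOK strain within configured bound.
#' @slot halfSpaceOK a/h < 0.1.
#' @exportClass ValidityReport
setClass("ValidityReport",
  representation(a = "numeric", strain = "numeric",
                 halfSpaceRatio = "numeric", h = "numeric",
                 strainOK = "logical", halfSpaceOK = "logical")
)

setMethod("show", "ValidityReport", function(object) {
  cat("ValidityReport: a =", signif(object@a, 4), "um (contact diameter",
      signif(2 * object@a, 4), "um), strain =", signif(object@strain, 3),
      ", a/h =", signif(object@halfSpaceRatio, 3),
      if (object@halfSpaceOK) "(half space OK)\n" else "(half space VIOLATED)\n")
})

#' HertzFit: apparent elastic modulus fit for one curve
#'
#' Result of the origin-constrained regression of force on
#' \eqn{\delta^{3/2}} over the evaluation window, with curve quality control
#' and contact-mechanics validity.
#'
#' @slot Ea apparent elastic modulus (Pa); `NA` when the fit failed.
#' @slot EaSinglePoint single-point estimate at the evaluation depth (Pa).
#' @slot deltaEval evaluation depth (um).
#' @slot linearityR2 uncentered R^2 of F vs delta^(3/2) through the origin.
#' @slot qc `"pass"` or `"failed"`.
#' @slot qcReason failure reason (`""` when pass).
#' @slot shallow TRUE when the curve did not reach `deltaEval` and the fit
#'   used the available depth.
#' @slot nPoints number of contact samples used.
#' @slot validity a [ValidityReport-class].
#' @slot position stage coordinates (um).
#' @exportClass HertzFit
setClass("HertzFit",
  representation(Ea = "numeric", EaSinglePoint = "numeric",
                 deltaEval = "numeric", linearityR2 = "numeric",
                 qc = "character", qcReason = "character",
                 shallow = "logical", nPoints = "numeric",
                 validity = "ValidityReport", position = "numeric"),
  prototype(qc = "pass", qcReason = "", shallow = FALSE,
            position = c(0, 0))
)

setValidity("HertzFit", function(object) {
  msgs <- character()
  if (object@qc == "pass" && (is.na(object@Ea) || object@Ea <= 0))
    msgs <- c(msgs, "Ea must be positive when qc is 'pass'")
  if (!is.na(object@linearityR2) &&
      (object@linearityR2 < -1e-9 || object@linearityR2 > 1 + 1e-9))
    msgs <- c(msgs, "linearityR2 must lie in [0, 1]")
  if (!object@qc %in% c("pass", "failed"))
    msgs <- c(msgs, "qc must be 'pass' or 'failed'")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "HertzFit", function(object) {
  if (object@qc == "pass") {
    cat("HertzFit: E_a =", signif(object@Ea, 4), "Pa at delta_eval =",
        object@deltaEval, "um (R2 =", signif(object@linearityR2, 4),
        ",", object@nPoints, "points",
        if (object@shallow) ", shallow)\n" else ")\n")
  } else {
    cat("HertzFit: FAILED (", object@qcReason, ")\n")
  }
})

#' StiffnessMap: grid of per-cell apparent elastic moduli
#'
#' One measurement slot per grid cell (half-open cells
#' \eqn{[x, x+\mathrm{cell}) \times [y, y+\mathrm{cell})}, row-major with
#' rows = y). Failed cells are `NA` in `values` with the reason in
#' `qcReasons`; they are never interpolated.
#'
#' @slot origin (x, y) of the lower-left corner (um).
#' @slot cellSize cell edge (um).
#' @slot values matrix of E_a (Pa); `NA` marks a failed cell ("cross").
#' @slot qcReasons character matrix of per-cell QC labels ("" = pass).
#' @exportClass StiffnessMap
setClass("StiffnessMap",
  representation(origin = "numeric", cellSize = "numeric",
                 values = "matrix", qcReasons = "matrix"),
  prototype(origin = c(0, 0), cellSize = 20)
)

setValidity("StiffnessMap", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@qcReasons)))
    msgs <- c(msgs, "values and qcReasons must have identical dimensions")
  if (object@cellSize <= 0) msgs <- c(msgs, "cellSize must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StiffnessMap", function(object) {
  nf <- sum(is.na(object@values))
  cat("StiffnessMap:", nrow(object@values), "x", ncol(object@values),
      "cells of", object@cellSize, "um;", nf, "failed (crosses)\n")
  if (any(!is.na(object@values)))
    cat("  median E_a =", signif(stats::median(object@values, na.rm = TRUE), 4),
        "Pa\n")
})

#' SampleSummary: per-sample aggregation of moduli
#'
#' @slot sampleId sample identifier.
#' @slot tissue tissue label.
#' @slot points passing modulus measurements (Pa).
#' @slot median sample median modulus (Pa).
#' @slot n number of measurements.
#' @exportClass SampleSummary
setClass("SampleSummary",
  representation(sampleId = "character", tissue = "character",
                 points = "numeric", median = "numeric", n = "numeric")
)

setValidity("SampleSummary", function(object) {
  msgs <- character()
  if (object@n != length(object@points))
    msgs <- c(msgs, "n must equal length(points)")
  if (length(object@points) &&
      !isTRUE(all.equal(object@median, stats::median(object@points))))
    msgs <- c(msgs, "median must be recomputable from points")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SampleSummary", function(object) {
  cat("SampleSummary:", object@sampleId, "(", object@tissue, ") median =",
      signif(object@median, 4), "Pa from n =", object@n, "points\n")
})

#' TissueSummary: mean of per-sample medians for one tissue
#'
#' @slot tissue tissue label.
#' @slot sampleMedians per-sample medians (Pa).
#' @slot meanOfMedians arithmetic mean of the sample medians (Pa).
#' @slot N number of samples.
#' @slot nTotal total measurements across samples.
#' @exportClass TissueSummary
setClass("TissueSummary",
  representation(tissue = "character", sampleMedians = "numeric",
                 meanOfMedians = "numeric", N = "numeric",
                 nTotal = "numeric")
)

setValidity("TissueSummary", function(object) {
  if (!isTRUE(all.equal(object@meanOfMedians, mean(object@sampleMedians))))
    "meanOfMedians must equal mean(sampleMedians)" else TRUE
})

setMethod("show", "TissueSummary", function(object) {
  cat("TissueSummary:", object@tissue, "E_a =",
      signif(object@meanOfMedians, 4), "Pa (mean of", object@N,
      "sample medians;", object@nTotal, "measurements)\n")
})

#' GroupComparison: result of a nonparametric group comparison
#'
#' @slot test test label.
#' @slot groups group names.
#' @slot statistic test statistic.
#' @slot pValue two-sided p-value (omnibus p for Kruskal-Wallis).
#' @slot alpha significance level.
#' @slot significant `pValue < alpha`.
#' @slot pairwise data.frame of Dunn pairwise comparisons (empty otherwise).
#' @slot details named list of method choices logged for the run.
#' @exportClass GroupComparison
setClass("GroupComparison",
  representation(test = "character", groups = "character",
                 statistic = "numeric", pValue = "numeric",
                 alpha = "numeric", significant = "logical",
                 pairwise = "data.frame", details = "list"),
  prototype(alpha = 0.05, pairwise = data.frame(), details = list())
)

setValidity("GroupComparison", function(object) {
  msgs <- character()
  if (object@pValue < 0 || object@pValue > 1)
    msgs <- c(msgs, "pValue must lie in [0, 1]")
  if (!identical(object@significant, object@pValue < object@alpha))
    msgs <- c(msgs, "significant must equal pValue < alpha")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison:", object@test, "on",
      paste(object@groups, collapse = " vs "), "\n")
  cat("  statistic =", signif(object@statistic, 5), ", p =",
      format.pval(object@pValue, digits = 4), significanceStars(object@pValue),
      "\n")
  if (nrow(object@pairwise)) {
    cat("  pairwise (Dunn,", object@details$adjust %||% "holm", "adjusted):\n")
    print(object@pairwise, row.names = FALSE)
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' DilutionFit: linear fit of modulus against hydrogel concentration
#'
#' @slot points data.frame with columns `concentration` (%) and `median`
#'   (Pa), one row per batch x dilution.
#' @slot slope Pa per concentration percent.
#' @slot intercept Pa.
#' @slot rSquared coefficient of determination.
#' @exportClass DilutionFit
setClass("DilutionFit",
  representation(points = "data.frame", slope = "numeric",
                 intercept = "numeric", rSquared = "numeric")
)

setValidity("DilutionFit", function(object) {
  if (object@rSquared < -1e-9 || object@rSquared > 1 + 1e-9)
    "rSquared must lie in [0, 1]" else TRUE
})

setMethod("show", "DilutionFit", function(object) {
  cat("DilutionFit: E_a =", signif(object@slope, 4), "* concentration ",
      ifelse(object@intercept < 0, "-", "+"),
      signif(abs(object@intercept), 4), " Pa,  R2 =",
      signif(object@rSquared, 3), "\n")
})
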