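# End-to-end analysis: curves -> per-curve fits -> map -> summaries, with a
# run manifest recording every configuration choice.

#' Analysis run configuration
#'
#' Bundles the tunable parameters of the pipeline with their defaults: a
#' 2 um evaluation depth, 0.90 linearity threshold, baseline fit over the
#' leading half of the approach, 20 um grid cells, a 1 kPa stiff-tail
#' threshold, and alpha = 0.05.
#'
#' @param deltaEval evaluation depth (um).
#' @param linearityThreshold minimum linearity R^2 for QC.
#' @param windowFraction baseline fit window fraction.
#' @param driftFractionMax QC baseline-flatness bound.
#' @param cellSize map cell edge (um).
#' @param stiffnessThreshold stiff-tail threshold (Pa).
#' @param alpha significance level.
#' @param h sample thickness (um) for validity reporting.
#' @param seed seed recorded into the manifest.
#' @return A named list of class `hertzmapConfig`.
#' @export
runConfig <- function(deltaEval = 2, linearityThreshold = 0.90,
                      windowFraction = 0.5, driftFractionMax = 0.02,
                      cellSize = 20, stiffnessThreshold = 1000,
                      alpha = 0.05, h = 5000, seed = NULL) {
  stopifnot(deltaEval > 0, linearityThreshold > 0, linearityThreshold <= 1,
            windowFraction > 0, windowFraction < 1, cellSize > 0,
            stiffnessThreshold > 0, alpha > 0, alpha < 1, h > 0)
  structure(list(deltaEval = deltaEval,
                 linearityThreshold = linearityThreshold,
                 windowFraction = windowFraction,
                 driftFractionMax = driftFractionMax,
                 cellSize = cellSize,
                 stiffnessThreshold = stiffnessThreshold,
                 alpha = alpha, h = h, seed = seed),
            class = "hertzmapConfig")
}

#' Analyse a batch of curves
#'
#' Runs [analyzeCurve()] on each curve with one configuration.
#'
#' @param curves list of [ForceCurve-class] objects.
#' @param calibration optional [CantileverCalibration-class].
#' @param config a [runConfig()] list.
#' @return List of [HertzFit-class] objects.
#' @export
analyzeCurves <- function(curves, calibration = NULL, config = runConfig()) {
  stopifnot(is(config, "hertzmapConfig"))
  lapply(curves, analyzeCurve, calibration = calibration,
         deltaEval = config$deltaEval,
         windowFraction = config$windowFraction,
         linearityThreshold = config$linearityThreshold,
         driftFractionMax = config$driftFractionMax, h = config$h)
}

#' Tidy per-curve result table
#'
#' @param fits list of [HertzFit-class] objects.
#' @return A data.frame with one row per curve: position, modulus,
#'   QC status/reason, linearity, validity fields.
#' @export
curveResults <- function(fits) {
  stopifnot(all(vapply(fits, is, logical(1), "HertzFit")))
  data.frame(
    x = vapply(fits, function(f) f@position[1], numeric(1)),
    y = vapply(fits, function(f) f@position[2], numeric(1)),
    Ea_Pa = vapply(fits, function(f) f@Ea, numeric(1)),
    Ea_single_point_Pa = vapply(fits, function(f) f@EaSinglePoint, numeric(1)),
    qc = vapply(fits, function(f) f@qc, character(1)),
    reason = vapply(fits, function(f) f@qcReason, character(1)),
    linearity_R2 = vapply(fits, function(f) f@linearityR2, numeric(1)),
    shallow = vapply(fits, function(f) f@shallow, logical(1)),
    n_points = vapply(fits, function(f) f@nPoints, numeric(1)),
    contact_radius_um = vapply(fits, function(f) f@validity@a, numeric(1)),
    strain = vapply(fits, function(f) f@validity@strain, numeric(1)),
    half_space_ok = vapply(fits, function(f) f@validity@halfSpaceOK,
                           logical(1))
  )
}

#' Run the full pipeline on a set of curves
#'
#' Baseline correction, contact detection, Hertz fitting and QC for every
#' curve; assembly into a stiffness map; map summary; and a manifest
#' recording the configuration and pass/fail counts.
#'
#' @param curves list of [ForceCurve-class] objects on a measurement grid.
#' @param calibration optional [CantileverCalibration-class]; otherwise each
#'   curve's own spring constant metadata is used.
#' @param config a [runConfig()] list.
#' @return A list: `fits`, `results` (tidy data.frame), `map`
#'   ([StiffnessMap-class]), `summary` (from [mapSummary()]), `manifest`.
#' @examples
#' fld <- simulateTissueField(extent = c(60, 60), seed = 11)
#' run <- runPipeline(fld$curves)
#' run$summary$nPass
#' @export
runPipeline <- function(curves, calibration = NULL, config = runConfig()) {
  fits <- analyzeCurves(curves, calibration = calibration, config = config)
  res <- curveResults(fits)
  map <- buildStiffnessMap(fits, cellSize = config$cellSize)
  sm <- mapSummary(map, threshold = config$stiffnessThreshold)
  manifest <- list(
    package = "hertzmap",
    version = as.character(utils::packageVersion("hertzmap")),
    config = unclass(config),
    n_curves = length(curves),
    n_pass = sum(res$qc == "pass"),
    n_failed = sum(res$qc == "failed"),
    failure_reasons = as.list(table(res$reason[res$qc == "failed"]))
  )
  list(fits = fits, results = res, map = map, summary = sm,
       manifest = manifest)
}

#' Write a run manifest as JSON
#'
#' @param run result of [runPipeline()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeManifest <- function(run, path) {
  jsonlite::write_json(run$manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
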