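# Thermal-noise spring-constant calibration (equipartition).

#' Estimate the cantilever spring constant by the thermal-noise method
#'
#' Inverts the equipartition identity
#' \eqn{\frac{1}{2} k \langle d^2 \rangle = \frac{1}{2} k_B T}: the spring
#' constant is \eqn{k = k_B T / \mathrm{var}(d)}, with the unbiased sample
#' variance of the mean-subtracted deflection series. An optional
#' multiplicative mode-shape correction (e.g. 0.971 for a rectangular
#' lever's first mode) can be supplied; the default is 1 (pure
#' equipartition).
#'
#' A warning is issued when the estimate falls outside the plausibility
#' band for the soft tipless levers this workflow targets (0.01-0.1 N/m by
#' default).
#'
#' @param series a [ThermalSeries-class] (at least 1000 samples).
#' @param correction multiplicative mode-shape correction factor.
#' @param plausible numeric(2), plausibility band for k (N/m); a warning is
#'   logged when the estimate falls outside it.
#' @return A [CantileverCalibration-class].
#' @examples
#' ts <- simulateThermalSeries(k = 0.05, temperature = 298, n = 1e4, seed = 42)
#' springConstant(estimateSpringConstant(ts))  # ~0.05 N/m
#' @export
estimateSpringConstant <- function(series, correction = 1,
                                   plausible = c(0.01, 0.1)) {
  stopifnot(is(series, "ThermalSeries"))
  if (length(series@samples) < 1000)
    stop("at least 1000 samples are required to calibrate")
  v_m2 <- stats::var(series@samples * .NM)  # unbiased, mean-subtracted
  if (v_m2 <= 0)
    stop("deflection series has zero variance: a constant series cannot calibrate")
  k <- correction * .kB * series@temperature / v_m2
  if (k < plausible[1] || k > plausible[2])
    warning("estimated spring constant ", signif(k, 3),
            " N/m lies outside the plausibility band [",
            plausible[1], ", ", plausible[2], "] N/m")
  new("CantileverCalibration", k = k, method = "thermal_equipartition",
      temperature = series@temperature, nSamples = length(series@samples),
      variance = v_m2, correction = correction)
}
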