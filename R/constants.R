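# Physical constants and unit conversions.
# Convention: SI (m, N, Pa, K) inside every numerical routine; interface
# units are those of the instrument software: z in um, deflection in nm,
# force in nN, modulus in Pa, spring constant in N/m.

.kB <- 1.380649e-23  # Boltzmann constant, J/K (2019 SI exact value)

.UM <- 1e-6  # um -> m
.NM <- 1e-9  # nm -> m
.NN <- 1e-9  # nN -> N

#' Hertz force for a sphere indenting an elastic half space
#'
#' Forward Hertz model \eqn{F = \frac{4}{3} E_a \sqrt{R}\, \delta^{3/2}} for a
#' rigid sphere of radius \eqn{R} indenting an elastic half space to depth
#' \eqn{\delta}. \eqn{E_a} is the apparent elastic modulus: no
#' \eqn{(1-\nu^2)} Poisson term is applied, so the returned force corresponds
#' to the effective modulus exactly as fitted by [fitModulus()].
#'
#' @param E apparent elastic modulus (Pa).
#' @param R probe bead radius (um).
#' @param delta indentation depth (um); vectorised, must be non-negative.
#' @return Force in nN (same length as `delta`).
#' @examples
#' hertzForce(1250, R = 18.64, delta = 2)  # ~20.35 nN
#' @export
hertzForce <- function(E, R, delta) {
  stopifnot(is.numeric(E), is.numeric(R), is.numeric(delta))
  if (E <= 0 || R <= 0) stop("E and R must be positive")
  if (any(delta < 0)) stop("indentation depth 'delta' must be non-negative")
  F_N <- (4 / 3) * E * sqrt(R * .UM) * (delta * .UM)^1.5
  F_N / .NN
}

# SI-core version used by the solver: all arguments/result in SI.
.hertzForceSI <- function(E, R_m, delta_m) {
  (4 / 3) * E * sqrt(R_m) * delta_m^1.5
}

#' Closed-form Hertz inversion: indentation at a given force
#'
#' Inverts the Hertz sphere-on-half-space relation to give the indentation
#' depth reached at force `F`: \eqn{\delta = (3F / (4 E \sqrt{R}))^{2/3}}.
#' Useful for predicting the maximum indentation at the instrument's trigger
#' force (e.g. 10 nN).
#'
#' @param F force (nN).
#' @param E apparent elastic modulus (Pa).
#' @param R probe bead radius (um).
#' @return Indentation depth in um.
#' @examples
#' hertzIndentation(10, E = 1250, R = 18.64)  # ~1.24 um
#' @export
hertzIndentation <- function(F, E, R) {
  stopifnot(F >= 0, E > 0, R > 0)
  delta_m <- (3 * F * .NN / (4 * E * sqrt(R * .UM)))^(2 / 3)
  delta_m / .UM
}

# run withr::with_seed only when a seed is given
.withSeed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}
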