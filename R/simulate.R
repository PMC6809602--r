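# Synthetic AFM data with known ground truth. The generator is first-class:
# it defines the conditions under which the analysis pipeline is validated.

# Solve the implicit deflection-indentation coupling for a soft cantilever:
#   k * d = (4/3) E sqrt(R) * ((z - z0) - d)^(3/2),  delta = (z - z0) - d.
# f(d) = k d - Hertz(zc - d) is strictly increasing in d with a sign change
# on [0, zc], so bisection converges unconditionally. Vectorised over
# samples; all quantities SI.
.solveDeflectionSI <- function(zc_m, E, R_m, k) {
  C <- (4 / 3) * E * sqrt(R_m)
  lo <- rep(0, length(zc_m))
  hi <- zc_m
  for (i in seq_len(64)) {
    mid <- (lo + hi) / 2
    f <- k * mid - C * (zc_m - mid)^1.5
    neg <- f < 0
    lo[neg] <- mid[neg]
    hi[!neg] <- mid[!neg]
  }
  (lo + hi) / 2
}

#' Simulate a single AFM force-displacement curve
#'
#' Generates the raw record a colloidal-probe indentation produces: the
#' approach deflection follows the implicit relation
#' \eqn{k d = \frac{4}{3} E \sqrt{R} \delta^{3/2}} with
#' \eqn{\delta = (z - z_0) - d} (the soft cantilever deflects, so the tip
#' travels less than the piezo). The approach stops at the first sample at
#' which the force reaches the trigger `Fmax`; a mirrored retract segment is
#' appended. Optical baseline tilt, Gaussian deflection noise, and two
#' failure artifacts (probe slip, nonlinear drift) can be added. Ground
#' truth is recorded in the returned object for recovery testing.
#'
#' @param E true apparent elastic modulus (Pa).
#' @param R bead radius (um). Default 18.64 um (a ~37 um polystyrene bead).
#' @param k cantilever spring constant (N/m).
#' @param z0 contact point position (um).
#' @param zRange piezo travel (um); approach samples run from 0 to `zRange`.
#' @param dz piezo sampling step (um).
#' @param Fmax trigger force (nN); approach stops when it is reached.
#' @param noiseSD deflection noise standard deviation (nm).
#' @param baselineSlope optical-drift tilt (nm per um of z).
#' @param failureMode `"none"`, `"slip"` (a downward force discontinuity of
#'   30-60% of the current force at a random point inside contact where the
#'   force has reached at least 20% of the trigger), or `"drift"` (a strong
#'   nonlinear baseline shaped like optical interference fringes: a sine in
#'   z with 2 um period and amplitude 30% of the trigger deflection).
#' @param position stage coordinates (x, y) in um.
#' @param approachSpeed,retractSpeed recorded metadata (um/s).
#' @param temperature recorded metadata (K).
#' @param seed RNG seed; same spec + seed gives an identical curve.
#' @return A [ForceCurve-class] with `groundTruth` filled in (including
#'   `deltaFinal`, the true indentation at the trigger sample, in um).
#' @examples
#' fc <- simulateForceCurve(E = 1250, noiseSD = 0)
#' groundTruth(fc)$deltaFinal  # ~1.24 um at the 10 nN trigger
#' @export
simulateForceCurve <- function(E, R = 18.64, k = 0.03, z0 = 5,
                               zRange = 15, dz = 0.01, Fmax = 10,
                               noiseSD = 0, baselineSlope = 0,
                               failureMode = c("none", "slip", "drift"),
                               position = c(0, 0),
                               approachSpeed = 10, retractSpeed = 50,
                               temperature = 295, seed = NULL) {
  failureMode <- match.arg(failureMode)
  if (E <= 0) stop("E must be positive")
  if (R <= 0) stop("R must be positive")
  if (k <= 0) stop("k must be positive")
  if (dz <= 0) stop("dz must be positive")
  if (Fmax <= 0) stop("Fmax must be positive")
  if (noiseSD < 0) stop("noiseSD must be non-negative")
  if (z0 >= zRange)
    stop("contact point z0 = ", z0, " um lies beyond z_range = ", zRange,
         " um: no contact possible (limiting parameter: z0)")

  .withSeed(seed, {
    z <- seq(0, zRange, by = dz)
    zc_m <- pmax(z - z0, 0) * .UM
    d_m <- numeric(length(z))
    inc <- zc_m > 0
    d_m[inc] <- .solveDeflectionSI(zc_m[inc], E, R * .UM, k)
    F_nN <- k * d_m / .NN

    hit <- which(F_nN >= Fmax)
    if (!length(hit))
      stop("trigger force Fmax = ", Fmax, " nN unreachable within z_range = ",
           zRange, " um (max force ", signif(max(F_nN), 3),
           " nN at full travel; limiting parameter: zRange)")
    iTrig <- hit[1]
    z <- z[seq_len(iTrig)]
    d_m <- d_m[seq_len(iTrig)]
    F_nN <- F_nN[seq_len(iTrig)]

    deltaFinal <- (z[iTrig] - z0) - d_m[iTrig] / .UM  # um, true indentation

    slipIndex <- NA_integer_
    slipFraction <- NA_real_
    if (failureMode == "slip") {
      cand <- which(F_nN >= 0.2 * Fmax)
      slipIndex <- if (length(cand) > 1) sample(cand[-length(cand)], 1) else cand[1]
      slipFraction <- stats::runif(1, 0.3, 0.6)
      drop_m <- slipFraction * d_m[slipIndex]
      idx <- seq(slipIndex, length(d_m))
      d_m[idx] <- pmax(d_m[idx] - drop_m, 0)
    }

    drift_nm <- 0
    if (failureMode == "drift") {
      driftAmp_nm <- 0.3 * (Fmax * .NN / k) / .NM  # 30% of trigger deflection
      drift_nm <- driftAmp_nm * sin(2 * pi * z / 2)  # 2 um fringe period
    }
    d_nm <- d_m / .NM + baselineSlope * z + drift_nm
    if (noiseSD > 0) d_nm <- d_nm + stats::rnorm(length(d_nm), 0, noiseSD)

    zAll <- c(z, rev(z))
    dApp <- d_nm
    dRet <- rev(d_m / .NM + baselineSlope * z + drift_nm)
    if (noiseSD > 0) dRet <- dRet + stats::rnorm(length(dRet), 0, noiseSD)
    seg <- c(rep("approach", length(z)), rep("retract", length(z)))

    new("ForceCurve",
        z = zAll, d = c(dApp, dRet), segment = seg,
        probeRadius = R, springConstant = k, position = position,
        metadata = list(approachSpeed = approachSpeed,
                        retractSpeed = retractSpeed,
                        triggerForce = Fmax, temperature = temperature),
        groundTruth = list(E_true = E, z0_true = z0, k_true = k,
                           R_true = R, deltaFinal = deltaFinal,
                           noiseSD = noiseSD, baselineSlope = baselineSlope,
                           failureMode = failureMode,
                           slipIndex = slipIndex,
                           slipFraction = slipFraction))
  })
}

#' Simulate a thermal-noise deflection series
#'
#' Free-cantilever thermal fluctuations modelled as i.i.d. Gaussian
#' displacements with the equipartition variance
#' \eqn{\langle d^2\rangle = k_B T / k}: the core identity the thermal-noise
#' spring-constant calibration inverts. A full Lorentzian resonance spectrum
#' is deliberately not modelled.
#'
#' @param k true spring constant (N/m).
#' @param temperature bath temperature (K).
#' @param n number of samples (at least 1000).
#' @param sampleRate recorded acquisition rate (Hz).
#' @param seed RNG seed.
#' @return A [ThermalSeries-class] (samples in nm).
#' @examples
#' ts <- simulateThermalSeries(k = 0.03, temperature = 298, n = 2000, seed = 1)
#' estimateSpringConstant(ts)
#' @export
simulateThermalSeries <- function(k, temperature = 295, n = 1e5,
                                  sampleRate = 1e5, seed = NULL) {
  if (k <= 0) stop("k must be positive")
  if (temperature <= 0) stop("temperature must be positive (K)")
  if (n < 1000) stop("n must be at least 1000 for calibration use")
  sd_m <- sqrt(.kB * temperature / k)
  samples_nm <- .withSeed(seed, stats::rnorm(n, 0, sd_m)) / .NM
  new("ThermalSeries", samples = samples_nm, temperature = temperature,
      sampleRate = sampleRate)
}

#' Simulate a spatially heterogeneous tissue stiffness field
#'
#' Lays a regular measurement grid over a rectangular field (one cell per
#' measurement), draws a lognormal stiffness background, overrides cells
#' whose centers fall inside stiff circular inclusions (mimicking the
#' stiff structures a placental-bed tissue presents every few hundred
#' micrometers), and generates one synthetic force curve per cell. A
#' fraction `failProb` of cells yields slip-type failed curves. Ground
#' truth is retained for recovery tests.
#'
#' Background draws are winsorised at three log-standard-deviations around
#' the median so every generated curve can reach the trigger force within
#' the configured piezo travel.
#'
#' @param extent field width and height (um).
#' @param backgroundMedian median background modulus (Pa).
#' @param backgroundLogSD lognormal log-scale spread of the background.
#'   The default 0.86 puts ~2% of background cells above 1 kPa.
#' @param inclusions `NULL` or a data.frame with columns `x`, `y` (um),
#'   `radius` (um), `E` (Pa).
#' @param cellSize grid cell edge (um); default 20.
#' @param failProb probability a cell yields a failed (slip) curve.
#' @param curveArgs named list of overrides passed to [simulateForceCurve()]
#'   (probe, sampling and noise settings for every cell).
#' @param seed RNG seed.
#' @return A list with `truth` (matrix of ground-truth moduli, rows = y),
#'   `failed` (logical matrix), `curves` (list of [ForceCurve-class], row-major),
#'   `centers` (data.frame x, y), `cellSize`, `extent`.
#' @examples
#' fld <- simulateTissueField(extent = c(100, 100), cellSize = 20,
#'                            backgroundLogSD = 0, seed = 1)
#' dim(fld$truth)  # 5 x 5
#' @export
simulateTissueField <- function(extent = c(100, 100),
                                backgroundMedian = 171,
                                backgroundLogSD = 0.86,
                                inclusions = NULL,
                                cellSize = 20, failProb = 0,
                                curveArgs = list(), seed = NULL) {
  if (any(extent <= 0)) stop("extent must be positive")
  if (cellSize > min(extent))
    stop("cellSize = ", cellSize, " um exceeds the field extent")
  if (failProb < 0 || failProb >= 1) stop("failProb must lie in [0, 1)")
  if (backgroundMedian <= 0 || backgroundLogSD < 0)
    stop("background parameters must be positive")
  if (!is.null(inclusions)) {
    stopifnot(all(c("x", "y", "radius", "E") %in% names(inclusions)))
    if (any(inclusions$radius <= 0) || any(inclusions$E <= 0))
      stop("inclusion radii and moduli must be positive")
  }

  nx <- floor(extent[1] / cellSize)
  ny <- floor(extent[2] / cellSize)
  cx <- (seq_len(nx) - 0.5) * cellSize
  cy <- (seq_len(ny) - 0.5) * cellSize
  centers <- expand.grid(x = cx, y = cy)  # row-major over y then x

  defaults <- list(R = 18.64, k = 0.03, z0 = 2, zRange = 30, dz = 0.02,
                   Fmax = 10, noiseSD = 2)
  ca <- utils::modifyList(defaults, curveArgs)

  .withSeed(seed, {
    E <- if (backgroundLogSD == 0) {
      rep(backgroundMedian, nrow(centers))
    } else {
      logE <- stats::rnorm(nrow(centers), log(backgroundMedian),
                           backgroundLogSD)
      lim <- 3 * backgroundLogSD
      exp(pmin(pmax(logE, log(backgroundMedian) - lim),
               log(backgroundMedian) + lim))
    }
    if (!is.null(inclusions)) {
      for (i in seq_len(nrow(inclusions))) {
        inside <- (centers$x - inclusions$x[i])^2 +
          (centers$y - inclusions$y[i])^2 <= inclusions$radius[i]^2
        E[inside] <- inclusions$E[i]
      }
    }
    fail <- stats::runif(nrow(centers)) < failProb
    curves <- vector("list", nrow(centers))
    for (i in seq_len(nrow(centers))) {
      args <- c(list(E = E[i],
                     position = c(centers$x[i], centers$y[i]),
                     failureMode = if (fail[i]) "slip" else "none"),
                ca)
      curves[[i]] <- do.call(simulateForceCurve, args)
    }
    list(truth = matrix(E, nrow = ny, ncol = nx, byrow = TRUE),
         failed = matrix(fail, nrow = ny, ncol = nx, byrow = TRUE),
         curves = curves,
         centers = centers, cellSize = cellSize, extent = extent)
  })
}
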