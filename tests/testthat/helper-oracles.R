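# Independent closed-form oracles, kept free of package internals.

kB <- 1.380649e-23

# Hertz forward model computed directly in SI units.
oracleHertzForce_nN <- function(E_Pa, R_um, delta_um) {
  (4 / 3) * E_Pa * sqrt(R_um * 1e-6) * (delta_um * 1e-6)^1.5 / 1e-9
}

# Closed-form inversion: indentation (um) at force F (nN).
oracleDelta_um <- function(F_nN, E_Pa, R_um) {
  ((3 * F_nN * 1e-9) / (4 * E_Pa * sqrt(R_um * 1e-6)))^(2 / 3) / 1e-6
}

# Build a ThermalSeries with an exactly known unbiased variance (m^2).
thermalSeriesWithVariance <- function(var_m2, n = 1000, temperature = 298) {
  a_m <- sqrt(var_m2 * (n - 1) / n)
  new("ThermalSeries", samples = rep(c(-a_m, a_m), n / 2) / 1e-9,
      temperature = temperature, sampleRate = 1e5)
}

# Minimal hand-built raw curve: z in um, d in nm, single approach segment.
rawCurve <- function(z, d, R = 18.64, k = 0.03, position = c(0, 0)) {
  new("ForceCurve", z = z, d = d, segment = rep("approach", length(z)),
      probeRadius = R, springConstant = k, position = position,
      metadata = list(approachSpeed = 10, retractSpeed = 50,
                      triggerForce = 10, temperature = 295))
}
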