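# hertzmap

Hertzian analysis of AFM force curves and tissue stiffness mapping.

## The problem

Atomic force microscopy (AFM) indentation with a colloidal (bead) probe is
the standard way to measure the stiffness of very soft biological samples —
reproductive tissues such as endometrium, decidua and placental villi, and
basement-membrane hydrogels like Matrigel®, all in the 10²–10⁴ Pa range.
The instrument records only piezo z-position and cantilever deflection;
everything of scientific interest (the apparent elastic modulus, its
spatial variation, group differences between tissues) must be recovered
from those raw force–displacement curves. `hertzmap` implements that
pipeline for R users: calibration, curve processing, Hertzian fitting,
quality control, force-volume stiffness maps, and the nonparametric
statistics layer used in tissue biomechanics.

## The model

For a rigid sphere of radius *R* indenting an elastic half space to depth
δ, the Hertz model gives

    F = (4/3) · E_a · √R · δ^(3/2)

where *E_a* is the **apparent elastic modulus** — no (1 − ν²) Poisson term
is applied, acknowledging that soft tissue is not an ideal elastic solid.
Because the cantilever is itself soft, the tip indents less than the piezo
travels: with deflection *d*, force is *F = k·d* and indentation is
δ = (z − z₀) − d, with z₀ the contact point. The pipeline:

1. **Calibration** — spring constant *k* from the thermal-noise method
   (equipartition: k = k_B·T / var(d)).
2. **Baseline correction** — least-squares line over the leading
   non-contact travel, iteratively re-fitted once the contact point is
   known.
3. **Contact point** — two-regime piecewise fit (flat before z₀,
   Hertz-shaped after), grid-searched over samples.
4. **Modulus** — origin-constrained regression of *F* on δ^(3/2) over
   δ ∈ [0, 2 μm]; E_a = (3/4)·m/√R. The uncentered R² of this regression
   is the linearity diagnostic.
5. **QC** — curves failing linearity (R² < 0.90), showing force
   discontinuities (probe slip) or non-flat baselines are marked failed
   and excluded from maps and statistics, but kept as crosses.
6. **Mapping** — one measurement per 20 × 20 μm grid cell; failed cells
   are explicit markers, never interpolated.
7. **Statistics** — median per sample, mean of medians per tissue,
   D'Agostino–Pearson normality screen, Mann–Whitney, Wilcoxon
   signed-rank, Kruskal–Wallis with Dunn's post-hoc (Holm-adjusted), and
   an OLS dilution regression for hydrogel standards.

A synthetic-data generator produces force curves with known ground truth
(solving the implicit cantilever–sample coupling by bisection), thermal
deflection series, and spatially heterogeneous stiffness fields with stiff
inclusions and failure artifacts, so the whole pipeline is testable end to
end without instrument data.

## Worked example

```r
library(hertzmap)

# calibrate a cantilever from thermal noise
ts  <- simulateThermalSeries(k = 0.03, temperature = 298, n = 1e5, seed = 1)
cal <- estimateSpringConstant(ts)
cal
#> CantileverCalibration: thermal_equipartition
#>   k = 0.02979 N/m from 100000 samples at 298 K

# a stiffness field with stiff inclusions on a 171 Pa background
fld <- simulateTissueField(
  extent = c(100, 100), backgroundMedian = 171,
  inclusions = data.frame(x = 30, y = 30, radius = 25, E = 5000),
  failProb = 0.1, seed = 42)

run <- runPipeline(fld$curves, calibration = cal)
run$map
#> StiffnessMap: 5 x 5 cells of 20 um; 4 failed (crosses)
#>   median E_a = 485.2 Pa
run$summary$fractionAbove   # fraction of passing cells stiffer than 1 kPa
#> [1] 0.2380952

# compare two tissues' pooled measurements
set.seed(99)
g <- list(basalis    = rlnorm(75, log(1250), 0.86),
          parietalis = rlnorm(75, log(171), 0.86))
runComparison(g, test = "mann_whitney")
#> GroupComparison: mann_whitney on basalis vs parietalis
#>   statistic = 5254 , p = < 2.2e-16 ****

# hydrogel dilution series
x <- c(40, 60, 80, 100)
fitDilutionRegression(x, 4.5 * x - 111.3)
#> DilutionFit: E_a = 4.5 * concentration  - 111.3  Pa,  R2 = 1
```

The map's `fractionAbove` is the size of the stiff tail: fields with stiff
inclusions show a large >1 kPa fraction, inclusion-free fields only the
few percent produced by the lognormal background.

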