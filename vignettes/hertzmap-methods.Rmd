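---
title: "Methods: Hertzian AFM curve analysis and stiffness mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Hertzian AFM curve analysis and stiffness mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hertzmap)
```

## The measurement and its model

A colloidal-probe AFM indentation measurement lowers a tipless cantilever
carrying a glued polystyrene bead (here ~37 μm diameter, so bead radius
R = 18.64 μm by default) onto a soft sample at ~10 μm/s until a trigger
force (10 nN) is reached, then retracts at ~50 μm/s. The record is piezo
z-position against cantilever deflection. Force follows from the spring
constant, F = k·d, and the tip–sample indentation is the piezo travel past
contact minus the cantilever's own deflection:

$$\delta = (z - z_0) - d.$$

For a rigid sphere on an elastic half space the Hertz model gives

$$F = \tfrac{4}{3}\, E_a\, \sqrt{R}\, \delta^{3/2},$$

with $E_a$ the *apparent* elastic modulus. The $(1-\nu^2)$ Poisson factor
is deliberately omitted (soft tissue is not an ideal elastic solid, and
the quantity of interest is the effective stiffness as fitted); an opt-in
Poisson correction would simply rescale $E_a$ by $1/(1-\nu^2)$ and is left
to the user at interpretation time.

Assumptions and their checks, reported per curve in a `ValidityReport`:

* **Rigid probe.** Polystyrene (~10⁹ Pa) is ≥5 orders stiffer than the
  10²–10⁴ Pa samples targeted.
* **Small strain.** Contact radius $a = \sqrt{R\delta}$; the strain scale
  $\epsilon = 0.2a/R$ is ~0.066 at the default 2 μm depth. Deviations from
  linear elasticity are expected above ~0.02, so $\epsilon$ is recorded
  with the configured bound but never used to hard-fail a curve — the
  modulus is "apparent" precisely because tissue is measured beyond the
  ideal-elastic regime.
* **Half space.** $a/h < 0.1$ with sample thickness $h$ (default 5000 μm,
  a 0.5 cm block): $a/h \approx 0.0012$, comfortably satisfied.

## Pipeline choices

**Units.** SI (m, N, Pa) inside every numerical routine; μm, nm, nN at all
interfaces and file formats, matching instrument software. This split
confines unit conversions to well-tested boundaries.

**Baseline.** A least-squares line over the leading 50% of the approach
travel (configurable) models optical drift. On very soft samples the
contact region can occupy most of the travel, so `analyzeCurve()` iterates:
after the first contact estimate the baseline is re-fitted over 90% of the
pre-contact travel only and contact is re-detected, up to three passes or
until the contact point moves less than 1% of the travel. Without this,
curves at ~50 Pa lose ~10% of their modulus to baseline contamination.

**Contact point.** A two-regime piecewise fit rather than a deflection
threshold: deflection is modelled as zero before the candidate $z_0$ and
proportional to $\delta^{3/2}$ after, and $z_0$ minimises the total squared
residual. The search is coarse-to-fine over the sample grid (≈200 coarse
candidates, then single-sample refinement), keeping cost near-linear in
curve length. On noiseless curves this recovers $z_0$ to within one
sampling step; at 1 nm deflection noise the median error stays below five
steps. A curve whose maximum deflection is under five times the baseline
noise is classified "no contact".

**Modulus.** Origin-constrained least squares of $F$ on $\delta^{3/2}$ over
$\delta \in [0, 2\,\mu m]$, so every sample in the evaluation window
contributes rather than a single point; $E_a = \tfrac{3}{4} m / \sqrt{R}$.
The uncentered $R^2$ of this regression is the linearity diagnostic — the
quantitative version of requiring the linearised force–indentation curve
to be a straight line. A single-point estimate at the evaluation depth is
reported alongside for comparison. Curves that hit the 10 nN trigger
before 2 μm (stiff spots: at 1250 Pa the closed-form trigger indentation
is ~1.25 μm) are fitted over their available depth and flagged `shallow`
but retained — discarding them would censor exactly the stiff tail of
interest.

**Quality control.** Failure rules, applied in order:
baseline flatness (RMS pre-contact force ≤ 2% of peak force — a clean
baseline is flat; interference-fringe-like drift violates this or the
linearity rule), slip (any force drop inside contact exceeding
max(5% of peak force, 6× the baseline force noise, 0.05 nN) — a probe
sliding over tissue produces a discontinuity), and linearity
($R^2 \ge 0.90$ by default; the threshold is configuration, logged in the
run manifest). Failed curves stay visible as crosses in maps.

**Maps.** One measurement slot per half-open 20 × 20 μm cell, row-major
with rows indexed by y (the convention is written into every map header).
Two measurements in one cell is an error, not an average. Failed cells are
never interpolated. The map summary reports the count above a 1 kPa
threshold — the tail statistic that distinguishes tissue invaded by stiff
structures from uniform soft tissue.

**Statistics.** Modulus distributions within a sample are skewed and
heavy-tailed, so the estimator chain is median per sample, then the
arithmetic mean of sample medians per tissue (each patient sample counts
once regardless of how many grid points it contributed). The
D'Agostino–Pearson $K^2$ omnibus test screens normality; group comparisons
are nonparametric: Mann–Whitney (exact two-sided p for combined n ≤ 20
without ties, tie-corrected normal approximation otherwise), Wilcoxon
signed-rank for paired samples, and Kruskal–Wallis followed by Dunn's
pairwise z comparisons with Holm adjustment (the adjustment method is
configurable and logged). The $K^2$ and Dunn procedures are implemented in
the package from their published formulas. The dilution regression is
ordinary least squares of per-batch median modulus on concentration
(% v/v): a hydrogel series diluted with culture medium is well described
by a line over the 40–100% range, and OLS on that line's form is used even
though such series are sometimes summarised with nonlinear fits.

## The synthetic-data generator

The generator is the package's test bed: it defines the conditions under
which the pipeline is validated.

* **Curves.** The approach deflection solves the implicit coupling
  $k d = \tfrac{4}{3} E \sqrt{R} ((z - z_0) - d)^{3/2}$ per sample by
  bisection (the relation is monotone in $d$), because that is what a soft
  cantilever physically measures and it exercises the same deflection
  correction the analysis applies. The approach stops at the first sample
  at or past the 10 nN trigger; a mirrored retract is appended for format
  fidelity and ignored by analysis. Defaults follow the instrument
  protocol: R = 18.64 μm, k = 0.03 N/m (inside the 0.01–0.1 N/m cantilever
  range), 10 nN trigger, 10 nm piezo step.
* **Artifacts.** Gaussian deflection noise (2 nm typical), linear optical
  tilt, and two labelled failure modes: *slip*, a downward force
  discontinuity of 30–60% of the current force at a random contact point
  where force has reached ≥20% of the trigger (a discontinuity at
  near-zero force would be no discontinuity at all); and *drift*, an
  interference-fringe-like sinusoidal baseline (2 μm period, amplitude 30%
  of the trigger deflection) — the classic optical artifact that defeats
  straight-line baselines.
* **Thermal series.** I.i.d. Gaussian displacements at the equipartition
  variance $k_B T / k$. A full Lorentzian resonance spectrum, mode-shape
  corrections and optical-lever sensitivity calibration are out of scope;
  the estimator exposes an optional multiplicative correction (default 1)
  and a calibration temperature defaulting to 295 K (room temperature,
  where tissue is measured; hydrogels are measured at 37 °C but
  calibration precedes measurement).
* **Fields.** Per-cell ground truth: lognormal background (median 171 Pa
  by default) overridden inside circular stiff inclusions, emulating soft
  decidual stroma punctuated by stiff vascular columns a few hundred μm
  apart. The default log-scale spread 0.86 puts ~2% of background cells
  above 1 kPa, matching the observed tail of uniform soft tissue; fields
  with inclusions covering roughly a third of cells reproduce the ~35%
  stiff tail seen at an implantation site. Background draws are winsorised
  at ±3 log-SD so every cell's trigger force is reachable within the
  configured piezo travel. What the generator does *not* emulate:
  viscoelastic/poroelastic response, adhesion (JKR/DMT), spatial
  correlation of the background, cantilever hydrodynamics. Passing
  recovery tests therefore demonstrates correctness of the elastic
  analysis chain, not robustness to every physical artifact of real
  tissue.

## Numerical notes

* Bisection uses 64 iterations on a bracket no wider than the local piezo
  travel, i.e. converges to machine precision; noiseless round trips
  recover $E$ to ~10⁻¹⁶ relative.
* The bead dimension is stated by its manufacturer in μm; the package's
  default radius is 18.64 μm, consistent with the ~12 μm contact diameter
  at 2 μm depth.
* Half-open windows $[start, end)$ everywhere; ties in the contact-point
  grid search resolve to the earliest minimising sample.
* Problem sizes in the test suite (500-curve Monte-Carlo recovery,
  200-curve QC arms, 50-seed field contrasts, 1000-rep null calibration)
  were chosen so the full suite completes in about two minutes on one
  core while keeping binomial uncertainty on the verified rates a few
  times smaller than the margins being asserted.

## Known limitations

* No vendor binary readers; only the documented plain-text TSV dialect.
* No bottom-effect (finite thickness) correction: thin samples violating
  $a/h < 0.1$ are flagged, not corrected.
* The per-tissue absolute moduli of any particular study are not
  reproducible from synthetic data; the package validates the method
  (recovery, calibration, discrimination), and its statistics layer is
  checked against exact enumeration and reference implementations rather
  than against any published per-sample dataset.
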