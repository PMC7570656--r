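---
title: "Method development statistics: from source optimization to pharmacokinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Method development statistics: from source optimization to pharmacokinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavopk)
```

flavopk implements the statistical chain of an LC-MS/MS method-development
study for small molecules in plasma: screening and optimizing the
electrospray (ESI) source by design of experiments, validating the assay,
and applying it in a noncompartmental pharmacokinetic (NCA) comparison.
This vignette documents the models, the conventions behind each numerical
choice, and what the synthetic-data generators do and do not emulate.

## Factor coding

Each instrument factor is described by the three actual settings mapped to
coded −1/0/+1. The center is not assumed to be the arithmetic midpoint:
coding is piecewise affine, `[low, center] → [−1, 0]` and
`[center, high] → [0, 1]`, so decoding is always an exact inverse on
`[low, high]`. For the packaged factor tables the centers happen to be
midpoints and the two conventions coincide, but the contract does not rely
on it. Values outside `[low, high]` are rejected rather than extrapolated.

## Screening: Plackett–Burman main effects

`pb_design()` builds the classical cyclic 12-run Plackett–Burman base: 11
mutually orthogonal two-level columns, each balanced at six highs and six
lows. With *k* real factors the remaining 11 − *k* columns ride along as
dummy columns; their "effects" estimate pure experimental error. The main
effect of a column is

$$E(X_i) = \frac{2\,(\sum M_{i+} - \sum M_{i-})}{N},$$

the high-level total minus the low-level total, doubled and divided by the
number of two-level runs — on a balanced design this equals the difference
of level means, and exactly twice the OLS coefficient of the coded column
(a property the tests exercise against `lm()`).

Significance testing of saturated screening designs is not uniquely
defined, so `rank_effects()` offers three routes and defaults to Lenth's
pseudo-standard-error: with effects $c_j$, $s_0 = 1.5\,\mathrm{median}|c_j|$
and $PSE = 1.5\,\mathrm{median}\{|c_j| : |c_j| < 2.5 s_0\}$, with $m/3$
degrees of freedom for the *m* effect columns. Lenth's method needs no
replication, which is the usual situation in a 12-run screen; the
dummy-column RMS and center-replicate routes are provided for designs that
have those resources. None of the three is asserted to be "the" method any
given software package used — they answer the same question and generally
agree on which factors matter. When the requested error source is missing
the effects are still ranked by magnitude, with the test statistics
reported as `NA` rather than silently switching method.

## Optimization: Box–Behnken response surface

`bbd_design()` generates the 3-factor Box–Behnken design: 12 edge
midpoints (each pair of factors at ±1 with the third at 0) plus
replicated center runs, 17 runs in the 12 + 5 layout. The full quadratic

$$Y = b_0 + \sum b_i x_i + \sum b_{ii} x_i^2 + \sum_{i<j} b_{ij} x_i x_j + \varepsilon$$

is fitted by OLS (10 parameters for k = 3; at least 11 runs are required
so the fit is not saturated). `anova_quadratic()` splits the residual sum
of squares into pure error — from the center replicates only, df = n_center
− 1 — and lack of fit, tested with an F ratio. When all center replicates
are identical the pure error is zero and the F ratio is reported as
undefined via an explicit flag instead of a division by zero.

### Stationary point vs operating optimum

The stationary point solves the zero-gradient linear system $Hx = -b$
(Hessian $H$ with $2b_{ii}$ on the diagonal, $b_{ij}$ off it) and is
classified by the Hessian eigenvalue signs. For the packaged reference
surface (`esi_surface_model()`) the stationary point is a saddle at coded
(4.199, −1.306, 0.604) — outside the explored region, so it is *not* an
operating recommendation. The package therefore always reports both the
stationary point (as a description of the surface) and the cube-constrained
optimum, and treats the latter as "the optimum".

`constrained_optimum()` finds the exact global maximum over $[-1,1]^k$ by
enumerating all $3^k$ cells of the cube (each coordinate pinned at −1, +1,
or left free), solving the reduced stationary system on every face and
keeping solutions inside their face, with all vertices always included.
A quadratic restricted to a face is again a quadratic, so the global
optimum over the compact cube is necessarily among these candidates; there
is no dependence on starting values or step sizes, and the tests verify
agreement with a 0.01-step brute-force grid on 100 random quadratics. The
"inside the region" test uses the tolerance |coordinate| ≤ 1 + 1e−9 so a
boundary optimum is not misreported as exterior; the gradient residual at
a reported stationary point is required to be below 1e−8 in norm.

For the reference surface the constrained maximum sits at the vertex
(−1, +1, +1): nebulizer 40 psi, sheath gas temperature 400 °C, nozzle
voltage 1500 V, predicted response 3219.1.

## Validation statistics

**Calibration** is unweighted OLS of peak area on concentration — no
weighting scheme is assumed, though `1/x`-style weights can be passed —
with t-based confidence half-widths $t_{\alpha/2} S_b$ and
$t_{\alpha/2} S_a$, Pearson *r*, and the residual standard deviation
$S_{y,x}$ on n − 2 df. An intercept interval containing zero sets a
"crosses the origin" flag. With replicate areas per level a lack-of-fit F
test against pure error is added; under a true linear model its p-value is
uniform (tested by Kolmogorov–Smirnov over 500 seeded simulations).

**Detection limits** use $L = k\,S_{y,x}/b$ with k = 3 (LOD) and k = 10
(LOQ), computed from a dedicated low-range calibration curve; LOQ/LOD =
10/3 identically. Concentration limits convert to on-column mass by
multiplying by the injection volume (ng/mL × µL = pg; 0.4 ng/mL at 2 µL is
0.8 pg).

**Precision and accuracy**: RSD = 100·sd/mean (sample sd) and accuracy =
100·mean/nominal. Intra-day statistics use the replicates of one day (the
n = 9 convention for nine replicates per day); inter-day statistics pool
all days (n = 27 for three such days). The pooled mean — not the mean of
daily means — defines inter-day accuracy; with equal replication the two
coincide.

**Recovery and matrix effect** compare three peak-area sets per QC level:
pure standard (R1), post-extraction spike (R2), pre-extraction spike (R3).
Recovery = 100·R̄3/R̄2 isolates extraction losses; matrix effect =
100·R̄2/R̄1 isolates ionization suppression (< 85%) or enhancement
(> 115%). The pooled summary across QC levels is the arithmetic mean ±
sample sd of per-level percentages. Report tables print integer
percentages (half-away-from-zero rounding, `round_half_up()`);
`overall_matrix_effect(..., rounded = TRUE)` averages those integer
percentages, reproducing the summary a reader computes from a printed
table, while the default averages the raw values. Raw unrounded values are
always retained in result objects; rounding only happens at the reporting
surface.

## Noncompartmental pharmacokinetics

**Profile assembly.** In a destructive sampling design each timepoint
comes from different animals (17 timepoints × 3 animals = 51 on the
default grid), so no real subject has a full curve. `assemble_profiles()`
offers the per-timepoint **mean profile** (with sds retained) and the
**pseudo-subject** scheme — the i-th composite profile concatenates the
i-th animal at every timepoint. Pseudo-subject is the default because it
yields n profiles and hence per-parameter sds of the kind PK summary
tables report with n = 3; it is a convention, not a claim that animal i at
one timepoint is related to animal i at another.

**Conventions**, chosen to match common NCA software defaults where the
field has no single rule:

* AUC/AUMC use the linear trapezoid (log-down available as an option).
  The trapezoid is exact for AUC on linear segments; AUMC is the same
  trapezoid applied to the moment curve t·C(t).
* Oral profiles with no t = 0 sample get a C(0) = 0 anchor before
  integration (configurable via `c0`); the AUC window must be covered by
  data — no extrapolation beyond the last sample.
* λz selection scans every contiguous terminal tail of ≥ 3 positive
  concentrations strictly after Tmax and keeps the largest adjusted R²,
  preferring more points on ties (the "best fit" rule). Manual index
  selection is available. A non-declining tail is an error, not a
  negative half-life.
* Concentrations below the LOQ are conventionally zeroed before Tmax and
  excluded after it upstream of profile construction.
* CL/F = dose/AUC₀₋ₜ and V/F = CL/λz in the (mg)/(ng/mL) unit family:
  doses enter in mg (mg/kg × body weight, defaulting to 0.225 kg for a
  200–250 g rat when unrecorded), concentrations in ng/mL. The units are
  kept verbatim rather than converted to litres, matching how oral NCA
  tables are usually printed; because F is unknown both are apparent
  quantities.
* Arm comparisons are two-sided t-tests, Welch by default, pooled
  optionally; the summary-statistics entry point (`mean`, `sd`, `n`)
  allows comparing printed tables without raw data. Tests check the
  pooled hand value t = −4.899 for (10 ± 1 vs 14 ± 1, n = 3) and a null
  rejection rate in [3%, 7%] over 2000 simulations.

## Synthetic data: what it emulates and what it does not

The generators produce data under the *assumed* models: exact quadratic
surfaces plus iid Gaussian noise; exactly linear calibration with constant
or proportional noise; multiplicative matrix and recovery factors acting
on expected areas; and one-compartment first-order-absorption (Bateman)
kinetics

$$C(t) = \frac{D\,k_a}{(V/F)(k_a - k_e)}\bigl(e^{-k_e t} - e^{-k_a t}\bigr)$$

with lognormal between-animal error of stated CV
($\eta \sim N(0, \log(1+cv^2))$ multiplicatively — concentrations stay
positive and the CV is constant, the usual bioanalytical error shape). The
degenerate case $k_a = k_e$ is rejected rather than handled by the
limiting $t e^{-kt}$ form. Defaults echo realistic magnitudes for a
flavonoid assay: absorption 1.5/h, elimination ln 2/3 h⁻¹ (a 3 h
half-life), V/F 0.34 (mg)/(ng/mL), a 69 mg/kg dose in a 225 g animal,
10% residual CV, 3 animals at each of the 17 sampling times (5 min to
24 h). They are plausible-order defaults, not estimates of any particular
compound.

Passing tests on these data show the estimators recover known truth under
the assumed models. Real instrument data violate them in ways the
generators deliberately do not emulate: integration artifacts and
carryover in peak areas, heteroscedasticity beyond the two noise shapes,
enterohepatic recirculation or multi-compartment kinetics, correlated
within-animal errors, and BLQ censoring mechanics. Conclusions about those
failure modes cannot be drawn from this test suite.

All generators are bit-reproducible given a seed; simulation sizes used in
the tests (200 seeded replicates for the end-to-end recovery properties,
500 for coverage/uniformity checks, 2000 for the t-test error rate) were
chosen to keep Monte-Carlo error well below the asserted margins while the
whole suite runs in about a minute.

## Known limitations

* The Box–Behnken generator covers exactly 3 factors; central-composite
  and D-optimal designs, >3-factor response surfaces and multi-response
  desirability optimization are out of scope.
* AUC is truncated at the last observation window (AUC₀₋₂₄ by default);
  extrapolation to infinity is not implemented.
* Recovery/matrix-effect inference is moment-based (ratio of means);
  no delta-method CIs are reported.
* `read_table()` handles comma/tab text tables only — peak areas are
  assumed to be integrated upstream; there is no chromatogram or vendor
  file ingestion.
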