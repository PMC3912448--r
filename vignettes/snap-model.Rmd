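---
title: "The SNAP soil-carbon model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The SNAP soil-carbon model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snapsoc)
```

## The model and its assumptions

SNAP is an annual mass balance for the stable soil organic carbon (SOC)
pool of tropical grasslands. It rests on four assumptions:

1. **Compensation.** Grazed C4 swards trade stem for leaf, so leaf area
   index (LAI) — the proxy for carbon assimilation — is roughly flat up to
   intermediate grazing intensity and collapses only near complete
   off-take. This is the model's distinctive ingredient: it makes grazing
   effects on SOC non-monotone.
2. **Stable carbon only.** Only lignin + cellulose survives decomposition
   long enough to matter for stocks; everything else is assumed respired
   within a year or two and is not tracked. One pool, no fractions.
3. **Input pathways.** Stable carbon enters soil from decomposing shoots
   (the fraction neither grazed nor burned), from roots, and from dung
   (grazed biomass returned and incorporated by macro-decomposers).
4. **Loss pathway.** The only loss from the stable pool is microbial
   respiration, proportional to the number of days the soil is moist
   enough for microbial activity (soil moisture above 10% gravimetric),
   a texture-dependent access factor, and a linear function of the stock.

A single annual time step with a 240-day wet season is used; fire burns
only the biomass grazers left, hence the `(1 - GI)(1 - FIRE)` product in
the plant-derived input. Nitrogen and temperature are deliberately
excluded: across tropical rainfall gradients soil moisture dominates both,
and a five-driver model keeps every parameter measurable in the field.

Setting the annual change to zero yields a closed-form equilibrium,

$$\mathrm{SOC_{eq}} = \frac{\mathrm{PDSOC} + \mathrm{DDSOC} +
0.579\,\mathrm{WETDAYS}\,s}{0.00044\,\mathrm{WETDAYS}\,s},
\qquad s = 0.7 + 0.3\,\mathrm{SAND\%}/100,$$

which decomposes into a *floor* of $0.579/0.00044 \approx 1316$ gC/m²
(where the daily respiration rate regression crosses zero) plus annual
inputs divided by the per-unit-stock loss rate. Because the annual map is
affine and contracting in the stock (`|1 - 0.00044 * WETDAYS * s| < 1`
everywhere in the supported driver space), this fixed point is the global
attractor of the iterated annual balance — `simulate_trajectory()` and
`soc_equilibrium()` are independent routes to the same number, and the
test suite checks their agreement on 200 randomly generated sites.

## Coefficients: two registries, kept apart

The model's constants come from fitted sub-models, and they circulate in
two slightly different versions: the constants embedded in the equations
above, and the fitted-coefficient table used for error propagation (0.597
vs 0.6 for the leaf intercept, 958.8/−0.82 vs 917.4/−0.763 for
belowground production, 1.04/−0.0070 vs 1.33/−0.0075 for the
water-holding adjustment, 0.00043 vs 0.00044 for the wet-day slope). Which
variant produced any given published figure is not always decidable, so
the package stores both as named registries — `"text-equations"` (the
deterministic default) and `"table2-mc"` — and never merges them. The
`"text-equations"` set carries the error table's standard errors attached
to its own values so that Monte Carlo propagation is centred on the
deterministic model. The registries serialise to a flat
`name value se source` text file with 17 significant digits, so a
write/read round trip is bit-exact.

The two sets also differ structurally in the LAI curve. The ratio form
`P_L / pl_intercept - b1 exp(b2 GI)` ties the curve's plateau to the leaf
proportion sub-model (LAI = 0.985 at GI = 0); the directly fitted form
uses an intercept of 1.15. Both are supported via the `use_lai_b0` switch
in the registry; the default follows the ratio form. The exponent is
parameterised with a positive growth rate (`b1, b2 > 0`,
`LAI = b0 - b1 exp(b2 GI)`), the only sign convention under which the
fitted values (1.15, 0.015, 4.6) describe a curve that is flat at low
grazing and collapses at high grazing.

## Numerical choices

* **LAI clamp.** The fitted curve goes negative for GI ≳ 0.98; LAI is
  clamped at 0 (leaf area cannot be negative), which also forces
  `anpp_est -> 0` at complete grazing.
* **Wet-day clamp.** The wet-day regression is negative below ~57 mm/yr;
  the result is clamped to [0, 240]. A site with zero wet days has no
  defined equilibrium and `soc_equilibrium()` refuses it.
* **Respiration clamp.** The daily maximum respiration rate is negative
  for stocks below the ~1316 gC/m² floor. In transient simulations the
  rate is clamped at 0 so low stocks cannot grow by "negative
  respiration"; the closed form is evaluated without the clamp, as the
  algebra requires, which is safe because the equilibrium always sits at
  or above the floor. The clamp makes the annual map piecewise affine;
  its fixed point lies on the upper piece, where the two formulations
  coincide.
* **Validity envelope.** The production regressions are not extrapolated:
  rainfall must exceed the aboveground zero-production root (~33 mm/yr)
  and stay below the belowground root (~1202 mm/yr). Point predictions
  fail loudly outside the envelope; grid sweeps (`cmd_grid()`) mark
  offending cells `NaN` and warn, because sweeps are exploratory while
  point predictions are contractual.
* **Convergence.** Trajectories stop when the annual change falls below
  `1e-6` of the closed-form equilibrium, with a hard cap of 1e5 years;
  the contraction property guarantees geometric convergence, so the cap
  is a safety net only.

## Monte Carlo error propagation

`monte_carlo_soc_eq()` perturbs every registry coefficient with a nonzero
standard error, and optionally the three measured drivers (grazing
intensity, lignin + cellulose, rainfall) using their site standard errors,
as independent normal draws. Independence is an acknowledged limitation:
no covariance structure between fitted coefficients is available, and
intercept/slope pairs from the same regression are in reality negatively
correlated, so the propagated spread is conservative. Draws that violate
the model's domain (proportions outside [0, 1], rainfall outside the
envelope, no wet days, non-positive equilibrium) are **rejected**, not
clipped — clipping would pile probability mass on the domain boundary and
bias the mean. Rejection is accounted for: `retained + rejected =
n_draws`, and the summary reports the retained count.

Conventions: `sem = sd(draws)/sqrt(retained)` (the standard error of the
Monte Carlo mean over the repetitions) and `cv = sd/mean`. With 100 draws
per site — the default — the eight packaged validation sites give
per-site standard errors of a few hundred gC/m², i.e. a few percent of
the predicted stocks.

## Sensitivity analysis

`sensitivity_analysis()` is one-at-a-time by design (no variance-based
indices): each driver is set to a low/medium/high level
(rain 450/650/900 mm; fire 0.25/0.5/0.75; GI 0.25/0.6/0.9; lignin +
cellulose 0.15/0.25/0.35; sand 25/45/70) and perturbed by +10%, and the
absolute percent change in equilibrium SOC is recorded against the
unperturbed equilibrium of the *same* background. "Holding other
parameters constant" is ambiguous, so two background policies are
exposed: the default evaluates every combination of the other four
drivers' levels (a 3^4 factorial, whose spread supplies the reported
standard error); `"medium"` holds the others at their middle level.
Perturbed proportions that would leave [0, 1] are clipped with a warning
(GI 0.9 perturbs to 0.99, which is valid; a fire frequency of 1 would
clip).

The ranking this produces is dominated by grazing intensity at its upper
level (~21% mean absolute change, about twice any other cell), the direct
signature of the compensation collapse. Rainfall and litter quality are
comparable in the mid range; fire has little leverage on the
*equilibrium* because it enters only the aboveground input term — its
importance in this model is its interaction with grazing (below), not its
main effect.

## The fire-grazing interaction

Under frequent fire, moderate grazing *increases* equilibrium SOC: grazed
carbon re-enters the soil as dung instead of burning, and compensation
keeps assimilation high. With `fire = 0.75` the optimum grazing intensity
is clearly interior (the equilibrium at the optimum exceeds the ungrazed
value by well over 10%). Without fire the curve is nearly flat at low
grazing — the interior advantage is under 5%, because with no fire the
total above-ground input `0.45 * LIGCELL * ANPP_est * [(1-GI)(1-FIRE) + GI]`
collapses to `0.45 * LIGCELL * ANPP_est`, which peaks wherever LAI does
(GI ≈ 0.38) — and all curves drop steeply beyond ~70% grazing. The package
treats the small no-fire interior optimum as a real property of the
equations and tests it as such.

## Validation data and what the regression shows

`load_experiment_sites()` ships the site-mean drivers and soil
measurements of an eight-site, nine-year grazing exclosure experiment
spanning 450–900 mm rainfall, sandy to silty-clay soils and grazing
intensities of 0.28–0.69, with fires counted over a nine-year monitoring
window (`fire = fires/9`). The transcription is guarded by a checksum.
Observed stocks are reconstructed as
`soil C%/100 x bulk density x 40 cm x 1e4` (gC/m²), the standard
carbon-density product over the rooting depth; no correction for coarse
fragments or assay recovery is applied, because none can be derived from
the site table alone.

`validate_site_level()` predicts the equilibrium for each site, fits OLS
`observed ~ predicted`, and z-tests slope = 1 / intercept = 0 on the OLS
standard errors. On the packaged site means with default coefficients
this regression has essentially no explanatory power (R² ≈ 0.003,
slope ≈ −0.03): the two driest sites dominate the prediction range —
their equilibria are high because few wet days mean little respiration —
yet their observed stocks sit at opposite ends of the observed range
(≈ 10.7 and ≈ 6.4 kgC/m²). Nothing in the site-mean table separates those
two sites enough for *any* setting of this model's equations to pull them
apart; pulling them apart would require inputs measured per site or per
plot (most plausibly directly measured wet days, which the rainfall
regression only summarises) that the site-mean table does not carry.
We verified this is not a coefficient
issue: both packaged registries, and a factorial sweep over the
defensible structural variants (fire denominator, wet-season length,
sand-access factor, root-offset form), leave R² below 0.05. The
reconstruction of *observed* stocks is also uncertain — three sites
exceed the 9 kgC/m² upper end usually quoted for these grasslands,
hinting at an undocumented correction factor. Users transferring SNAP to
new regions should therefore validate against locally measured stocks and
treat the packaged table as a worked example of the pipeline, not as
evidence of site-level skill.

Plot-level validation (24 plots) is implemented in the same code path —
`validate_site_level()` accepts any list of sites carrying soil %C and
bulk density — but no per-plot driver data are packaged.

## Calibration and the synthetic-data generators

To transfer SNAP to other grasslands, every sub-model can be re-fitted:
`fit_linear_submodel()` (OLS, roles for the production, water-holding,
wet-day and respiration regressions and the leaf-proportion line) and
`fit_lai_response()` (nonlinear least squares for the compensation curve,
multi-started over exponent rates {1, 3, 5, 8} because exponential-rate
fits are start-sensitive, keeping the converged fit with the lowest
residual sum of squares). Re-fitted coefficients are installed with
`update_coefficients()` and flow through the whole model unchanged.

`generate_synthetic_sites()` draws drivers uniformly and independently
within the validity envelope (rain 100–1100 mm/yr, GI 0–0.95, fire 0–1,
lignin + cellulose 0.05–0.5, sand 0–100%) — deliberately wider than any
real landscape, to exercise the equations, and deliberately independent,
which real drivers are not (rainfall and soil texture covary in the
field). `generate_lai_response()` simulates the compensation curve with
Gaussian noise; the recovery tests use 36 points and noise SD 0.05,
matching the scale of a two-season paired-quadrat campaign, and 200
replicate data sets. Passing these tests shows the estimators are
consistent on data generated by their own model — it does not show that
field LAI data are that clean, nor that drivers are independent in
nature.

Problem sizes throughout the test suite (200 random sites for the
fixed-point property, 100–400 Monte Carlo draws, 200 replicate
calibration fits) were chosen so the whole suite documents the model's
behaviour in seconds while keeping every stochastic margin wide.

## Known limitations

* One stable pool; no fractions, no within-year dynamics, no
  stochastic weather — mean annual rainfall only.
* No nitrogen or temperature response, by design.
* Coefficient errors propagated as independent normals (conservative).
* The respiration access factor and the wet-day regression are the
  weakest empirical links; both clamp at domain edges.
* Site-level validation on the packaged site means shows no predictive
  skill (see above); the packaged table validates the pipeline, not the
  model's transferability.
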