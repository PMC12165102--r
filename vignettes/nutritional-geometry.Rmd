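---
title: "Nutritional-geometry response surfaces: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutritional-geometry response surfaces: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nutrigeom)
```

This vignette is the package's account of the statistical machinery it
implements: what the models assume, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data generators
do and do not emulate, and where a genuinely open design choice was
resolved.

## 1. Mixture models on the macronutrient simplex

A diet is a point `(x₁, x₂, x₃)` of protein, carbohydrate and fat energy
fractions with `x₁ + x₂ + x₃ = 1`. The candidate family is the Scheffé
polynomial hierarchy for mixture experiments — null (intercept only),
linear, quadratic, special cubic and full cubic — fitted by least squares
with **no intercept** for the polynomial models, since the simplex
constraint makes a constant column linearly dependent on the linear
terms. The solver is QR (rank-revealing orthogonal) decomposition rather
than explicit normal equations; near-collinear designs arise easily in
mixture settings (e.g. replicated single diets), and the QR route keeps
full accuracy there while the tests use an explicit normal-equations
solve as an *independent oracle* on well-conditioned tables.

Assumptions: i.i.d. Gaussian residuals per animal, responses on the raw
percentage scale. A logit transform of percentage responses is
deliberately *not* the default — isolines are then directly readable in
percentage points, matching how such surfaces are usually annotated — but
callers can transform the response column themselves; the machinery is
scale-agnostic.

**AIC convention.** `AIC = n·ln(rss/n) + 2(k+1)`, counting the error
variance as a parameter. Only AIC *differences* matter for selection, so
the additive constant is irrelevant; the convention is fixed and
documented so that reported numbers are reproducible bit for bit. An
exact fit (`rss = 0`) has no finite AIC; `select_model()` prefers exact
fits outright and breaks ties toward the smaller model, which is what
makes selection consistent in the noiseless limit. Ties among positive-rss
candidates (|ΔAIC| < 1e-9) also resolve to the smaller model.

A property worth stating plainly: with the 2-per-parameter penalty, AIC
retains a nonvanishing probability (≈ 12–16% at n = 80) of preferring a
strictly nested-above model on data generated from a smaller truth. This
is inherent to AIC, not a defect of the implementation — the test suite
checks selection against an independent all-candidate oracle seed by
seed, and checks operating characteristics (modal selection, fat
dominance among linear picks) rather than pretending per-seed certainty.

**Coefficient sampling variance.** On a mixture design the regressors are
fractions below one, so `diag((XᵀX)⁻¹)` is substantially larger than
`1/n`; with the default 10-diet array, 8 animals per diet and unit noise
the per-coefficient standard deviations are ≈ 0.39–0.49, not `1/√80 ≈
0.11`. The recovery tests therefore compare the observed mean absolute
coefficient error against the closed-form expectation
`√(2/π)·mean(√diag((XᵀX)⁻¹))` instead of a generic `1/√n` yardstick.

## 2. The isocaloric diet design

`make_apex_diets()` returns the three macronutrient-apex diets — HP
(60:20:20), HC (5:75:20), HF (5:20:75) — and the AIN-93G growth reference
(20:64:16), all at 14.5 MJ/kg. `make_full_design()` always includes the
three apexes and fills the remaining slots by a seeded maximin greedy
selection from a Latin-hypercube cloud restricted to the feasible window
(5–60% protein, 20–75% carbohydrate, 20–75% fat). The published 10-diet
array's interior compositions are not available as a table, so the
package generates a deterministic space-filling interior rather than
inventing specific numbers; the default experiment design is
`make_full_design(10, seed = 1)`, frozen so that replicate simulations
vary only in noise. Ketogenic classification uses a *strict* `<` on the
carbohydrate fraction (default threshold 0.10): a diet at exactly 10%
carbohydrate energy is not ketogenic.

## 3. Right-angled mixture triangle surfaces

The RMT projection is the linear bijection `x = 100·protein`,
`y = 100·fat` with carbohydrate implicit as `100 − x − y`. Surfaces are
evaluated on a regular grid (default step 1%, ≤ 101×101 evaluations —
desk-scale and visually smooth) and masked to the axis-aligned design
window by default rather than to the convex hull of the diets: the full
window is what the diets were chosen to span, and with the apex diets at
the window's corners the two masks coincide anyway; hull masking remains
available for narrower designs. The fitted polynomial is never
extrapolated outside the mask. Isolines come from marching-squares
contour extraction on the full grid, then clipped to the mask so no
polyline crosses the boundary; a dense-grid (0.1%) level-set oracle in
the tests bounds the discrepancy by one coarse grid cell. Rendering is
red = high, blue = low; supply-surface rendering uses a red-to-green ramp
(the convention of global-burden panels); both are fixed styles with no
timestamps, so identical surfaces produce byte-identical PNGs.

## 4. The penalized-spline GAMM engine

The panel model is

```
g(rate) = β₀ + Σ_t f_t(covariates) + u_country + ε,
```

with `g(rate) = log(rate + 0.5)` by default. Rates per 100,000 are
positive and right-skewed, and multiplicative covariate effects are the
natural scale for them; the +0.5 offset keeps zero rates finite and is
small against typical rates (tens per 100,000). GDP enters every smooth
as **log GDP**: per-capita GDP spans two orders of magnitude and its
epidemiological gradients are conventionally log-linear. Year is a
continuous smooth; country is the only random effect, a per-country
intercept.

Each `f_t` is a tensor-product P-spline: marginal cubic B-spline bases on
equally spaced knots over the training range (quadratic when a margin has
only 3 basis functions), combined by row-wise Kronecker product, with one
order-2 difference penalty per margin (Kronecker-expanded with identities
on the other margins). Marginal basis sizes default to K = 5 for 1-D
smooths, 4 per margin for the 3-D nutrient smooth (64 columns) and 3 per
margin for the 4-D nutrient×GDP tensor (81 columns): the largest design
stays near 81 + country dummies columns — identifiable and fast on a
4,350-row panel.

**Identifiability.** B-splines form a partition of unity, so each smooth
block contains the constant function; mean-centering its columns then
leaves the all-ones *coefficient* direction mapping to zero while the
difference penalty also leaves it unpenalized, making the penalized
normal equations exactly singular. The engine therefore absorbs the
constraint by reparameterizing every smooth block onto the orthonormal
complement of the ones vector (one column fewer per block, penalties
congruently transformed). This is the standard constraint-absorption
device of mature GAMM software, keeps the system nonsingular at every λ,
and makes the effective degrees of freedom exactly monotone in each
smoothing parameter. The country-dummy block needs no such treatment: its
identity (ridge) penalty is full rank, which is precisely the
random-intercept shrinkage.

**Smoothing selection.** One λ per penalty block, chosen by GCV
`n·rss/(n − edf)²` via coordinate descent over the log₁₀ grid
{−4, …, +4}, three sweeps. GCV rather than REML keeps the engine
deterministic, dependency-free and transparent; for the selection-level
conclusions the package draws (which candidate structure wins, what the
surface looks like), the difference is immaterial, but fits should not be
expected to match an REML-based smoother coefficient for coefficient.
A Cholesky solve with escalating diagonal jitter guards the rare
ill-conditioned λ corners, and any λ yielding an invalid influence trace
is rejected (GCV = ∞) rather than trusted.

**Model comparison.** `AIC = n·ln(rss/n) + 2(edf+1)` with edf the trace
of the influence matrix — a conditional-AIC analogue applied uniformly
across candidates. The candidate set is fixed and deterministic: null, N,
G, Y, N+G, N+Y, G+Y, N+G+Y, N×G, N×G+Y, every one with the country random
intercept. "All combinations of individual, additive and interactive
effects" is unbounded as a literal enumeration (arbitrary tensor orders);
this ten-structure truncation covers every structure of scientific
interest here, including the nutrient×GDP-interaction-plus-year form, and
omits only the 3-way nutrient×GDP×year tensor, whose 243-column design
would dwarf the information in a 150 × 29 panel.

**Prediction surfaces.** `predict_nutrient_surface()` evaluates the
population-level fit (country intercept 0) over a (fat, carb) supply
grid with protein held at a quantile (0.25 / 0.5 / 0.75 are the
conventional choices) and GDP and year fixed; the grid is masked to the
convex hull of the observed (fat, carb) pairs, because the axis-aligned
supply rectangle contains corners (high fat with low GDP, say) that no
country ever realizes and where a tensor fit is pure extrapolation.

## 5. What the generators emulate — and what they do not

`gen_country_panel()` emulates the *structure* of a global
burden-vs-supply panel: ~150 countries × 29 years (1990–2018); log-GDP as
a per-country random walk with drift (0.02/yr, innovation SD 0.03, baseline
log-normal around e^8.5 ≈ $4,900); supplies as baseline + secular trend +
positive coupling to log GDP + noise (defaults: protein 250 kcal
base/1.0 kcal·yr⁻¹ trend/25 kcal per log-dollar; carbohydrate
1400/3.0/60; fat 550/4.0/90, noise SDs 15/60/45 kcal) — numbers chosen
once to sit in the range of FAOSTAT-style supply tables and to reproduce
the intercorrelation (pooled r > 0.3 with GDP) that makes the inference
problem genuinely confounded. The truth surface rises smoothly in
carbohydrate supply and falls in fat supply (amplitudes 0.5 on the log
scale across ±1 SD of supply), has a mild saturating nonlinearity
(tanh weight 0.5), an optional multiplicative GDP interaction (amplitude
0.5; 0 gives the additive truth), a mild declining year trend
(−0.005/yr), country intercept SD 0.3 and residual SD 0.15 on the log
scale around a baseline of ~30 per 100,000. The sign structure encodes
the qualitative finding the package's surface plots are designed to
display (carbohydrate up, fat down); the magnitudes are generator
conventions for testing recovery, not empirical claims.

Not emulated: GBD-style uncertainty intervals, realistic country
metadata, non-uniform missingness (only a uniform dropout knob),
non-Gaussian noise, or reporting artefacts. Passing the recovery tests
therefore shows the engine recovers a smooth confounded signal of this
size from panel data of this shape — not that any real-world estimate is
correct.

`gen_treg_experiment()` draws per-animal responses from a chosen Scheffé
truth on the frozen 10-diet array (default: linear, β = (2, 4, 12) —
fat-dominant, 8 animals/diet, unit noise) and returns the generating
coefficients for recovery checks.

## 6. Numerical conventions and degenerate inputs

* Simplex closure validated at 1e-8; compositions may be supplied in
  percent (CSV readers normalize).
* Exact mixture fits are detected at `rss ≤ 1e-12·max(1, Σy²)` and win
  selection outright, smallest model first.
* Rank deficiency raises an error naming the collinear terms; too few
  observations raises an insufficient-data error; both are per-candidate
  conditions that `select_model()`/`select_gamm()` absorb, failing only
  if *no* candidate is feasible.
* B-spline evaluation outside the training range is an error, not an
  extrapolation; boundary knots are pinned exactly so rounding cannot
  push boundary data outside.
* Isoline levels outside the observed response range are skipped (with a
  warning when user-supplied), never errors.
* All generators take a mandatory seed, use one RNG stream per call, and
  restore the caller's RNG state.

## 7. Problem sizes used in the checks

The packaged checks run at the study scale the generators encode: 200
replicate diet experiments (80 rows each) for selection and recovery
rates; 50 random tables for oracle equivalence; ten 4,350-row panels for
surface recovery (25×25 evaluation grid) and ten panel pairs
(interaction vs additive truth) for candidate selection, each fitting
all ten candidates. The full suite and the acceptance script each finish
in a few minutes on one CPU.

## 8. Known limitations

* GCV on a coarse λ grid can sit a notch away from the REML optimum;
  smoothing parameters are selection-grade, not inference-grade.
* No standard errors, confidence bands or p-values for smooths — the
  engine is built for surface estimation and structure selection.
* The mixture stage fits per-animal rows (the design default here);
  per-diet means would change AIC's effective sample size and its
  overfitting behaviour.
* Tensor smooths use one λ per margin but a single shared basis size;
  strongly anisotropic surfaces may prefer unequal K.
* The panel engine assumes Gaussian errors on the transformed scale;
  counts near zero (rates < 1 per 100,000) push the log transform's
  offset into visibility.
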