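---
title: "Methods: heat accumulation, warming velocity, and vulnerability tiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat accumulation, warming velocity, and vulnerability tiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermalscape)
library(dplyr)
```

`thermalscape` quantifies how vulnerable mountain lake landscapes are to a
warming climate, using nothing more granular than monthly mean air
temperature. The pipeline has four stages: annual heat accumulation
(growing and killing degree days) per watershed, a per-watershed *velocity
of change* from random-slope mixed models, a three-tier
cold/transitional/hot classification by one-dimensional k-means, and a
projection of tier membership onto future period climatologies with a
linear discriminant. A synthetic landscape generator with known warming
trends makes the whole chain testable end to end.

## Heat accumulation from monthly means

Degree days accumulate daily temperature excess above a threshold $T_0$:

$$\mathrm{DD} = \sum_{t=1}^{N} (T_t - T_0), \qquad T_t > T_0 .$$

Monthly climate archives do not resolve days, so the sum is evaluated with
a *monthly expansion*: every day of a month is assigned that month's mean
temperature. A month at mean $T_m$ with $d_m$ days therefore contributes
$d_m \max(0, T_m - T_0)$ degree days, and an annual value is the sum over
the twelve months. Negative accumulations are truncated to zero month by
month (no heat is accrued above the threshold), never applied to the
annual sum; zero-GDD and zero-KDD years are retained as observations.

Two thresholds are used:

* **GDD** uses a base of 0 °C, the most parsimonious base for growth of
  cold-water taxa. Configurable via `gdd_base_c`.
* **KDD** uses a region-specific supraoptimal threshold: the 90th
  percentile of all pooled (watershed, year, month) monthly means of the
  region over the historical window. The pool is unweighted monthly means;
  because the day expansion replicates a month's mean over its days, a
  day-expanded pool would give identical thresholds. The quantile uses the
  linear order-statistic interpolation convention with position
  $h = (n-1)q + 1$ (R's type 7); thresholds are sensitive to the
  convention, so it is fixed and documented. `kdd_quantile` is
  configurable.

Historical years use the Gregorian calendar with leap days. Period
climatologies have no specific year, so their annual sums use fixed
365-day (non-leap) month lengths. Incomplete years are rejected with a
warning rather than imputed, mirroring the usual exclusion of partially
observed edge years in climate archives.

## Velocity of change

For each region, annual heat accumulation is modelled with a linear mixed
model fitted by REML:

$$y_{it} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t + \varepsilon_{it},
\qquad (b_{0i}, b_{1i}) \sim \mathcal N(0, \Sigma),$$

with year $t$ as the fixed effect and watershed $i$ as a random effect on
both intercept and slope, $\Sigma$ unstructured (the intercept–slope
correlation is estimated, not pinned at zero). The response is
$\ln(\mathrm{GDD} + 1)$ by default; $\log_{10}(\mathrm{GDD}+1)$ and
$\ln(T + 10)$ (for the parallel annual-mean-temperature analysis) are
options. The log base rescales every slope by a constant and leaves
correlations and the ANOVA F invariant, which the test suite asserts.

Each watershed's **velocity of change** is its total slope
$\beta_1 + b_{1i}$, the fixed trend plus the BLUP deviation. Deviations
alone are mean-zero by construction and would hide the landscape-wide
trend; they remain available via `mode = "deviation"` for users who want
the relative ranking only. Year is centred at its sample mean internally
for numerical stability; slopes are per calendar year regardless.

The model is fitted with `lme4::lmer`. Boundary (singular) fits — zero
variance estimates — are flagged, not rejected: degenerate inputs such as
identical watersheds legitimately drive $\mathrm{Var}(b_1)$ to zero, and
the degenerate-limit tests rely on that behaviour. The test suite checks
the fits against an independent direct numerical maximisation of the
profiled REML objective.

In place of random-effect p-values the package reports marginal and
conditional pseudo-$R^2$: variance of the fixed-effect predictions, and
fixed plus random-effect variance, each over the total including residual
variance. The random-slope contribution uses the design-adjusted
(mean-covariate) form $\sigma_{00} + 2\sigma_{01}\bar t + \sigma_{11}
\overline{t^2}$ over the observed centred year covariate. Differences
among regions are tested with fixed-effects one-way ANOVA on the
velocities, and the velocity–elevation association with a Pearson
correlation and its two-sided t-test.

## Vulnerability tiers

Each watershed's classification feature is its mean annual historical GDD,
$\ln(x+1)$ transformed. Within each region the features are clustered by
k-means constrained a priori to three clusters, labelled cold,
transitional and hot by ascending centre — labels are therefore invariant
to initialisation or method.

One-dimensional k-means admits an exact solution: optimal clusters are
contiguous in sorted order, so dynamic programming over contiguous
partitions finds the global within-cluster sum-of-squares optimum in
$O(kn^2)$ with prefix sums. That exact method is the default. The
classical alternative, Lloyd's algorithm with multiple restarts, is kept
as `method = "lloyd"` (quantile-based and k-means++ starts, best of 25 by
within-SS); in experiments it reaches the same optimum on almost all
inputs but retains an irreducible ~0.1% chance per instance of lodging in
a local optimum on skewed data — e.g. when the optimal partition isolates
a single extreme value — which is exactly the situation a deterministic
exact method removes. The tests compare the default method against an
independent brute-force enumeration of all contiguous three-partitions.

Clustering deliberately uses mean GDD rather than velocity slopes:
projected climatologies carry no interannual variance, so slope-based
clusters could not be projected consistently, and mean GDD and slope are
nearly collinear anyway.

## Projecting membership

A linear discriminant on the single standardised feature is fitted per
region to the k-means labels: class means, pooled within-class variance,
empirical priors. The feature scaler (mean and SD of the ln-transformed
historical GDD) is stored with the model, and projected GDD is mapped
through **the historical scaler** — re-standardising within each future
period would erase the warming signal, which is the quantity of interest.
Posteriors are normalised class likelihood times prior; the assigned tier
is the argmax. With ordered class means on one feature the decision
regions are intervals, so predicted tier is monotone non-decreasing in
projected GDD (asserted on a grid in the tests). Accuracy is reported as
resubstitution (training) accuracy; with one feature and well-separated
tiers it is typically near 1 and should be read as a consistency check on
the wiring, not an out-of-sample error rate.

Historic membership rows are the k-means assignments themselves (reported
with a one-hot posterior, since they are deterministic cluster
memberships, not predictions); future rows come from the discriminant.
Membership tables report, per region and pooled over all regions
(count-weighted, not a mean of region percentages), the share of
watersheds per tier per period and the percent change of each share
against the historic baseline. Percent changes are computed on unrounded
shares; rounding is display-only, because bold-style percent-change
entries recomputed from rounded percentages are not reproducible.

## The synthetic landscape generator

The generator emulates the statistical structure the analysis assumes,
with hidden truth for recovery tests. Monthly mean temperature at
watershed $w$, year $y$, month $m$ is

$$T = T_0 - \Gamma e_w + A \cos\!\big(2\pi (m - m_{\mathrm{peak}})/12\big)
  + s_w (y - y_1) + \varepsilon, \qquad
  s_w = a + c\, e_w,$$

with elevation $e_w$ in km and iid Gaussian noise. Defaults, chosen once
as a realistic warm-temperate mountain landscape and then left alone:
14 °C baseline at sea level; 5 °C/km surface lapse rate (valley/surface
lapse rates are commonly shallower than the 6.5 °C/km free-air value);
seasonal half-amplitude 8 °C peaking in July; warming $a = 0.035$ °C/yr at
sea level with elevation coupling $c = -0.009$ °C/(yr·km), so every
elevation warms (0.004–0.031 °C/yr over 500–3500 m) and low elevations
warm fastest — the sign structure the velocity analysis is designed to
detect; monthly noise SD 0.5 °C; historical window 1980–2019. Two
structural considerations shaped the trend defaults: every true slope
should be positive (a warming landscape), and the velocity–truth
correlation should be strong *by construction* — because the
$\ln(\mathrm{GDD}+1)$ transform divides the trend by the local heat
level, a landscape that is too cold or too steep relative to its warming
contrast destroys that correlation structurally, not statistically.

Projected climatologies are generated noise-free — one value per
watershed, period and month — matching the fact that real projected
climatologies carry no interannual variance. The structural mean is
evaluated at the midpoint of the historical window, and each period label
adds a configurable warming offset (defaults +1.0, +2.2 and +3.5 °C for
the three standard periods, a business-as-usual-like staircase). Period
labels carry no years of their own, so the offsets are the projection; a
user wanting trend-consistent offsets can compute them from the trend
parameters.

The generator does *not* emulate: spatial autocorrelation among
watersheds, topographic effects beyond the linear lapse, snow/ice
feedbacks, non-Gaussian or autocorrelated weather noise, or realistic
emission-scenario forcing curves. Passing recovery tests therefore shows
the estimators are wired correctly and identify the generating structure;
it does not certify performance on real archives, where residual
dependence would widen uncertainty.

## Numerical choices and degenerate inputs

* Quantile convention: R type 7 ($h = (n-1)q + 1$), fixed because KDD
  thresholds are sensitive to it.
* Calendars: Gregorian (leap) for historical years; fixed 365-day months
  for climatologies.
* Incomplete years/periods: rejected (warning for historical tables, error
  for climatologies), never imputed.
* Boundary REML fits: flagged via `singular`, returned with estimates;
  convergence is reported honestly in `converged`.
* k-means centre ties (possible only on degenerate data): lower tier goes
  to the cluster containing the smaller data index; the fit is flagged.
* A tier with fewer than two members makes the discriminant unfittable;
  the error names the offending tier rather than silently merging.
* Zero-variance features, empty regions, unknown period labels and
  missing thresholds raise classed errors (`thermalscape_*_error`).

## Problem sizes

The shipped demo configuration is 2 regions × 50 watersheds × 40 years
× 3 projection periods, which exercises every stage in a few seconds. The
test suite works at that scale and below: mixed-model oracles on balanced
panels up to 150 × 30, clustering oracles on 200 instances of n ≤ 12
(where exhaustive enumeration is exact), and the full pipeline twice for
byte-identical reproducibility. These sizes were chosen so the whole suite
gives sharp answers quickly; every operation scales to archive-sized
inputs (tens of thousands of watersheds) with the same code paths, the
k-means step via its $O(kn^2)$ exact solver or Lloyd's for very large
regions.

## Known limitations

* Air temperature is a proxy; lake surface or at-depth water temperature
  can decouple from it, so interpretations should stay at landscape scale.
* The monthly expansion flattens within-month variability, biasing both
  GDD and KDD low relative to daily data near their thresholds.
* Velocities are linear trends; accelerating warming would be aliased
  into the slope.
* Resubstitution accuracy overstates out-of-sample accuracy; a
  cross-validated option can be built from `resubstitution_accuracy`'s
  evaluation-set arguments.
* The three-cluster constraint is by design (cold/transitional/hot); the
  package deliberately offers no $k$ selection.
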