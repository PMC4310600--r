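---
title: "Design-based estimation of seedling versus mature-tree range shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design-based estimation of seedling versus mature-tree range shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A warming climate should push tree recruitment towards formerly colder
ground. Because trees are long-lived and sessile, the displacement shows up
first as a mismatch between where seedlings establish today and where mature
trees — the imprint of recruitment decades ago — stand. `rangeshift`
estimates that mismatch from a single measurement of a plot-based
probability sample, the design used by national forest inventories: for
each species it compares the seedling-occupied and mature-tree-occupied
plots with respect to mean annual temperature, elevation and latitude.

Temperature is the headline attribute. Elevation and latitude are
surrogates that are mutually confounded (terrain height falls with
latitude across most mountain systems), and the package's scenario
machinery exists in part to demonstrate how opposed elevational and
latitudinal shifts can coexist with no thermal signal at all.

## Data model and cohorts

Plots carry a stratum label, a design weight (km² represented, e.g. one
plot per 24 km² in a California–Oregon stratum and one per 26.6 km² in a
Washington stratum), coordinates, elevation and climate attributes.
Tallies are stems or seedling counts on nested fixed-area subplots: stems
≥ 12.7 cm on 672.5 m², stems of 2.54–12.7 cm on 54 m², seedlings (stems
< 2.54 cm above a minimum established length) counted on the 54 m²
footprint. A stem's expansion weight is plot weight × count / subplot
area, so small-subplot stems represent proportionally more stems per unit
area.

Age is not measured, so size separates the cohorts. The mature cohort of a
species comprises plots holding a stem at least as large as the
`percentile`-th quantile (default the 75th) of the species' expansion-
weighted diameter distribution over forested plots; stems between 2.54 cm
and the cutoff belong to neither cohort. This guarantees temporal
separation: mature trees recruited well before today's seedlings. Species
are analyzed only when they occupy at least 25 plots in each cohort (100
for the range-extreme analysis, which needs far more data in the tails).

Two cohort conventions are deliberate package choices:

* **Quantile convention.** All quantiles — diameter cutoffs and range
  extremes alike — use the left-continuous inverse of the weighted
  empirical CDF (the smallest observed value whose cumulative weight
  reaches *p*). It is deterministic, exactly reproducible, and with equal
  weights reduces to the classical type-1 sample quantile.
* **Expansion weighting of the cutoff.** The diameter distribution is
  estimated from all measured stems of both subplot classes, each with its
  design-consistent expansion weight. This is the standard design-based
  choice; the sensitivity stage (below) shows results barely move when the
  cutoff percentile itself is varied, which bounds the influence of any
  reasonable alternative weighting.

Seedling minimum-length rules (15.2 cm conifer / 30.5 cm hardwood) are
treated as upstream tally semantics: lengths are not in the schema, so any
record flagged as a seedling is assumed to have passed them.

## Estimators

For domain *d* (one species' cohort) with indicator *z* over forested
plots, weight *w* and attribute *y*, the domain mean is the ratio estimator

$$\hat R_d = \frac{\sum_i w_i z_{di} y_i}{\sum_i w_i z_{di}}.$$

The seedling-minus-tree difference $\hat\Delta = \hat R_s - \hat R_t$ is
linearized through per-plot influence values

$$u_i = w_i\left[\frac{z_{si}(y_i - \hat R_s)}{\hat N_s}
              - \frac{z_{ti}(y_i - \hat R_t)}{\hat N_t}\right],
  \qquad \hat N_d = \sum_i w_i z_{di},$$

with variance $\frac{n}{n-1}\sum_i u_i^2$ over the *n* plots of the
analysis universe (forested plots with a non-missing attribute value;
$\sum_i u_i = 0$ identically, so this is the usual centered form). 95%
intervals use the fixed normal quantile 1.959964. Both indicators live on
the same plots, so the covariance between the two cohort means — a plot
can and often does host both cohorts — is carried entirely by $u_i$; no
independence assumption is made anywhere.

Two variance conventions deserve note:

* The spatially balanced design is treated as with-replacement sampling
  within the pooled forested sample. This is the standard conservative
  approximation when exact joint inclusion densities are unavailable; the
  package validates it by simulation (the linearized standard error tracks
  both the Monte-Carlo sd and a stratified bootstrap within a few percent
  at n = 500, and 95% intervals cover at ~0.95 in the recovery study).
  A stratified-sum variance (per-stratum centering) is available behind
  `stratified_var = TRUE`, default off.
* Ratio estimators make every result invariant to rescaling all weights by
  a constant, which the tests assert explicitly.

Range extremes (5th/95th percentiles of each cohort's attribute
distribution) use the same weighted quantile convention, with
percentile-method bootstrap intervals: whole plots are resampled with
replacement within stratum, both memberships attached, and both quantiles
recomputed per resample — preserving the seedling/tree dependence. The
default is 2000 resamples, seeded and reproducible.

## Combining species

Per-species differences share the plot sample and are therefore
correlated. Their joint covariance is rebuilt from the stored influence
vectors, $\hat\Sigma_{jk} = \frac{n}{n-1}\sum_i u_i^{(j)} u_i^{(k)}$,
whose diagonal equals each species' linearized variance by construction.
The overall (or taxonomic-group) mean difference is the GLS mean

$$\hat\mu = \frac{\mathbf{1}^\top\hat\Sigma^{-1}\mathbf{d}}
                 {\mathbf{1}^\top\hat\Sigma^{-1}\mathbf{1}},
  \qquad \mathrm{se}(\hat\mu) = (\mathbf{1}^\top\hat\Sigma^{-1}\mathbf{1})^{-1/2},$$

solved by Cholesky factorization, never an explicit inverse. With many
species estimated from the same plots $\hat\Sigma$ can be near-singular,
so it is shrunk toward its diagonal, $(1-\lambda)\hat\Sigma +
\lambda\,\mathrm{diag}(\hat\Sigma)$, taking the smallest $\lambda$ on a
0.05 grid that brings the condition number below 10⁸; the $\lambda$ used
is reported in every output row. With a diagonal covariance the GLS mean
reduces to the classical fixed-effect inverse-variance mean, and only in
that diagonal case is the combined se guaranteed not to exceed the
smallest per-species se — correlation can legitimately violate it.

An alternative joint-bootstrap covariance
(`bootstrap_cross_species_covariance()`) exists for sensitivity checks;
linearization is the default because it is deterministic and exact at the
first order. For the across-species summary of the percentile shifts only
a diagonal (bootstrap-variance) weighting is used, since quantile
estimators carry no influence vectors; that summary is labeled `"ALL"` in
the percentile table and should be read as an inverse-variance average,
not a full GLS mean.

The quadrant summary classifies each species by the signs of its latitude
and elevation differences and by which of the two exclude 0 at the 0.05
level. Significance is per-species with no multiple-testing correction —
a reporting convention, stated here prominently. A difference of exactly
zero counts as positive; on continuous data this is a measure-zero
tie-break.

## The synthetic generator

Real inventory coordinates are confidential, so the package ships a
generator that emulates the design well enough to give every estimator a
known truth:

* stratified-grid-jittered plot locations in two strata (fractions
  0.78/0.22 of area; densities 24 and 26.6 km² per plot) — a quasi-uniform
  stand-in for a spatially balanced draw, sufficient because the
  estimators exploit no spatial structure;
* an elevation field of seeded sinusoidal ridges plus noise, optionally
  tilted in latitude;
* temperature following the exact linear model
  `mat = t0 − lat_gradient·(lat − lat_min) − lapse_rate·elev/1000`
  (defaults 17 °C, 0.8 °C/degree, 6.5 °C/km), assertable per plot;
* Gaussian occupancy niches per species (default width σ = 2 °C, peak
  occupancy 0.4, centers spread over 4–12 °C, well interior to the
  landscape's temperature range so kernel tails are not clipped);
* lognormal stem diameters (positive, right-skewed, two parameters, easy
  to place 75th percentiles across a realistic 8–28 cm span), with stems
  under 12.7 cm retained with probability 54/672.5 — the nested-subplot
  thinning that the cutoff estimator's expansion weighting undoes exactly;
* a planted seedling shift δ (default 0.12 °C towards colder).

**Calibration of the planted shift.** On a bounded landscape, shifting a
Gaussian kernel's center by δ moves the population mean by slightly less
than δ (the kernel tails feel the edges of the temperature density; the
attenuation is ~10% under the defaults). Since δ is meant to *be* the
ground truth the estimators are judged against, the generator solves per
species for the seedling center whose population-level mean difference
equals exactly −δ (`calibrate = TRUE`, the default), and records the
center actually used in the truth table. The truth table's population
means are computed by integrating the exact occupancy probabilities over
the generated plot population, so estimator bias and interval coverage can
be measured against an exact target.

Scenario perturbations stress the interpretation rather than the
estimator: `edge_contraction` thins seedlings only on the warm side of the
niche (abundance shifts cold without the footprint moving);
`pathogen_patch` multiplies occupancy inside a seeded circular patch, with
separate tree/seedling factors; `elevational_confound` moves the niche to
the elevation axis over terrain (`confound_landscape()`) that falls
northward at exactly `1000·lat_gradient/lapse_rate` m per degree — the
slope along which climbing and moving south are thermally equivalent.
Under that construction an upward seedling displacement (default 90 m)
drags mean latitude south by roughly `delta_m/|lat_trend|` degrees while
leaving mean temperature flat. One geometric constraint matters: the
occupancy kernel projected on latitude has width
`sqrt(sigma_m² + relief²)/|lat_trend|` degrees and must sit well inside
the latitude range, otherwise boundary truncation attenuates the
latitudinal response and re-opens a spurious thermal signal; the defaults
(σ = 150 m, relief ≈ 140 m, centers within the middle half of the range)
respect this.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real inventories: seedling and tree occupancy are
drawn independently given temperature (no dispersal limitation, stand
dynamics or disturbance history); topography is synthetic, not a DEM;
there is no measurement error in diameters or climate attribution; plots
are points, not 4-point clusters, so within-cluster correlation is absent;
and the spatial balance of a true systematic-hexagon draw is only
approximated, which makes the with-replacement variance, if anything,
conservative.

## Validation design and problem sizes

The test suite validates each layer against an independent route: hand
instances of at most 8 plots against brute-force ratio, influence,
quantile-scan and explicit-inverse GLS computations (at 10⁻¹⁰); a
delete-one jackknife against the linearized variance; and the generator's
exact truth against the full pipeline. The simulation studies use sizes
chosen to balance resolution against run time: 200 replicates of 12,000
plots × 40 species for recovery and coverage of the combined estimator,
200 replicates at 500 plots (plus one 2000-resample bootstrap) for
variance calibration, 30 × 40 species-replicates at 4,000 plots for the
null type-I error, 15 replicates of the confound scenario, and one
12,000-plot dataset for the cohort-percentile sensitivity comparison at
the 60th/75th/85th percentiles.

## Known limitations

* The with-replacement variance ignores the efficiency gain of spatial
  balance; intervals are slightly conservative in principle, though
  simulation shows near-nominal coverage at these sizes.
* Finite-population corrections, model-assisted estimators and explicit
  spatial autocorrelation are out of scope.
* The percentile-shift summary across species uses diagonal weighting
  (see above), unlike the mean-shift combination.
* Cohort membership is binary presence; abundance within a plot is used
  only through the diameter distribution, not in the domain indicators.
* With very small domains the normal intervals on per-species differences
  are approximate; the plot-count filters (25/100) are the guard rails.
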