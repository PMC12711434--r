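---
title: "Methods: resource dispersion analysis for free-ranging dog populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource dispersion analysis for free-ranging dog populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdhtools)
```

## The scientific problem

The Resource Dispersion Hypothesis (RDH) proposes that in species exploiting
patchy resources, the **size of a territory** is set by the spatial
dispersion of the resource patches a group must encompass, while the **size
of the group** is set by the richness of those patches — so the two traits
can be decoupled. Free-ranging dogs, which scavenge almost exclusively from
anthropogenic food sources (shops, eateries, garbage points, direct
provisioning), are an unusually tractable system for testing this: their
resource landscape can be mapped exhaustively on foot, scored for quality,
and related to censused dog densities and to the territories of known social
groups followed across reproductive seasons.

`rdhtools` implements the two analysis tracks of such a study:

* a **census track**: survey polygons stratified as rural or urban, each
  yielding a dog density (dogs ha⁻¹) and an area-standardized resource score
  density, analysed by rank contrasts and a Gamma log-link GLM with a
  resource × settlement interaction;
* a **territory track**: group × season records with territory polygons,
  mapped resource points, and group composition, summarized by three spatial
  statistics (patch richness, resource heterogeneity, resource dispersion)
  and analysed with Gamma GLMs, Gamma mixed models with a group random
  intercept, a season-specific dispersion submodel, and a log-distance
  linear model.

Because the field data are an external deposit, the package also ships a
synthetic landscape generator that reproduces the statistical structure the
analyses assume; every stage of the pipeline is validated against it.

## Geometry

All analysis happens in a local planar frame in metres. Geographic
coordinates are planarized once per study site around its centroid
(`local_projection()`): northings use the ellipsoidal meridional radius of
curvature at the origin and eastings the prime-vertical radius scaled by
each point's own latitude, carrying meridian convergence exactly. Over the
≤ 50 km extents of these study regions, planar distances agree with WGS84
geodesics to better than 0.1% (the test suite checks this against
`geosphere::distGeo`), and the projection inverts exactly.

Polygon areas are shoelace areas divided by 10,000 (hectares), invariant to
vertex-ring rotation and orientation. Territory polygons are built as the
**convex hull** of recorded marking/defence points: field protocols only say
boundary points were "connected", and the hull is the unique deterministic,
order-free choice consistent with the downstream use of area alone. If the
authors traced ordered (possibly concave) boundary walks instead, hull areas
are upper bounds; this is a known, unresolvable ambiguity and the
`territory_record()` constructor therefore also accepts an explicit polygon.

## Resource scoring and census densities

Each food source carries one of eight categories with an ordinal score
(meat/fish shop 8 … uncovered household dustbin 1; see
`resource_categories()`). A point carries exactly one category — the scheme
is a partition, and mixed sources must be entered as the single
best-fitting category. Resource density of a survey polygon is the summed
score divided by area (score ha⁻¹); dog density is the dog count divided by
area. Pups are counted in census densities (the census records age class but
excludes nobody); adult-count models in the territory track exclude pups.

Zero-resource polygons are legal (density 0). Zero-dog polygons, however,
violate the support of the Gamma response in the census GLM and are dropped
with a logged count; adding a small constant instead is config-exposed
(`zero_offset`) but off by default, since it changes the estimand.

## Territory metrics

For a territory with \(N\) resource points:

* **patch richness** is \(N\) (coincident points count separately — two bins
  at one corner are two patches);
* **heterogeneity** is the number of distinct categories present (0–8);
* **dispersion** is the mean over points of each point's average distance to
  the other points. With the default divisor \(N-1\) this equals the mean
  pairwise inter-point distance \( \frac{2}{N(N-1)} \sum_{i<j} d_{ij} \).
  The field description of the statistic does not pin down whether the
  divisor includes the point itself; the \(N\) convention (which shrinks
  every per-point average by \((N-1)/N\)) is available via
  `resource_dispersion(divisor = "n")`. \(N-1\) is the default because it
  makes the two-point case return the actual separation. Units are metres;
  the ~0.02-per-unit coefficient scale of the territory-size model is
  consistent with metre-scaled dispersions of tens of metres.

Dispersion is undefined below two points and the male:female ratio is
undefined in a group with no females; both yield `NA`, and model fitters
drop incomplete rows listwise, reporting the count. How all-male groups were
handled in the original analysis is unstated; exclusion is the only choice
that leaves the ratio interpretable.

## Census models

Dog density is modelled as Gamma with a log link,
\( \mu = \exp(\beta_0 + \beta_1 r + \beta_2 u + \beta_3 r u) \), where
\(r\) is resource density and \(u\) the urban indicator (reference: rural).
Rate ratios are \(e^{\beta}\) with 95% Wald intervals on the log scale —
these reproduce printed rate-ratio columns exactly from their estimates and
SEs. The within-urban resource slope is \(\beta_1+\beta_3\) with SE
\(\sqrt{v_{11}+v_{33}+2v_{13}}\) (`combined_slope()`).

Rank contrasts use the two-sided Mann–Whitney test, exact when the smaller
sample has ≤ 8 values and no ties, otherwise the normal approximation with
tie-corrected variance and 0.5 continuity correction. Both statistic
conventions (`U` and the first-sample rank sum `W`) are reported.

The sensitivity analysis is the noncentral-t power of the two-sided
two-sample t test: df \(= n_1+n_2-2\), noncentrality
\(d/\sqrt{1/n_1+1/n_2}\). At \(n_1=52\), \(n_2=41\), \(\alpha=0.05\), power
at \(d=0.6\) is 0.811; inverting to 80% power gives \(d=0.591\), which maps
under the normal-shift equivalence to a Mann–Whitney AUC of
\(\Phi(d/\sqrt2)=0.662\) and Cliff's \(\delta = 2\,\mathrm{AUC}-1 = 0.324\).
The noncentral-t (rather than normal) formulation matches the convention of
the standard power calculators.

## Territory models

Territory size (ha) and adult count are Gamma log-link GLMs on the metric
set (plus adult count for the territory model, territory size for the group
model). Likelihood-ratio tests against the intercept-only model report the
raw deviance difference — the quantity conventionally printed — but take
the p-value from the dispersion-scaled difference, which is the statistic
with an approximate \(\chi^2\) reference for a Gamma family; the raw
difference is \(\chi^2\)-distributed only when the dispersion is 1.

Seasonal models are Gamma mixed models with season as fixed effect and a
random intercept per dog group. The season factor is parameterized with
**mating as the reference level**, so the reported contrasts are
post-mating-vs-mating and pre-mating-vs-mating. Estimation maximizes the
Laplace-approximate marginal likelihood: the random intercept enters the
linear predictor additively, so each group's conditional mode is a
one-dimensional Newton problem with closed-form derivatives, vectorized over
groups; the outer problem (fixed effects, dispersion coefficients, log
random-SD) is solved with BFGS. The test suite verifies agreement of this
fitter with glmmTMB (an independent implementation of the same marginal
likelihood) to 10⁻⁶ on the log-likelihood on shared fixtures.

The heterogeneity model adds a **log-linear dispersion submodel**,
\(\log \phi = \gamma_0 + \gamma_1 \text{post} + \gamma_2 \text{pre}\),
fitted jointly with the mean model and compared with the constant-dispersion
model by a 2-df likelihood-ratio test plus AIC/BIC
(`fit_dispersion_model()`). Resource dispersion itself, whose
random-intercept variants are prone to near-singularity, falls back to an
ordinary linear model on the log scale with season as the only predictor
(`fit_logdistance_lm()`), reporting \(F(2, n-3)\) and \(R^2\).

### Singular fits

A random-effect SD estimated at — or numerically indistinguishable from —
zero is flagged singular: either the SD collapses below 10⁻⁴, or it is
below 0.1 (log scale, i.e. CV units) and removing the random term costs
less than 10⁻³ units of twice the log-likelihood. A flagged fit is refitted
as the fixed-effects model, mirroring the standard fallback. Under a true
zero variance the flag fires in roughly half of replicates: the LRT mass at
the boundary is the ½χ²₀+½χ²₁ mixture, so about half of all fits land on a
small positive variance that does carry (spurious) likelihood, and no honest
criterion can label those "zero". When the two arms of the dispersion
comparison disagree on singularity, both are refitted without the random
term so the LRT compares like with like.

Season-specific dispersion with group random intercepts has a genuine
degenerate direction: if one season's dispersion is free to shrink while
every group has only one observation in that season, the group intercepts
can pin those observations exactly and the dispersion runs to the zero
boundary. This is a property of the model (glmmTMB reproduces it on the
same data), not of the optimizer; strongly contrasting but well-identified
fixtures avoid it.

## The synthetic landscape generator

`sim_config()` fixes the study conditions; all draws flow from one
`set.seed()` call, so every output is reproducible.

* **Census**: 52 rural and 41 urban polygons; areas uniform on 1.29–161 ha
  (the surveyed range); star-shaped random polygons rescaled to the exact
  requested area. Resource intensity averages 1.2 (rural) / 2.9 (urban)
  points ha⁻¹ with settlement-specific category weights, chosen so mean
  score densities sit near the field values (≈ 4 and 10 score ha⁻¹), and a
  mean-preserving lognormal site effect (sdlog 1.0) reproducing the
  observed site-to-site coefficient of variation (≈ 1.3). Dog density is
  drawn from a Gamma with log mean
  \((-0.346) + 0.110\,r + 1.169\,u - 0.106\,ru\) — the census-model truth —
  and dispersion 0.5; the continuous density is discretized to a whole-dog
  count (round-trip error below one dog by construction) and the stored
  density recomputed as count/area so the pair is self-consistent. Sexes
  are 1:1: the census found no sex difference, and the generator embeds
  that null.
* **Territory panel**: 36 groups × 3 seasons thinned at random to an
  84-row panel (the analysed sample size). Each group has persistent
  resource parameters — a resource-cloud radius (lognormal, median 65 m)
  controlling dispersion and an expected patch count (lognormal, median
  15) controlling richness, with group-specific category-weight skew
  spreading heterogeneity — so the metric spread needed by the
  territory-size model arises between groups without collinearity (all
  pairwise |r| < 0.8 is a tested design property). Territory area is Gamma
  with log mean given by the territory-truth coefficients
  (−2.788, −0.0006, 0.102, 0.041, 0.391, 0.0206) applied to the realized
  metrics, a group intercept (SD 0.4), season effects (post-mating −0.075,
  pre-mating −0.021 — the log-ratios of the reported seasonal means) and
  residual dispersion 0.02, the scale implied by the reported seasonal
  contrast z-statistic. Adult counts are intercept-only Gamma (log mean
  1.776, the group-model truth) with binomial sexes — the generator embeds
  the finding that covariates do not predict group size.
* **Point processes**: `"poisson"` scatters uniformly; `"clustered"` is a
  Matérn-style parent–offspring process; `"regular"` is sequential
  hard-core inhibition (relaxing the core radius when jammed). All three
  share the expected count (intensity × area), and at matched intensity
  they order mean inter-point dispersion clustered < Poisson < regular —
  the gradient the dispersion metric must detect.

**What the generator does not emulate:** spatial autocorrelation between
census sites, territory overlap between neighbouring groups, within-season
resource turnover, fission–fusion group dynamics, and any real between-group
covariance structure of the metrics beyond what the group-level parameters
induce. Passing tests therefore demonstrate that the estimators recover the
assumed generating structure at the study's sample sizes — not that the
field system satisfies those assumptions.

## Calibration and problem sizes

The test suite validates, at sizes chosen to keep a full run inside a few
minutes on one CPU:

* dispersion vs a brute-force double loop up to N = 200 (10⁻⁹ relative) and
  polygon areas vs a 10⁶-sample Monte-Carlo oracle (1%);
* census-truth recovery within ±2 SE at 2,000 simulated sites; recovery of
  all four positive territory-model effect signs in ≥ 90% of 200 panels at
  n = 84;
* type-I error of the 2-df dispersion LRT within the binomial 95% band of
  5% over 1,000 null panels, and > 90% rejection under a 10-fold
  post-mating dispersion contrast (200 panels). The calibration baseline
  dispersion is 0.6: at much smaller baselines the group intercepts absorb
  most of the dispersion signal and the contrast is only weakly identified
  — the regime matching the magnitude of the reported test statistic;
* GLM coefficients vs an independent gradient-based ML optimizer (10⁻⁵
  relative, achieved at ~10⁻⁷).

## Known limitations

* The Laplace approximation is used throughout the mixed models; no
  adaptive quadrature. With ≤ 3 observations per group, small-sample bias
  in the random-effect SD is expected (and visible in the generator
  round-trips, which recover fixed effects much more precisely than
  variance components).
* The dispersion submodel's zero-boundary degeneracy (above) means its LRT
  should be read alongside the fitted dispersion contrasts, not alone.
* Convex-hull territories cannot represent concave territories; areas are
  upper bounds under concavity.
* The scoring scheme is ordinal but is summed as if interval-scaled; this
  mirrors the original design and is not revisited here.
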