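---
title: "Multilevel ecological regression across non-adjacent cities: models, inference and kriging"
author: "svcmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel ecological regression across non-adjacent cities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Small-area ecological regression studies relate an area-level health
outcome (for example, tract-level mortality counts) to an area-level
exposure (for example, an unemployment rate used as a deprivation
surrogate).  When several cities are studied at once, the common practice
is to fit each city separately, which yields unrelated and often noisy
city-specific association estimates and ignores that the same process is
being measured everywhere.  `svcmap` implements a joint multilevel
treatment: census tracts are nested within cities, tract counts follow a
Poisson disease-mapping model with BYM-type random effects, and the
city-level regression coefficients are themselves modelled — either as
independent fixed effects, as exchangeable random effects, or as a
spatially correlated Gaussian field over the cities' geographic locations.
The last variant lets estimates borrow strength across nearby cities and
supports kriging of the association onto locations with no data.

## The three model variants

For tract $i = 1, \dots, n_j$ of city $j = 1, \dots, J$, with observed
count $O_{ij}$, expected count $E_{ij}$ and covariate $X_{ij}$:

$$O_{ij} \sim \mathrm{Poisson}(E_{ij}\,\theta_{ij}), \qquad
\log \theta_{ij} = b_{1j} + b_{2j} X_{ij} + S_{ij} + H_{ij}.$$

Per city, $S_{\cdot j}$ follows an intrinsic CAR (ICAR) prior on the
tract adjacency graph with conditional standard deviation
$\sigma_{Sj}$, and $H_{ij} \sim \mathrm{N}(0, \sigma_{Hj}^2)$; every city
has its own pair of variances, so each city may show a different degree
of spatial structure.  All standard deviations carry
$\mathrm{Uniform}(0, l)$ priors.

* **M1** — $b_{1j}, b_{2j}$ flat (independent fixed effects): equivalent
  to separate BYM ecological regressions per city.
* **M2** — $b_{1j} \sim \mathrm{N}(\alpha, \sigma_{b1}^2)$,
  $b_{2j} \sim \mathrm{N}(\beta, \sigma_{b2}^2)$, conditionally
  independent given the variances: cities share information, and
  $\exp(\beta)$ is an overall pooled relative risk per 1% covariate
  increase.
* **M3** — $b_1 \sim \mathrm{MVN}(\alpha \mathbf{1}, \sigma_1^2
  e^{-\phi_1 D})$ and $b_2 \sim \mathrm{MVN}(\beta \mathbf{1}, \sigma_2^2
  e^{-\phi_2 D})$, where $D$ is the intercity distance matrix in km:
  geographically close cities have correlated coefficients.  The decay
  parameters carry $\mathrm{Uniform}(a, b)$ priors, and the *effective
  range* $R = -\ln(0.05)/\phi_2$ (the distance at which correlation drops
  to 0.05) summarises the spatial pattern in km.

The "NormalJ" structure is read as $J$ conditionally independent normals
in M2 and as one $J$-dimensional multivariate normal in M3; this is the
only reading consistent with the conditional-independence statement for
M2 and the covariance-matrix construction for M3.

### Identifiability conventions

The ICAR prior is improper (invariant to level shifts), so each graph
component of $S$ is constrained to sum to zero; its normalizing exponent
uses $n_j - c_j$ where $c_j$ counts the city's graph components.
Isolated tracts are permitted — they drop from the quadratic form and
their field value is pinned at zero — but are reported loudly, since real
census tracts within a city are contiguous.  The classic BYM aliasing
between $S$ and $H$ means their split is not an inferential target; the
package reports relative risks, variance components and the decay
summaries, not the $S$/$H$ decomposition.  The covariate is used in its
original percentage units, uncentered, so $\exp(b_{2j})$ is directly the
relative risk per 1% covariate increase.

## Priors and the decay bounds

Defaults: $l = 10$ on the log-relative-risk scale (vague for
epidemiological relative risks; configurable), flat improper priors on
$\alpha, \beta$ (a proper $\mathrm{N}(0, s_0^2)$ option exists and is used
by the sampler self-check, which needs prior draws).

The support $(a, b)$ of the decay priors deserves care.
`decayBounds(D, rhoLo, rhoHi)` derives bounds from correlation
constraints ($a = -\ln \rho_{hi} / d_{\min}$,
$b = -\ln \rho_{lo} / d_{\max}$), which keeps every pairwise correlation
away from 0 and 1 and is numerically safest.  However, with any
reasonable correlation floor this *forbids effectively independent far
cities*: the minimum representable effective range is
$\ln(0.05)/\ln(\rho_{lo}) \cdot d_{\max}$, i.e. 65% of the largest
intercity distance at $\rho_{lo} = 0.01$.  Realistic studies (and this
package's own default synthetic truth, range 400 km in a 1000 km region)
need shorter ranges.  The default used by `runMcmc` is therefore
`defaultDecayBounds(D)`: the effective range is bounded between the
closest intercity distance (below which no pair of cities informs the
decay) and 1.25 times the span of the region (above which the field is
indistinguishable from a constant).  This is the convention of mainstream
geostatistical samplers; the correlation-based bounds remain available
when wanted.

## MCMC design

The sampler is a bespoke Metropolis-within-Gibbs scheme written in C++
(the model class has no off-the-shelf exact sampler; the inferential
algorithm is standard and not itself a contribution):

* **ICAR fields** — single-site random-walk proposals that move along
  $e_i - \mathbf{1}/m$ within the site's graph component ($m$ = component
  size), so every proposal satisfies the sum-to-zero constraint exactly
  and the constrained target is preserved without any post-hoc
  re-centring adjustment.  The aggregate likelihood change uses
  component totals, so a proposal costs O(1) and an acceptance O(m).
* **Heterogeneity effects** — single-site random-walk Metropolis.
* **City coefficients** — per-city random-walk Metropolis with the
  variant's prior term (for M3, via the precomputed inverse correlation
  matrix).
* **$\alpha, \beta$ and all variances** — conjugate Gibbs:
  normal draws for the means; for a standard deviation with conditional
  $\propto \sigma^{-n} e^{-q/(2\sigma^2)}$ on $(0, l)$, an exact draw of
  the precision from the correspondingly truncated gamma distribution via
  its quantile function.  Degenerate exponents ($n \le 1$) fall back to
  an independence Metropolis step.
* **Decays** — random-walk Metropolis inside $(a, b)$ with a fresh
  Cholesky factorisation per proposal ($J \times J$, cheap).
* **Mixing moves** — three reparameterisation moves that target the
  model's known ridges: a per-city swap between $b_{1j}$ and the mean of
  its $H$ field (likelihood-invariant; breaks the BYM intercept
  aliasing), global level shifts of $(\alpha, b_1)$ and $(\beta, b_2)$
  holding the residuals fixed (the Gibbs step for $\alpha$ given $b_1$
  cannot move the overall level), and joint rescalings of each city's
  random-effect field together with its standard deviation (moves the
  spatial-vs-unstructured variance split, which single-site updates
  traverse very slowly).  Without these, intercepts and variance
  components needed runs an order of magnitude longer.

Proposal scales adapt toward 44% acceptance in batches of 50 sweeps
during burn-in only and are frozen afterwards, so retained draws come
from a fixed kernel.  A single master seed spawns per-chain streams; runs
are bit-reproducible.

Two presets are provided: `"desk"` (4 chains × 5000 iterations, burn-in
1000, thin 4 — the scale used throughout the package's tests and example
scripts) and `"paper-protocol"` (7 × 100000, burn-in 10000, thin 126),
the heavy protocol appropriate for real studies where variance components
mix slowly.  Convergence is checked per parameter with the
Brooks–Gelman–Rubin statistic and an initial-positive-sequence effective
sample size, against the conventional thresholds $\hat R < 1.1$ and
$\mathrm{ESS} > 100$.  Note the plain $\hat R$ form gives exactly
$\sqrt{(n-1)/n}$ (slightly below 1) for identical chains.

**DIC.** The deviance includes its factorial constant so models are
comparable; $\bar D$ averages the retained deviances, and the plug-in
deviance is evaluated at the posterior mean of each tract's
$\log \theta_{ij}$ (linear-predictor scale, the WinBUGS-style convention
for this model class — $p_D$ is plug-in-dependent, which is why the
convention is stated).  Differences are banded negligible (< 3), moderate
(3–7) and clear (> 7).

**Sampler validation.** Beyond per-move unit oracles, the transition
kernel as a whole is checked by a joint-distribution consistency test:
marginal prior draws of $(\alpha, \beta, \sigma_2, \phi_2)$ are compared
(Kolmogorov–Smirnov) with draws from a chain alternating MCMC
transitions and data re-simulation on a small configuration with proper
priors.  Any error in any conditional update would shift these marginals.

## Kriging the coefficient surface

Under M3 the slope field is a stationary Gaussian process with mean
$\beta$ and covariance $\sigma_2^2 e^{-\phi_2 d}$.  For *each retained
posterior draw*, the coefficient at the grid locations conditional on
that draw's city coefficients is exactly multivariate normal; one
realization is sampled per draw, so the resulting draw set integrates
over the full posterior (plug-in kriging at posterior means would
understate both the posterior SD surface and the exceedance
probabilities).  The model has no nugget — the coefficient field is not
observed with micro-scale error — so the surface interpolates the city
coefficients exactly; a grid point within $10^{-9}$ km of a city receives
the city's draw directly rather than inverting a near-singular system.
Surfaces report the posterior mean relative risk $\exp(b_2)$, its
posterior SD, and $P(\mathrm{RR} > 1)$ with a strict inequality (draws at
exactly $\mathrm{RR} = 1$ do not count as exceedances).

Joint conditional simulation (with the full grid–grid conditional
covariance, eigenvalue-clipped at zero for numerical safety) is used for
grids up to 250 points; larger grids use per-location marginal
conditionals, which leave all per-location summaries identical and scale
linearly.  The grid is a row-major rectangular lattice, optionally masked
by a polygon with an even-odd ray-casting test.

## The synthetic-data generator

`simulateLayout` places city centroids uniformly over a square region
with a minimum-separation rejection rule and gives each city a
rook-adjacency grid lattice of tracts — the ICAR prior consumes adjacency
topology only, so realistic tract geometry is deliberately not emulated.
`simulateDataset` then draws the full generative hierarchy of M3 (M1/M2
arise by switching components off).

The default truth preset emulates a national multi-city mortality study:
31 cities, 36 tracts each, a 1000 km region; $\beta = 0.025$ (overall RR
≈ 1.025 per 1% covariate increase), effective range 400 km for both
coefficient fields, tract covariate $\mathrm{U}(5, 30)$% and expected
counts $\mathrm{U}(0.5, 5)$.  The remaining scales are the package's own
choices, fixed once: $\sigma_1 = 0.15$, $\sigma_2 = 0.02$ (city relative
risks spread over roughly 0.96–1.09, informative but overlapping
credible intervals), $\sigma_{Sj} = 0.1$ and $\sigma_{Hj} = 0.05$
(tract-level spatial structure dominating unstructured noise, as typical
for smoking-related mortality).  What the generator does *not* emulate:
irregular tract geographies and populations, covariate spatial
autocorrelation within cities, registration artefacts, and overdispersion
beyond the model.  Passing recovery and coverage tests on these data
therefore validates the estimation machinery under the model's own
assumptions — it does not certify behaviour under model misspecification.

## Numerical choices

* Distances are in km throughout (Euclidean on projected-km coordinates,
  haversine on lon/lat), so decay summaries read directly in km.
* Truncated inverse-gamma draws go through `qgamma` on the precision
  scale; when the truncation point carries essentially all mass the draw
  is pinned just inside the bound.
* Conditional covariance matrices in joint kriging are symmetrised and
  eigenvalue-clipped at zero before factorisation.
* Degenerate inputs: tie handling and error contracts are exercised
  directly in the test suite (zero expected counts, duplicated tracts,
  self-loops, single-city distance matrices, empty masks, constant
  chains, M1 pooled-RR requests).
* Test and example problem sizes (desk preset; J between 3 and 31;
  replicate counts 5–20) were chosen so the full suite exercises every
  pipeline at study-like dimensions while remaining comfortable on a
  single CPU.

## Known limitations

* The exchangeable and geostatistical variants share a single covariate;
  multiple covariates per city would need a straightforward but unwritten
  extension of the state layout.
* No Matérn or spherical covariance families, no proper-CAR variant, and
  no zero-inflated or overdispersed likelihoods.
* Polygon masks use even-odd ray casting with ambiguous behaviour exactly
  on polygon edges — acceptable for masking prediction lattices, not
  meant as a general computational-geometry tool.
* Adjacency is taken as input (edge lists or GeoBUGS `num`/`adj`
  vectors); deriving it from shapefiles is out of scope, and no
  contiguity rule (queen/rook) is guessed on the user's behalf.
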