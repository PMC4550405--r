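# svcmap

Joint Bayesian ecological regression for small areas nested in
**non-adjacent cities**, with spatially varying city coefficients and
kriging of the relative-risk surface.

## Who this is for

Epidemiologists and biostatisticians running multi-city small-area
studies — e.g. census-tract mortality counts against a deprivation
indicator across the large cities of a country.  The common practice of
fitting each city separately yields noisy, unrelated estimates.  `svcmap`
fits all cities jointly, letting them share information and, when the
association has spatial structure, predicting it at locations with no
data at all.

## The models

For tract *i* of city *j*: `O_ij ~ Poisson(E_ij * theta_ij)` with

```
log(theta_ij) = b1_j + b2_j * X_ij + S_ij + H_ij
```

where `S` is an intrinsic-CAR (spatially structured) tract effect per
city, `H` an unstructured normal effect per city (the BYM pair, with
city-specific variances), `E_ij` comes from indirect standardization and
`X_ij` is the covariate in percentage units, so `exp(b2_j)` is the
relative risk per 1% covariate increase.  Three nested priors on the city
coefficients:

| Variant | City coefficients | What you get |
|---|---|---|
| M1 | flat, independent | separate BYM regressions per city |
| M2 | `b2_j ~ N(beta, sigma_b2^2)` exchangeable | pooled RR `exp(beta)`, shrunken city RRs |
| M3 | `b2 ~ MVN(beta*1, sigma_2^2 * exp(-phi_2 * D))` | spatial sharing, effective range `-ln(0.05)/phi_2`, kriged RR surfaces |

Inference is Metropolis-within-Gibbs MCMC (C++ core) with
Brooks–Gelman–Rubin / effective-sample-size diagnostics and DIC model
comparison.  M3 surfaces report posterior mean RR, posterior SD and
P(RR > 1) at every grid point.  See the methods vignette
(`vignettes/multicity-ecological-regression.Rmd`) for the full model,
prior and sampler account.

## Worked example

Simulate a 31-city study at the package's default scale (overall RR
1.025 per 1%, effective range 400 km in a 1000 km region), fit the
geostatistical variant, and krige the slope surface:

```r
library(svcmap)
layout <- simulateLayout(J = 31, nPerCity = 36, regionKm = 1000, seed = 1)
ds     <- simulateDataset(layout, defaultTruth(), seed = 2)
fit    <- runMcmc(ds@data, ds@adjacency, modelSpec("M3"),
                  mcmcSettings(seed = 3), geo = ds@geo)

round(pooledRR(fit), 3)
#>  mean lower upper
#> 1.018 1.007 1.029
round(effectiveRangeSummary(fit))
#>  mean lower upper
#>   169    86   460
head(cityRR(fit), 3)
#>     city       rr     lower    upper
#> 1 city01 1.014907 0.9975729 1.032967
#> 2 city02 1.041888 1.0266101 1.056306
#> 3 city03 1.008414 0.9904756 1.025797
dic(fit, ds@data)
#> DIC = 4645.99 (Dbar = 4360.93, pD = 285.05)

grid <- makeGrid(c(0, 1000, 0, 1000), 100, 100)
surf <- predictSurface(krigeCoefficient(fit, ds@geo, grid, seed = 4,
                                        nDraws = 1000, joint = FALSE))
head(as.data.frame(surf), 3)
#>     x y  rr_mean      rr_sd prob_gt1
#> 1   0 0 1.016471 0.02341188    0.759
#> 2 100 0 1.016421 0.02230577    0.783
#> 3 200 0 1.023042 0.02140916    0.869
```

The pooled RR covers this replicate's generating value (1.025); the
effective-range posterior is wide at this single-dataset scale — its mean
lands within a factor of two of the truth in most replicates (that
calibration is exercised across 20 replicates in the test suite).  The
surface columns are the posterior mean RR at each grid point, its
posterior SD (growing with distance from the nearest city), and the
probability the RR exceeds 1.

A thin command-line wrapper over the same workflow functions
(`fit`, `simulate`, `predict`, `compare`, YAML configs) is installed at
`inst/cli/svcmap.R`.

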