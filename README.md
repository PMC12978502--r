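# holoreef

Holocene coral-reef growth reconstruction and spatio-temporal Bayesian
modelling.

## What this package is for

Radiocarbon-dated reef cores record how fast coral reefs built vertical
framework through the Holocene (the last 11,700 calibrated years before
1950 CE). Each pair of consecutive dated depths in a core is one
growth-rate sample: `rate = depth difference / age difference` (mm/yr).
`holoreef` is for researchers who want to relate such growth records to the
environmental and climatic history of the same intervals — rate of
sea-level change, sea-surface temperature (SST), surface insolation derived
from total solar irradiance and Earth's orbital configuration, atmospheric
CO2, volcanic aerosol forcing, and North Atlantic ice-rafted-debris (Bond
cycle) activity.

The core of the package is a hierarchical Bayesian gamma model for the
growth rate \(y_i\):

```
y_i ~ Gamma(alpha, alpha / mu_i)
log mu_i = beta_0 + x_i' beta                  (fixed effects, z-scored)
         + sum_k f_k(c_ki)                     (RW2 smooths on binned covariates)
         + sum_g u_g[i]                        (iid group effects)
         + s(loc_i)                            (Matern spatial field, SPDE/GMRF)
```

The spatial field uses the finite-element (SPDE) representation of a
Matern field on a triangular mesh with sparse precision
`Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)`; the smooths are
second-order random walks on binned covariates; inference is an
empirical-Bayes nested-Laplace scheme with hyperparameter-uncertainty
mixing. Model criticism uses WAIC, importance-weighted leave-one-out
predictive checks and probability integral transforms. A small
feed-forward network (two hidden layers, 20 and 10 rectified units, 30
restarts selected on validation RMSE) estimates nonlinear
partial-dependence responses of growth to SST, sea-level rate, and
latitude. A seeded synthetic-data generator emulates every input — dated
cores, proxy series at native resolutions, a gridded SST reconstruction
with missing cells, regional sea-level curves — from a generative model
with known parameters, so the whole pipeline is testable offline.

## Worked example

```r
library(holoreef)

## a complete synthetic study with known ground truth
sim <- synth_scenario("default", seed = 1)

## record filters: Holocene bound on T2, central 97% of pooled rates
samples <- percentile_filter(filter_max_age(sim$samples))
nrow(samples)                         # 329 growth samples
median(samples$segment_years)        # ~430 yr median segment length

## the hierarchical gamma model
fit <- reef_fit(rate ~ sl_rate + sst + volc + rw2(co2, bins = 20) +
                  rw2(mean_age, bins = 20) + iid(region) + iid(core_uid) +
                  spde(lon, lat),
                data = samples, n_draws = 1000, seed = 1)
summary(fit)
classify_effect(fit, "sl_rate", level = 0.8)
waic(fit)$waic
pit_loo(fit)$ks_p
```

This prints (abridged):

```
Hierarchical gamma growth model (log link)
  observations: 329
  fixed effects: sl_rate, sst, volc
  rw2 smooths: co2(20 bins), mean_age(20 bins)
  iid groups: region, core_uid
  spatial field: on ( 128 mesh nodes )
  gamma shape: 7.098

        term  mean    sd    q10  q90
 (Intercept)  0.73 0.265  0.418 1.04
     sl_rate  0.29 0.091  0.170 0.41
         sst -0.03 0.069 -0.116 0.06
        volc -0.01 0.024 -0.042 0.02

 sl_rate : credible-positive
     sst : not-credible
    volc : not-credible
WAIC: 786.4
PIT Kolmogorov-Smirnov p: 0.67
```

Read this as: the generating scenario has a positive sea-level-rate effect
and exactly null SST/volcanic effects, and the fit recovers that sign
pattern — the sea-level-rate coefficient (per sd of the covariate, log
scale) is credibly positive at the 80% level while the other two
coefficients straddle zero; the gamma shape near 7 matches the generating
noise level (truth 6), and the leave-one-out probability integral
transform is consistent with a calibrated model (Kolmogorov-Smirnov
p = 0.67). `effect_curve(fit, "co2")` exposes the posterior-mean smooth:
on this run its two local maxima sit at 265.8 and 279.7 ppmv against
generating bumps at 266 and 279.

The nonlinear response module works the same way on the `"optimum"`
scenario, whose truth peaks at exactly 25 C:

```r
opt <- synth_scenario("optimum", seed = 71)
d <- percentile_filter(filter_max_age(opt$samples))
nn <- nn_train_select(d, nn_config(seed = 71))      # 30 restarts, 20/10 units
pd <- partial_dependence(nn, d, "sst")
pd$grid[which.max(pd$mean_pred)]                    # 25.86 C (truth: 25 C)
```

Orbital elements come from a bundled truncated Berger-type series:

```r
orbital_elements(0)$obliquity    # 23.447 degrees at present
```

## Documentation

The methods vignette (`vignettes/holoreef-methods.Rmd`) describes the
model, priors, numerical choices, the synthetic scenarios and their
limitations. Every exported function carries roxygen documentation.
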