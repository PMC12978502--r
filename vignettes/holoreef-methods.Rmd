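---
title: "Modelling Holocene coral-reef growth with holoreef"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling Holocene coral-reef growth with holoreef}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Geological reef cores carry radiocarbon-dated depth points. Between two
dated points a core records how much carbonate framework accumulated over a
known interval, so each consecutive pair of dates yields one vertical
growth-rate sample (mm/yr). Pooled across hundreds of cores and sites, such
samples span the entire Holocene (the last 11,700 calibrated years before
1950 CE) and let us ask which environmental and climatic conditions favoured
reef growth: the rate of sea-level change (which creates accommodation
space), sea-surface temperature, solar irradiance at the sea surface,
atmospheric CO2, volcanic aerosol forcing, and North Atlantic drift-ice
(Bond-cycle) activity.

`holoreef` implements that full analysis pathway: record reconstruction and
filtering, covariate construction from paleo proxy archives, a hierarchical
Bayesian gamma model with a spatial random field and nonlinear smooths,
leave-one-out predictive validation, and a small feed-forward network for
partial-dependence response curves. A seeded synthetic-data generator
provides every input with known ground truth, so each stage — and the whole
pipeline — is testable without any external download.

## The growth record

`reconstruct_segments()` turns each core's dated points into samples: the
deeper, older date of a pair is the segment's T2, the shallower, younger
one its T1, and interior dates are shared between adjacent segments. The
rate is depth difference over age difference; `mean_age` is the arithmetic
midpoint (the only symmetric choice for an interval summary). Two filters
follow the compilation conventions for this kind of archive:

* `filter_max_age()` drops samples whose T2 exceeds 11,700 yr BP; the
  boundary itself is kept (the published retention counts are consistent
  with an inclusive bound).
* `percentile_filter()` removes two-tailed outliers, retaining the central
  97% of the pooled rate distribution (1.5% per tail). Quantiles use the
  linear-interpolation estimator (R's type 7) so retained counts are
  bit-reproducible. The filter is applied to the pooled rates, not per
  region, because retention counts for such archives are reported globally.

Cores with tied ages would give undefined rates for that pair; the pair is
skipped with a warning instead of rejecting the whole core. Depth is
conserved exactly: the segment lengths of a core sum to its dated depth
span.

`regional_trend()` is local linear regression with tricube weights
(`stats::loess`, degree 1) of rate on mean age with a pointwise 95% band;
it refuses regions with fewer than 10 samples. The Barbados region is a
special case: its reefs sit on a tectonically active platform, so it is
excluded from observational trend reporting (`regional_trends()`) while
remaining available for model fitting.

## Orbital elements and insolation

Surface insolation is computed geometrically from total solar irradiance
(TSI) and Earth's orbital configuration; no atmospheric attenuation is
applied, which is exactly how the standard daily-insolation computation for
paleoclimate work is defined. The orbital solution is a truncated
Berger-type trigonometric series (obliquity, eccentricity, general
precession) whose coefficient tables ship as plain-text files with
provenance headers. Truncation error over the Holocene is far below every
tolerance used downstream: the present-epoch obliquity evaluates to
23.447 degrees (reference 23.446), the Holocene obliquity range to 0.787
degrees, and the climatic precession index `e*sin(varpi)` spans ~0.037.

`daily_mean_insolation()` implements the textbook daily mean
`(S/pi) * rho^2 * (H0 sin(phi) sin(delta) + cos(phi) cos(delta) sin(H0))`,
with declination from obliquity and true solar longitude, sun-hour angle
H0 clamped for polar day and night (polar night returns exactly zero), and
the Kepler distance factor from eccentricity and the longitude of
perihelion. The calendar is a fixed 365-day year with standard month
lengths; the vernal equinox is pinned to day 80, and mean longitude is
converted to true longitude with the equation-of-centre expansion.
`annual_mean_insolation()` evaluates the 12 month midpoints and averages
with month-length weights; against a 1,000-point daily quadrature this
agrees to better than 1%, and the area-and-year average over the sphere
recovers TSI/4 to 0.1% (the orbit's eccentricity contributes the remaining
0.01-0.04%).

TSI anomalies are converted to absolute values against the 1365 W/m^2
reference before use.

## Sample-level covariates

Each proxy archive is interpolated with the same two rules: linear
interpolation weighted by temporal distance inside the record, and
nearest-endpoint extrapolation outside (`interp_at()`). Per-sample
aggregation follows the native resolution of each archive via
`segment_grid(T1, T2, step)` — ages T1, T1+step, ... with T2 always
appended, collapsing to the two endpoints when the segment is shorter than
one step:

* irradiance at 22-yr steps, each age point converted to annual-mean
  insolation at the site latitude and averaged (`sample_insolation()`);
  samples partially overlapping the TSI record use only in-record age
  points, and wholly-outside samples fall back to nearest-value
  extrapolation;
* CO2 at 8-yr and ice-rafted debris at 70-yr steps through the shared
  kernel `sample_mean_series()`;
* SST from the nearest grid cell holding data (great-circle distance via
  `geosphere`), averaging the native 200-yr series clipped to the segment
  plus interpolated endpoint values — which reduces to the endpoint mean
  for sub-resolution segments (`sample_sst()`);
* sea-level rate as the mean of year-to-year differences of submergence
  interpolated at every integer year in the segment, in mm/yr with rising
  sea level positive (`sea_level_rate()`); the annual mean telescopes to
  the endpoint slope of the year grid, which pins the convention and makes
  linear curves exact;
* volcanic forcing from monthly stratospheric aerosol optical depth:
  calendar-year means per 10-degree band, linear interpolation between the
  flanking band centres (clamped at the outermost bands), scaling at
  25 W/m^2 per unit SAOD, 20-year window sums at a 1-year stride kept fully
  inside the segment, and the mean of the window sums as the sample metric
  (`volcanic_metric()`); segments shorter than a window use one window of
  all available years.

The 1-year stride is the natural "rolling" choice and maximises the
boundary-effect avoidance that motivates overlapping windows; windows are
kept inside the segment because covariates should not borrow forcing from
outside the interval whose growth they explain. The year grid for sea level
uses integer calendar years between `ceiling(T1)` and `floor(T2)`, documented
so results are reproducible to the bit.

`correlation_screen()` reports pairwise Pearson correlations on complete
cases and flags |r| > 0.7; in both the real system and the synthetic
scenarios, absolute latitude, insolation and SST form such a cluster, which
is why SST alone enters the model as a fixed effect.

## The hierarchical gamma model

Growth rates are positive and right-skewed, so the response is gamma with a
log link — the standard link for gamma mixed models, making effects
multiplicative:

y_i ~ Gamma(alpha, alpha / mu_i)

log mu_i = beta_0 + x_i' beta + sum_k f_k(c_ki) + sum_g u_g[i] + s(loc_i)

with z-scored fixed effects (sea-level rate, SST, volcanic forcing),
second-order random-walk smooths f_k on binned CO2, ice-rafted debris, mean
age and segment length, exchangeable (iid) group effects u for ocean,
region, locality and core, and a Matern spatial field s. The formula
interface mirrors the model:
`rate ~ sl_rate + sst + volc + rw2(co2, bins = 20) + iid(region) + spde(lon, lat)`.

**Spatial field.** The Matern field (smoothness alpha = 2 in two
dimensions) is represented as a finite-element Gaussian Markov random field
on a triangular mesh: `build_mesh()` triangulates (Bowyer-Watson) a node
set that is fine near sites and coarse over a buffered hull, and
`spde_precision()` assembles `Q = tau^2 (kappa^4 C + 2 kappa^2 G + G C^-1 G)`
from the lumped mass matrix C and stiffness matrix G. The closed-form
marginal variance `1/(4 pi kappa^2 tau^2)` and the correlation-0.13 range
`sqrt(8)/kappa` are asserted against Monte-Carlo field draws in the tests.
Sites are projected to a local equirectangular plane in kilometres
(`project_coords()`); distances enter the Matern kernel, so the projection
is fixed and documented. A great-circle mesh is a possible extension but
regional-to-basin extents at Matern ranges of a few thousand kilometres are
served adequately by the planar approximation.

**Smooths.** Each rw2 covariate is cut into equal-width bins over its
observed range (20 by default, balancing resolution against per-bin sample
support); the smooth gets the second-difference penalty `D'D` of rank
`bins - 2`, a tight prior on its mean level acting as a soft sum-to-zero
constraint, and a hair of ridge for propriety. The unpenalised linear
component stays effectively free, as second-order random walks intend.

**Priors.** Nothing in the source analysis pins the priors, so the
defaults are penalised-complexity-style and exposed in `reef_priors()`:
exponential priors on every random-effect standard deviation (rate 2.3,
i.e. 10% prior mass above one log-unit), an inverse-range prior for the
field with median at 30% of the site extent plus an exponential prior on
the field sd, N(0, 1) on standardised fixed effects, N(0, 10^2) on the
intercept, and an exponential-rate gamma prior on the shape. Every choice
is a config argument.

**Inference.** All latent effects are jointly Gaussian given the
hyperparameters and the gamma log-likelihood is strictly log-concave in the
linear predictor, so the package uses a nested-Laplace scheme: an inner
damped-Newton iteration yields the Gaussian approximation of the latent
field at fixed hyperparameters; the Laplace-approximate marginal likelihood
(plus hyperpriors) is maximised over the low-dimensional hyperparameter
vector by `nlminb`; and, by default (`hyper = "integrate"`), hyperparameter
uncertainty is propagated by drawing hyperparameters from a Gaussian
approximation at their posterior mode (numerical Hessian) and mixing the
latent Gaussian approximations across those draws. The contract is
statistical, not algorithmic: on data simulated from the model, posterior
means converge to the generating values and interval coverage is honest,
which is what the test suite asserts. A `"plugin"` mode skips the
hyperparameter mixture for speed. Non-convergence of either loop is flagged
in `$flags`, never silent.

**Validation.** `waic()` computes `-2(lppd - p_waic)` from the stored
draw-by-observation log-likelihood matrix and is tested to machine
tolerance against the raw definition; `compare_models()` ranks candidate
fits. `pit_loo()` approximates leave-one-out predictive distributions by
importance-weighting the posterior draws with the reciprocal of each
observation's likelihood (weights truncated at sqrt(S) times their mean,
the standard stabilisation), evaluates the predictive CDF at the
observation, and summarises departure from uniformity with a
Kolmogorov-Smirnov statistic. Observations whose importance weights carry
an effective sample size below S/10 are flagged. `classify_effect()`
labels a coefficient credible-positive, credible-negative, or not-credible
by whether the equal-tailed interval at the requested level (50/80/90%)
excludes zero.

## The nonlinear-response network

`nn_train_select()` follows a fixed protocol: a seeded 70/15/15
train/test/validation split (`split_data()`), a multilayer perceptron with
two hidden layers of 20 and 10 rectified units, squared-error loss, Adam
updates (learning rate 0.01, mini-batches of 32), at most 100 epochs with
early stopping after 5 epochs without validation improvement, 30 random
restarts, and selection of the run with the lowest validation RMSE. The
activation, optimiser and loss are free choices of the protocol, so the
package uses those mainstream defaults and records them in `nn_config()`;
`nn_candidates()` documents a six-architecture screening list containing
the final 20/10 layout. Inputs are z-scored internally and predictions
return on the original mm/yr scale. Early stopping monitors the validation
split — the same split that drives selection — because a consistent
monitor/selection pair is the least surprising resolution of an ambiguous
protocol.

`partial_dependence()` sweeps one input over a grid (defaulting to 50
points over the observed range), sets it to each grid value for every
record, averages the predictions, and carries a histogram of the observed
input so sparse regions are visible. PDPs of additive signals recover each
component up to a constant; a zero-weight input gives an exactly flat
curve; both are tested.

## The synthetic scenarios

`synth_scenario()` builds complete, seeded inputs: every generator draws
from a substream keyed by a label (`substream_seed()`), so adding a
generator never perturbs existing output under the same base seed, and
identical (config, seed) reproduce byte-identical data.

The **default scenario** is the desk-scale study condition used by the
recovery tests: 40 sites in six regions across three ocean basins, a
Poisson number of cores per site and dated points per core, log-normal age
gaps with median near the ~410-yr segment scale of the emulated archive,
and environmental records at native resolutions (22-yr TSI anomaly, 8-yr
CO2 ramp-plus-cycle between ~252 and ~288 ppmv, 70-yr ice-rafted debris
with a 1,470-yr Bond-type cycle, monthly aerosol optical depth in
10-degree bands driven by a Poisson eruption process with 18-month decay,
a 1-degree/200-yr SST grid with a latitudinal gradient, a mid-Holocene warm
anomaly, 10% random missing cells plus a deliberate data hole near one
region to exercise nearest-valid-cell search, and basin-style sea-level
curves: Pacific/Indian stabilising ~5,500 yr BP, the Atlantic still rising
until ~50 yr BP). The generative log-mean combines an intercept, a
sea-level-rate coefficient of 0.25 per mm/yr, exactly null SST and
volcanic coefficients, a bimodal CO2 effect (Gaussian bumps at 266 and 279
ppmv, amplitude 0.5), a smooth age effect, a Matern field (sd 0.25, range
2,500 km), iid ocean/region/locality/core effects, and gamma noise with
shape 6. The effect sizes were fixed by a design-stage power argument: the
scenario exists to exhibit a decisive positive sea-level effect and a
clearly bimodal CO2 response, so both are sized to be recoverable at
n ~ 300 — a deliberately detectable regime, not an estimate of the real
system's effect sizes.

The **optimum scenario** drives the nonlinear-response tests: a growth
optimum at exactly 25 C (Gaussian in SST, amplitude 1.0, sd 2.0 C), a
sea-level-rate effect rising to a plateau at 20 mm/yr, a mild latitude
penalty, and regionally staggered sea-level stabilisation ages so that
temperature, sea-level rate and age are not one shared axis. Heterogeneity
that is unobservable to the network's three inputs (locality, region,
spatial lumps) is kept small (sd 0.05-0.08) by design: the network cannot
condition on what it cannot see, and an identifiability experiment should
not be decided by unobservable noise. An oracle check with an independent
smoother (a gamma GAM) confirmed that with larger unobservable lumps the
data themselves — not the estimator — carry a spurious warm-edge optimum.

What the generator does **not** emulate: real spatial clustering of
sampling effort, radiocarbon calibration error (ages arrive calibrated),
reservoir corrections, proxy-specific biases of the environmental
reconstructions, or tectonics. Passing recovery tests therefore show that
the estimators work on data from the stated generative family at desk
scale; they do not validate the reconstruction choices embedded in the
real archives.

## Numerical choices and degenerate inputs

* Quantile estimator: linear interpolation (type 7), so filter counts are
  exactly reproducible.
* Tied ages in a core: the zero-duration pair is skipped with a warning.
* Gamma Newton weights are clamped at |eta| = 40 to avoid overflow; the
  inner Newton is damped by step-halving and declares convergence at a
  1e-8 relative step.
* The Bowyer-Watson triangulation centres and rescales coordinates, and
  grid nodes get a seeded 1e-3-edge jitter to break co-circular
  degeneracy; fully collinear site sets are rejected.
* Latent draws use the sparse Cholesky factor with its fill-reducing
  permutation applied on both solve legs.
* With zero data rows the fit returns the prior at the initial
  hyperparameters — used by the prior-predictive tests.
* PDP grids must stay inside the observed range of the variable
  (extrapolated partial dependence is undefined by construction).

## Problem sizes used by the test suite

The suite regenerates everything it tests: default-scenario fits use ~40
sites and ~300 samples with 1,000 posterior draws (16 hyperparameter
draws), the Monte-Carlo field check uses a ~10x10 domain with 2,000 draws,
the covariate oracle suite runs 500 randomised cases per operation, the
WAIC screen runs 50 small replicates, and the network tests train 30
restarts per seed on ~600-sample optimum scenarios. These sizes were
chosen as the smallest at which the statistical contracts are sharp.

## Known limitations

* The Laplace posterior is a Gaussian mixture approximation; strongly
  non-Gaussian latent posteriors (tiny groups, extreme shapes) are outside
  its comfort zone, and the `$flags` field should be consulted.
* The planar projection distorts basin-scale distances at global extents;
  the Matern range is interpreted in projected kilometres.
* The importance-weighted leave-one-out is the truncated-weight variant;
  observations with flagged weights deserve a refit-without-observation
  check.
* Joint classification events compound interval calibration: with exactly
  calibrated 80% intervals, two truly-null effects both land "not-credible"
  only ~64% of the time. Replicate studies of sign patterns should judge
  each effect marginally or widen the level accordingly.
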