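# Seeded synthetic study data: sites, cores, dated intervals, all paleo
# forcing records, an SST grid with missing cells, regional sea-level
# curves, and a generative gamma growth model with known parameters. The
# default scenario is sized for desk studies (40 sites, ~300 growth
# samples); the "optimum" scenario builds in a 25 C temperature optimum and
# a sea-level-rate plateau at 20 mm/yr; "paper_scale" approximates the size
# of the real compilation and is provided for exploration only.

#' Scenario configuration for the synthetic generator
#'
#' All defaults are fixed study conditions: record resolutions mirror the
#' emulated archives (22-year irradiance, 8-year CO2, monthly aerosol depth
#' in 10-degree bands, 70-year ice-rafted debris, 200-year ~1-degree SST),
#' Pacific/Indian sea level stabilises at ~5,500 yr BP while the Atlantic
#' keeps rising until ~50 yr BP, and the generative growth model uses a
#' positive sea-level-rate coefficient with null SST and volcanic
#' coefficients plus a bimodal CO2 smooth (the "optimum" scenario instead
#' peaks at 25 C and plateaus above 20 mm/yr).
#'
#' @param name one of `"default"`, `"optimum"`, `"paper_scale"`.
#' @param ... named overrides of individual fields.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(name = c("default", "optimum", "paper_scale"), ...) {
  name <- match.arg(name)
  regions <- data.frame(
    region = c("Caribbean", "Red Sea", "Indian Ocean", "Asia",
               "Central Pacific", "Eastern Australia"),
    ocean = c("Atlantic", "Indian", "Indian", "Pacific", "Pacific", "Pacific"),
    lon_c = c(-75, 38, 73, 115, 172, 150),
    lat_c = c(18, 22, -5, 15, -8, -20),
    stringsAsFactors = FALSE)
  cfg <- list(
    name = name,
    regions = regions,
    n_sites = 40L,
    site_spread_deg = 4,
    cores_per_site_mean = 2,
    extra_points_per_core_mean = 3.2,   # points per core = 2 + Poisson
    gap_meanlog = log(410), gap_sdlog = 0.7,
    young_age_max = 8000,
    age_span = c(0, 11700),
    age_cap = 12800,
    # environmental series
    tsi_step = 22, tsi_span = c(0, 9389), tsi_amp = 0.4, tsi_period = 2300,
    tsi_noise = 0.15,
    co2_step = 8, co2_base = 258, co2_ramp = 22, co2_cycle_amp = 6,
    co2_cycle_period = 2500, co2_noise = 1,
    ird_step = 70, ird_mean = 5, bond_amp = 3, bond_period = 1470,
    ird_noise = 0.4,
    eruption_rate = 1 / 40, eruption_meanlog = log(0.03), eruption_sdlog = 1,
    eruption_decay_months = 18, saod_background = 0.002,
    sst_lat = seq(-35, 35, by = 1), sst_lon = seq(-85, 180, by = 1),
    sst_step = 200, sst_base = 28.5, sst_lat_coef = 0.010, htm_amp = 1.0,
    sst_noise = 0.3, sst_missing_frac = 0.10, sst_hole_region = "Red Sea",
    sst_hole_deg = 3,
    sl_rate_max_pi = 8, sl_stab_pi = 5500,    # Pacific/Indian basins
    sl_rate_max_atl = 4, sl_stab_atl = 50,    # late-stabilising Atlantic
    sl_stab_spread = 0,  # regional stagger of stabilisation ages (yr)
    # generative growth model
    truth = list(b0 = log(1.8), b_slr = 0.25, b_sst = 0, b_volc = 0,
                 b_abslat = 0,
                 co2_bumps = c(266, 279), co2_bump_sd = 3.5, co2_bump_amp = 0.5,
                 age_amp = 0.15, age_period = 9000,
                 sst_opt = NULL, sst_opt_sd = 2.5, sst_opt_amp = 0,
                 slr_plateau = NULL, slr_plateau_slope = 0,
                 spatial_sigma = 0.25, spatial_range_km = 2500,
                 sd_ocean = 0.10, sd_region = 0.15, sd_locality = 0.10,
                 sd_core = 0.15, shape = 6))
  if (name == "optimum") {
    cfg$n_sites <- 60L
    cfg$site_spread_deg <- 8
    cfg$cores_per_site_mean <- 2.5
    cfg$sst_base <- 29.5; cfg$sst_lat_coef <- 0.012
    cfg$sl_rate_max_pi <- 30; cfg$sl_stab_pi <- 4500
    cfg$sl_rate_max_atl <- 30; cfg$sl_stab_atl <- 4500
    cfg$sl_stab_spread <- 2000
    cfg$truth$b0 <- log(1.5)
    cfg$truth$b_slr <- 0
    cfg$truth$co2_bump_amp <- 0
    cfg$truth$age_amp <- 0
    cfg$truth$sst_opt <- 25; cfg$truth$sst_opt_amp <- 1.0
    cfg$truth$sst_opt_sd <- 2.0
    cfg$truth$slr_plateau <- 20; cfg$truth$slr_plateau_slope <- 0.04
    cfg$truth$b_abslat <- -0.008
    cfg$truth$spatial_sigma <- 0.08
    cfg$truth$sd_ocean <- 0.05; cfg$truth$sd_region <- 0.05
    cfg$truth$sd_locality <- 0.05; cfg$truth$sd_core <- 0.05
    cfg$truth$shape <- 8
  }
  if (name == "paper_scale") {
    cfg$n_sites <- 290L
    cfg$cores_per_site_mean <- 2.4
  }
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "truth") cfg$truth[names(dots$truth)] <- dots$truth
    else cfg[[nm]] <- dots[[nm]]
  }
  structure(cfg, class = "scenario_config")
}

#' Generate the synthetic environmental records
#'
#' Builds every forcing input at its native resolution: the irradiance
#' anomaly, CO2 and ice-rafted debris proxy series, a monthly stratospheric
#' aerosol record in 10-degree bands driven by a Poisson eruption process,
#' a gridded SST reconstruction with a built-in latitudinal gradient, a
#' mid-Holocene warm anomaly and deliberately missing cells near one region,
#' and basin-style regional sea-level curves.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return List with elements `tsi`, `co2`, `ird` ([paleo_series()]),
#'   `saod` ([saod_record()]), `sst` ([sst_grid()]), `sealevel` (named list
#'   of [sea_level_curve()]).
#' @export
gen_environment <- function(config, seed = 1L) {
  span <- c(0, config$age_cap)

  set.seed(substream_seed(seed, "env-tsi"))
  ages <- seq(config$tsi_span[1], config$tsi_span[2], by = config$tsi_step)
  tsi <- paleo_series(ages,
                      config$tsi_amp * sin(2 * pi * ages / config$tsi_period) +
                        rnorm(length(ages), sd = config$tsi_noise),
                      units = "W/m2 anomaly", native_step = config$tsi_step)

  set.seed(substream_seed(seed, "env-co2"))
  ages <- seq(span[1], span[2], by = config$co2_step)
  frac <- pmin(1, ages / config$age_span[2])
  co2 <- paleo_series(ages,
                      config$co2_base + config$co2_ramp * (1 - frac) +
                        config$co2_cycle_amp * sin(2 * pi * ages / config$co2_cycle_period) +
                        rnorm(length(ages), sd = config$co2_noise),
                      units = "ppmv", native_step = config$co2_step)

  set.seed(substream_seed(seed, "env-ird"))
  ages <- seq(span[1], span[2], by = config$ird_step)
  ird <- paleo_series(ages,
                      pmax(0, config$ird_mean +
                             config$bond_amp * sin(2 * pi * ages / config$bond_period) +
                             rnorm(length(ages), sd = config$ird_noise)),
                      units = "% lithic grains", native_step = config$ird_step)

  set.seed(substream_seed(seed, "env-saod"))
  n_years <- span[2] + 1L
  months <- seq(0.5 / 12, n_years, by = 1 / 12)[seq_len(n_years * 12L)]
  bands <- seq(-85, 85, by = 10)
  m <- matrix(config$saod_background, length(months), length(bands))
  n_erupt <- rpois(1, config$eruption_rate * n_years)
  e_year <- runif(n_erupt, 0, n_years - 1)
  e_peak <- rlnorm(n_erupt, config$eruption_meanlog, config$eruption_sdlog)
  e_lat <- runif(n_erupt, -60, 60)
  decay <- exp(-(0:(4 * 12 - 1)) / config$eruption_decay_months)
  for (e in seq_len(n_erupt)) {
    m0 <- floor(e_year[e] * 12) + 1L
    rows <- m0:min(m0 + length(decay) - 1L, length(months))
    prof <- exp(-((bands - e_lat[e]) / 30)^2)
    m[rows, ] <- m[rows, ] + e_peak[e] * decay[seq_along(rows)] %o% prof
  }
  saod <- saod_record(months, bands, pmin(m, 1.5))

  set.seed(substream_seed(seed, "env-sst"))
  lat <- config$sst_lat; lon <- config$sst_lon
  ages <- seq(span[1], span[2], by = config$sst_step)
  base <- config$sst_base - config$sst_lat_coef * lat^2
  htm <- config$htm_amp * exp(-((ages - 8000) / 2500)^2)
  arr <- array(0, dim = c(length(lat), length(lon), length(ages)))
  for (k in seq_along(ages)) {
    arr[, , k] <- outer(base + htm[k], 0.5 * sin(lon * pi / 60), `+`) +
      rnorm(length(lat) * length(lon), sd = config$sst_noise)
  }
  mask <- matrix(runif(length(lat) * length(lon)) < config$sst_missing_frac,
                 length(lat), length(lon))
  hole <- config$regions[config$regions$region == config$sst_hole_region, ]
  if (nrow(hole) == 1L) {
    mask <- mask | outer(abs(lat - hole$lat_c) <= config$sst_hole_deg,
                         abs(lon - hole$lon_c) <= config$sst_hole_deg, `&`)
  }
  arr[which(rep(mask, length(ages)))] <- NA_real_
  arr <- pmin(pmax(arr, -4.5), 39.5)
  sst <- sst_grid(lat, lon, ages, arr)

  sealevel <- list()
  grid_ages <- seq(0, config$age_cap, by = 25)
  n_reg <- nrow(config$regions)
  stab_offsets <- if (n_reg > 1) {
    seq(-1, 1, length.out = n_reg) * config$sl_stab_spread
  } else 0
  for (r in seq_len(n_reg)) {
    atl <- config$regions$ocean[r] == "Atlantic"
    stab <- if (atl) config$sl_stab_atl else config$sl_stab_pi
    stab <- max(50, stab + stab_offsets[r])
    rmax <- if (atl) config$sl_rate_max_atl else config$sl_rate_max_pi
    rate <- rmax * pmin(1, pmax(0, (grid_ages - stab) /
                                  max(config$age_span[2] - stab, 1)))
    sub_m <- cumsum(c(0, (rate[-1] + rate[-length(rate)]) / 2 * diff(grid_ages))) / 1000
    sealevel[[config$regions$region[r]]] <-
      sea_level_curve(config$regions$region[r], grid_ages, sub_m)
  }

  list(tsi = tsi, co2 = co2, ird = ird, saod = saod, sst = sst,
       sealevel = sealevel)
}

#' Generate synthetic dated core points
#'
#' Sites are scattered around the configured region centres; each site gets
#' a Poisson number of cores and each core a Poisson number of dated points
#' whose age gaps are log-normal (median near the emulated archive's ~410-yr
#' segment length). Depths accumulate as positive increments, so age-depth
#' monotonicity holds by construction; final depths are overwritten by
#' [simulate_growth()] to be consistent with the generated rates.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @return Data frame of dated core points (schema of [read_core_points()]).
#' @export
gen_cores <- function(config, seed = 1L) {
  set.seed(substream_seed(seed, "cores"))
  reg <- config$regions
  n_reg <- nrow(reg)
  sites_per_reg <- diff(round(seq(0, config$n_sites, length.out = n_reg + 1)))
  studies <- paste0("SynStudy", LETTERS[1:4])
  zones <- c("fringing", "reef crest", "back reef", "fore reef")
  rows <- list()
  site_no <- 0L
  for (r in seq_len(n_reg)) {
    for (s in seq_len(sites_per_reg[r])) {
      site_no <- site_no + 1L
      lon <- reg$lon_c[r] + runif(1, -1, 1) * config$site_spread_deg
      lat <- reg$lat_c[r] + runif(1, -1, 1) * config$site_spread_deg
      lat <- pmin(pmax(lat, min(config$sst_lat) + 1), max(config$sst_lat) - 1)
      locality <- sprintf("Site%03d", site_no)
      n_cores <- 1L + rpois(1, config$cores_per_site_mean - 1)
      for (cc in seq_len(n_cores)) {
        study <- sample(studies, 1)
        core <- sprintf("P%d-%d", site_no, cc)
        n_pts <- 2L + rpois(1, config$extra_points_per_core_mean)
        t_young <- runif(1, 0, config$young_age_max)
        gaps <- pmax(5, rlnorm(n_pts - 1L, config$gap_meanlog, config$gap_sdlog))
        ages <- t_young + cumsum(c(0, gaps))
        ages <- ages[ages <= config$age_cap]
        if (length(ages) < 2L) ages <- t_young + c(0, gaps[1])
        prov_rate <- rlnorm(1, log(2), 0.4)
        depths <- runif(1, 0, 500) + c(0, cumsum(diff(ages) * prov_rate))
        rows[[length(rows) + 1L]] <- data.frame(
          study = study, core = core, lon = lon, lat = lat,
          region = reg$region[r], ocean = reg$ocean[r], locality = locality,
          reef_zone = sample(zones, 1), age_ybp = ages, depth_mm = depths)
      }
    }
  }
  do.call(rbind, rows)
}

# Evaluate the generative log-mean at a covariate table.
.truth_eta <- function(tr, cov) {
  eta <- tr$b0 + tr$b_slr * cov$sl_rate + tr$b_sst * cov$sst +
    tr$b_volc * cov$volc + tr$b_abslat * cov$abs_latitude
  if (tr$co2_bump_amp != 0) {
    for (b in tr$co2_bumps) {
      eta <- eta + tr$co2_bump_amp * exp(-((cov$co2 - b) / tr$co2_bump_sd)^2)
    }
    eta <- eta - tr$co2_bump_amp  # centre roughly around zero
  }
  if (tr$age_amp != 0) eta <- eta + tr$age_amp * cos(2 * pi * cov$mean_age / tr$age_period)
  if (!is.null(tr$sst_opt) && tr$sst_opt_amp != 0) {
    eta <- eta + tr$sst_opt_amp * exp(-((cov$sst - tr$sst_opt) / tr$sst_opt_sd)^2)
  }
  if (!is.null(tr$slr_plateau) && tr$slr_plateau_slope != 0) {
    eta <- eta + tr$slr_plateau_slope * pmin(cov$sl_rate, tr$slr_plateau)
  }
  eta
}

#' Simulate growth rates from the generative model
#'
#' Reconstructs segments from the dated points, computes their covariates
#' from the environment, evaluates the generative log-mean (fixed effects,
#' nonlinear smooth shapes, a Matern spatial field drawn on a mesh over the
#' sites, and iid ocean/region/locality/core effects), and draws gamma
#' growth rates. Depths of the input points are rewritten so that each
#' core's depth increments equal rate x time, keeping the record internally
#' consistent.
#'
#' @param points dated core points from [gen_cores()].
#' @param env environment list from [gen_environment()].
#' @param config a [scenario_config()] (its `truth` element is the ground
#'   truth).
#' @param seed integer seed.
#' @return List of class `reef_sim` with `points` (depth-consistent),
#'   `samples` (segments with covariates and simulated `rate`), `env`,
#'   `truth` (generating parameters, field values, iid draws, and the
#'   per-sample linear predictor), and `config`.
#' @export
simulate_growth <- function(points, env, config, seed = 1L) {
  suppressWarnings(segments <- reconstruct_segments(points))
  cov <- build_covariates(segments, env)
  tr <- config$truth

  coords <- project_coords(cov$lon, cov$lat)
  kappa <- sqrt(8) / tr$spatial_range_km
  tau <- 1 / (sqrt(4 * pi) * kappa * tr$spatial_sigma)
  extent <- max(apply(coords, 2, function(z) diff(range(z))), 1)
  mesh <- build_mesh(coords, fine_edge = extent / 12, coarse_edge = extent / 4,
                     buffer = extent / 3, seed = substream_seed(seed, "sim-mesh"))
  Q <- spde_precision(mesh, kappa, tau)
  field <- spde_sample(Q, 1, seed = substream_seed(seed, "sim-field"))[, 1]
  s <- as.numeric(mesh_project(mesh, coords) %*% field)

  draw_iid <- function(label, values, sd) {
    lev <- unique(values)
    set.seed(substream_seed(seed, paste0("sim-iid-", label)))
    setNames(rnorm(length(lev), sd = sd), lev)
  }
  u_ocean <- draw_iid("ocean", cov$ocean, tr$sd_ocean)
  u_region <- draw_iid("region", cov$region, tr$sd_region)
  u_loc <- draw_iid("locality", cov$locality, tr$sd_locality)
  u_core <- draw_iid("core", cov$core_uid, tr$sd_core)

  eta <- unname(.truth_eta(tr, cov) + s + u_ocean[cov$ocean] +
                  u_region[cov$region] + u_loc[cov$locality] +
                  u_core[cov$core_uid])
  mu <- exp(eta)
  set.seed(substream_seed(seed, "sim-rates"))
  rate <- rgamma(nrow(cov), shape = tr$shape, rate = tr$shape / mu)

  cov$rate <- rate
  cov$segment_mm <- rate * cov$segment_years

  # rewrite depths so the record is consistent with the simulated rates
  pts <- points[order(points$core_uid %||% build_core_uid(points$study, points$core),
                      points$age_ybp), ]
  pts$core_uid <- build_core_uid(pts$study, pts$core)
  for (uid in unique(pts$core_uid)) {
    sel <- which(pts$core_uid == uid)
    seg <- cov[cov$core_uid == uid, ]
    if (nrow(seg) == 0) next
    seg <- seg[order(seg$T1_age), ]
    pts$depth_mm[sel] <- pts$depth_mm[sel][1] +
      c(0, cumsum(seg$segment_mm))[seq_along(sel)]
  }

  structure(list(points = pts, samples = cov, env = env,
                 truth = c(tr, list(field = field, mesh = mesh,
                                    u_ocean = u_ocean, u_region = u_region,
                                    u_locality = u_loc, u_core = u_core,
                                    eta = eta, seed = seed)),
                 config = config), class = "reef_sim")
}

#' Generate a complete synthetic scenario
#'
#' Convenience wrapper: environment, cores, and simulated growth under one
#' base seed (substreams keep the components independently reproducible).
#'
#' @param name scenario name, see [scenario_config()].
#' @param seed integer seed.
#' @param config optional pre-built configuration (overrides `name`).
#' @return A `reef_sim` (see [simulate_growth()]).
#' @export
synth_scenario <- function(name = "default", seed = 1L, config = NULL) {
  config <- config %||% scenario_config(name)
  env <- gen_environment(config, seed = seed)
  pts <- gen_cores(config, seed = seed)
  simulate_growth(pts, env, config, seed = seed)
}

#' Write a synthetic scenario to disk in the reader formats
#'
#' Emits the CSV dialects the reader functions accept plus a ground-truth
#' JSON for scoring recovery experiments. The monthly aerosol record is
#' large in long form; writing can be restricted to the other inputs.
#'
#' @param sim a `reef_sim`.
#' @param dir output directory (created if needed).
#' @param include_saod write the (large) long-format monthly SAOD CSV.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir, include_saod = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(sim$points, file.path(dir, "points.csv"), row.names = FALSE)
  write.csv(sim$samples, file.path(dir, "samples.csv"), row.names = FALSE)
  ser <- function(x, f) write.csv(data.frame(age_ybp = x$ages, value = x$values),
                                  file.path(dir, f), row.names = FALSE)
  ser(sim$env$tsi, "tsi.csv"); ser(sim$env$co2, "co2.csv"); ser(sim$env$ird, "ird.csv")
  for (r in names(sim$env$sealevel)) {
    cv <- sim$env$sealevel[[r]]$series
    write.csv(data.frame(age_ybp = cv$ages, level_m = cv$values),
              file.path(dir, paste0("sealevel_", gsub("\\W+", "_", r), ".csv")),
              row.names = FALSE)
  }
  if (include_saod) {
    sa <- sim$env$saod
    long <- data.frame(age_ybp = rep(sa$ages, times = length(sa$band_centers)),
                       lat_band = rep(sa$band_centers, each = length(sa$ages)),
                       saod = as.numeric(sa$saod))
    write.csv(long, file.path(dir, "saod.csv"), row.names = FALSE)
  }
  tr <- sim$truth
  keep <- !vapply(tr, function(z) inherits(z, "reef_mesh") || length(z) > 500, logical(1))
  jsonlite::write_json(tr[keep], file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
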