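# Synthetic scenario generator: determinism, record structure, and the
# generative growth model.

test_that("generation is deterministic given (config, seed)", {
  cfg <- scenario_config("default", n_sites = 10L)
  e1 <- gen_environment(cfg, seed = 5)
  e2 <- gen_environment(cfg, seed = 5)
  expect_identical(e1$co2$values, e2$co2$values)
  expect_identical(e1$saod$saod, e2$saod$saod)
  expect_identical(e1$sst$sst, e2$sst$sst)
  p1 <- gen_cores(cfg, seed = 5)
  p2 <- gen_cores(cfg, seed = 5)
  expect_identical(p1, p2)
  e3 <- gen_environment(cfg, seed = 6)
  expect_false(identical(e1$co2$values, e3$co2$values))
})

test_that("environmental records carry the stated native resolutions", {
  cfg <- scenario_config("default", n_sites = 8L)
  env <- gen_environment(cfg, seed = 3)
  expect_equal(unique(diff(env$tsi$ages)), 22)
  expect_equal(unique(diff(env$co2$ages)), 8)
  expect_equal(unique(diff(env$ird$ages)), 70)
  expect_equal(unique(diff(env$sst$ages)), 200)
  expect_equal(diff(env$saod$ages)[1], 1 / 12, tolerance = 1e-9)
  expect_equal(unique(diff(env$saod$band_centers)), 10)
  expect_true(all(env$co2$values > 150 & env$co2$values < 500))
  expect_true(all(env$ird$values >= 0))
  # built-in SST gradient: warmer at the equator than at 30 degrees
  eq <- mean(env$sst$sst[env$sst$lat == 0, , ], na.rm = TRUE)
  mid <- mean(env$sst$sst[abs(env$sst$lat) == 30, , ], na.rm = TRUE)
  expect_gt(eq, mid)
  # the deliberate data hole near one region exists
  hole <- cfg$regions[cfg$regions$region == cfg$sst_hole_region, ]
  cells <- env$sst$sst[abs(env$sst$lat - hole$lat_c) <= cfg$sst_hole_deg,
                       abs(env$sst$lon - hole$lon_c) <= cfg$sst_hole_deg, ]
  expect_true(all(is.na(cells)))
})

test_that("a zero-eruption configuration produces zero volcanic forcing", {
  cfg <- scenario_config("default", n_sites = 8L, eruption_rate = 0,
                         saod_background = 0)
  env <- gen_environment(cfg, seed = 2)
  expect_true(all(env$saod$saod == 0))
  expect_equal(volcanic_metric(5, 1000, 1800, env$saod), 0)
})

test_that("the ice-rafted debris series peaks at the configured Bond period", {
  cfg <- scenario_config("default", ird_noise = 0.2)
  env <- gen_environment(cfg, seed = 9)
  x <- env$ird$values - mean(env$ird$values)
  sp <- spec.pgram(ts(x, deltat = cfg$ird_step), plot = FALSE, taper = 0)
  peak_period <- 1 / sp$freq[which.max(sp$spec)]
  expect_lt(abs(peak_period - cfg$bond_period) / cfg$bond_period, 0.25)
})

test_that("synthetic cores have the emulated record geometry", {
  cfg <- scenario_config("default")
  pts <- gen_cores(cfg, seed = 4)
  expect_true(all(pts$age_ybp <= cfg$age_cap))
  expect_silent(read_core_points(pts))  # monotone age-depth by construction
  seg <- reconstruct_segments(pts)
  # k dated points in a core yield k-1 segments
  n_pts <- table(pts$core_uid <- build_core_uid(pts$study, pts$core))
  n_seg <- table(seg$core_uid)
  expect_equal(as.integer(n_seg[names(n_pts)]), as.integer(n_pts) - 1L)
  # median segment length within a factor of 2 of the ~410-yr archive scale
  expect_gt(median(seg$segment_years), 205)
  expect_lt(median(seg$segment_years), 820)
})

test_that("simulated rates follow the generative gamma mean", {
  cfg <- scenario_config("default", n_sites = 24L)
  env <- gen_environment(cfg, seed = 11)
  pts <- gen_cores(cfg, seed = 11)
  sim <- simulate_growth(pts, env, cfg, seed = 11)
  expect_true(all(sim$samples$rate > 0))
  mu <- exp(sim$truth$eta)
  expect_lt(abs(mean(sim$samples$rate) - mean(mu)) / mean(mu), 0.10)
  # depths rewritten to match rate x time within each core
  seg2 <- reconstruct_segments(sim$points)
  seg2 <- seg2[order(seg2$core_uid, seg2$T1_age), ]
  s0 <- sim$samples[order(sim$samples$core_uid, sim$samples$T1_age), ]
  expect_equal(seg2$rate, s0$rate, tolerance = 1e-9)
})

test_that("the near-noise-free limit collapses rates onto exp(b0)", {
  cfg <- scenario_config("default", n_sites = 10L,
                         truth = list(b_slr = 0, co2_bump_amp = 0, age_amp = 0,
                                      spatial_sigma = 1e-4, sd_ocean = 0,
                                      sd_region = 0, sd_locality = 0,
                                      sd_core = 0, shape = 5000))
  sim <- synth_scenario(config = cfg, seed = 13)
  expect_lt(max(abs(sim$samples$rate - exp(cfg$truth$b0))) / exp(cfg$truth$b0),
            0.1)
  expect_lt(abs(mean(sim$samples$rate) - exp(cfg$truth$b0)) / exp(cfg$truth$b0),
            0.01)
})

test_that("doubling the sea-level coefficient doubles its log-scale contribution", {
  cfg1 <- scenario_config("default", n_sites = 10L, truth = list(b_slr = 0.1))
  cfg2 <- scenario_config("default", n_sites = 10L, truth = list(b_slr = 0.2))
  env <- gen_environment(cfg1, seed = 14)
  pts <- gen_cores(cfg1, seed = 14)
  s1 <- simulate_growth(pts, env, cfg1, seed = 14)
  s2 <- simulate_growth(pts, env, cfg2, seed = 14)
  d_eta <- s2$truth$eta - s1$truth$eta
  expect_equal(d_eta, 0.1 * s1$samples$sl_rate, tolerance = 1e-12)
})

test_that("scenario outputs round-trip through the plain-text writers", {
  cfg <- scenario_config("default", n_sites = 8L)
  sim <- synth_scenario(config = cfg, seed = 15)
  dir <- tempfile("simout")
  write_sim(sim, dir)
  expect_true(file.exists(file.path(dir, "points.csv")))
  pts <- read_core_points(file.path(dir, "points.csv"))
  expect_equal(nrow(pts), nrow(sim$points))
  tsi <- read_paleo_series(file.path(dir, "tsi.csv"), native_step = 22)
  expect_equal(tsi$values, sim$env$tsi$values, tolerance = 1e-9)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$b_slr, sim$config$truth$b_slr)
  unlink(dir, recursive = TRUE)
})

test_that("the optimum scenario spans the response surface it encodes", {
  sim <- synth_scenario("optimum", seed = 20)
  d <- sim$samples
  expect_gt(max(d$sst), 28)
  expect_lt(min(d$sst), 23)      # the 25 C optimum is interior
  expect_gt(max(d$sl_rate), 20)  # reaches past the plateau
  expect_true(all(d$rate > 0))
})
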