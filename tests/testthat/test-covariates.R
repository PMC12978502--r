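# Covariate engine: interpolation, segment grids, segment means, SST
# extraction, sea-level rates, volcanic windows, and the collinearity screen.

test_that("interp_at is exact at nodes, linear between, constant outside", {
  s <- paleo_series(c(0, 100, 200), c(10, 20, 5))
  expect_identical(interp_at(s, c(0, 100, 200)), c(10, 20, 5))
  expect_equal(interp_at(s, 50), 15)
  expect_equal(interp_at(s, c(-500, 900)), c(10, 5))   # nearest endpoint
  expect_error(paleo_series(numeric(0), numeric(0)), "empty")
  expect_error(paleo_series(c(1, 1, 2), c(1, 2, 3)), "strictly increasing")
  expect_error(interp_at(s, c(1, NA)), "non-finite")
})

test_that("segment grids step from T1, always include T2, and collapse short segments", {
  expect_identical(segment_grid(0, 44, 22), c(0, 22, 44))
  expect_identical(segment_grid(4000, 4010, 22), c(4000, 4010))
  g <- segment_grid(4000, 4200, 22)
  expect_equal(g[1], 4000)
  expect_equal(g[length(g)], 4200)
  expect_equal(length(g), 11L)            # T1 plus 9 interior steps plus T2
  expect_true(all(diff(g) <= 22 + 1e-12))
  expect_error(segment_grid(10, 10, 5), "exceed")
  expect_error(segment_grid(0, 10, -1), "positive")
})

test_that("segment means reduce correctly for constant and linear series", {
  con <- paleo_series(seq(0, 1000, 50), rep(4.2, 21), native_step = 50)
  expect_equal(sample_mean_series(100, 700, con), 4.2)
  lin <- paleo_series(seq(0, 1000, 10), seq(0, 1000, 10) * 0.3, native_step = 10)
  # symmetric grid over [200, 400] -> mean = value at the midpoint 300
  expect_equal(sample_mean_series(200, 400, lin), 0.3 * 300, tolerance = 1e-12)
})

test_that("segment means match the brute-force oracle on random cases", {
  set.seed(11)
  for (k in 1:60) {
    s <- tiny_series(k, n = sample(10:60, 1), step = sample(c(8, 22, 70), 1),
                     start = runif(1, 0, 2000))
    span <- range(s$ages)
    T1 <- runif(1, span[1] - 300, span[2])
    T2 <- T1 + runif(1, 1, 800)
    expect_equal(sample_mean_series(T1, T2, s),
                 oracle_segment_mean(s$ages, s$values, T1, T2, s$native_step),
                 tolerance = 1e-12)
  }
})

test_that("sample insolation averages annual values over the TSI grid", {
  tsi <- paleo_series(seq(0, 9389, 22), rep(0.5, length(seq(0, 9389, 22))),
                      native_step = 22)
  si <- sample_insolation(6000, 6010, 15, tsi)
  # constant anomaly: mean of the annual values at the two endpoint ages
  direct <- mean(annual_mean_insolation(15, c(6000, 6010), 1365.5))
  expect_equal(si$insolation, direct, tolerance = 1e-10)
  expect_equal(si$tsi, 1365.5)

  # brute-force loop over the age points of a long segment
  set.seed(2)
  tsi2 <- paleo_series(seq(0, 9389, 22), rnorm(length(seq(0, 9389, 22)), 0, 0.4),
                       native_step = 22)
  si2 <- sample_insolation(3000, 3300, -12, tsi2)
  grid <- segment_grid(3000, 3300, 22)
  acc <- 0
  for (g in grid) {
    acc <- acc + annual_mean_insolation(-12, g, 1365 + interp_at(tsi2, g))
  }
  expect_equal(si2$insolation, acc / length(grid), tolerance = 1e-10)
})

test_that("samples partially or wholly outside the TSI record use the stated rules", {
  ages <- seq(0, 9389, 22)
  set.seed(3)
  tsi <- paleo_series(ages, rnorm(length(ages), 0, 0.3), native_step = 22)
  # T1 inside, T2 outside: only in-record age points contribute
  si <- sample_insolation(9300, 9600, 5, tsi)
  grid <- segment_grid(9300, 9600, 22)
  inr <- grid[grid <= max(ages)]
  acc <- 0
  for (g in inr) acc <- acc + annual_mean_insolation(5, g, 1365 + interp_at(tsi, g))
  expect_equal(si$insolation, acc / length(inr), tolerance = 1e-10)
  # wholly outside: nearest-value extrapolation over the full grid
  si2 <- sample_insolation(11000, 11100, 5, tsi)
  expect_equal(si2$tsi, 1365 + tsi$values[length(tsi$values)], tolerance = 1e-12)
})

test_that("SST extraction uses the nearest valid cell and averages the segment", {
  lat <- seq(-5, 5, 1); lon <- seq(100, 110, 1); ages <- seq(0, 2000, 200)
  arr <- array(25, dim = c(11, 11, 11))
  g <- sst_grid(lat, lon, ages, arr)
  # constant-in-time field: the constant, regardless of the segment
  expect_equal(sample_sst(105, 0, 130, 890, g), 25)

  # site on a missing cell: the single valid neighbour wins; check against
  # an exhaustive great-circle scan
  arr2 <- array(NA_real_, dim = c(11, 11, 11))
  arr2[6, 6, ] <- 24 + (0:10) / 10   # only (lat 0, lon 105) holds data
  g2 <- sst_grid(lat, lon, ages, arr2)
  v <- sample_sst(103, 3, 0, 400, g2)
  ser <- 24 + (0:10) / 10
  pts <- c(0, 200, 400)
  expect_equal(v, mean(oracle_interp(ages, ser, pts)), tolerance = 1e-12)

  empty <- suppressWarnings(sst_grid(0:1, 0:1, c(0, 200),
                                     array(NA_real_, c(2, 2, 2))))
  expect_error(sample_sst(1, 1, 0, 100, empty), "no valid")
})

test_that("sub-resolution SST segments reduce to the endpoint mean", {
  lat <- 0:2; lon <- 0:2; ages <- seq(0, 1000, 200)
  arr <- array(rep(20 + (0:5), each = 9), dim = c(3, 3, 6))
  g <- sst_grid(lat, lon, ages, arr)
  v <- sample_sst(1, 1, 250, 350, g)
  expect_equal(v, mean(oracle_interp(ages, 20 + (0:5), c(250, 350))),
               tolerance = 1e-12)
})

test_that("sea-level rate telescopes to the endpoint slope and signs rise as positive", {
  cv <- sea_level_curve("R", seq(0, 11000, 100), seq(0, 11000, 100) * 0.005)
  # +5 m per kyr of age: sea level was rising at 5 mm/yr
  expect_equal(sea_level_rate(2000, 3000, cv), 5, tolerance = 1e-9)
  expect_equal(sea_level_rate(2203.7, 8411.2, cv), 5, tolerance = 1e-9)
  flat <- sea_level_curve("R", c(0, 10000), c(2, 2))
  expect_equal(sea_level_rate(100, 5000, flat), 0)
  # telescoping: the mean annual difference equals the endpoint slope of the
  # integer-year grid for any curve
  set.seed(4)
  ages <- sort(c(0, runif(20, 1, 9999), 10000))
  wavy <- sea_level_curve("R", ages, cumsum(abs(rnorm(length(ages)))) / 50)
  T1 <- 333.4; T2 <- 7801.9
  years <- ceiling(T1):floor(T2)
  s <- interp_at(wavy$series, c(min(years), max(years)))
  expect_equal(sea_level_rate(T1, T2, wavy),
               (s[2] - s[1]) / (max(years) - min(years)) * 1000,
               tolerance = 1e-9)
  # sub-annual segment: endpoint difference
  expect_equal(sea_level_rate(100.2, 100.7, cv), 5, tolerance = 1e-6)
})

test_that("volcanic metric reproduces the closed-form constant case", {
  months <- seq(0.5 / 12, 200, by = 1 / 12)[1:(200 * 12)]
  sa <- saod_record(months, c(-5, 5), matrix(0.02, length(months), 2))
  # 25 W/m2 per unit SAOD * 0.02 = 0.5 W/m2 per year; 20-yr window = 10
  expect_equal(volcanic_metric(0, 30.5, 170.5, sa), 10, tolerance = 1e-9)
  sa0 <- saod_record(months, c(-5, 5), matrix(0, length(months), 2))
  expect_equal(volcanic_metric(12, 10, 190, sa0), 0)
  # segment shorter than the window: a single window of available years
  expect_equal(volcanic_metric(0, 50.2, 60.8, sa), 0.5 * 10, tolerance = 1e-9)
})

test_that("volcanic metric is invariant to the monthly layout at fixed annual means", {
  months <- seq(0.5 / 12, 120, by = 1 / 12)[1:(120 * 12)]
  set.seed(9)
  ann <- runif(120, 0, 0.1)
  flat <- matrix(rep(ann, each = 12), ncol = 1)
  lumpy <- matrix(0, length(months), 1)
  lumpy[seq(1, length(months), 12)] <- ann * 12   # all mass in January
  s1 <- saod_record(months, 0, flat)
  s2 <- saod_record(months, 0, lumpy)
  expect_equal(volcanic_metric(0, 5.5, 110.2, s1),
               volcanic_metric(0, 5.5, 110.2, s2), tolerance = 1e-9)
})

test_that("correlation screen flags collinear pairs and survives zero variance", {
  set.seed(12)
  x <- rnorm(200)
  d <- data.frame(x = x, y = 2 * x + 1, z = rnorm(200), c = rep(1, 200))
  sc <- correlation_screen(d)
  xy <- sc[sc$var1 == "x" & sc$var2 == "y", ]
  expect_true(xy$flagged)
  expect_equal(xy$r, 1)
  expect_true(all(is.na(sc$r[sc$var1 == "c" | sc$var2 == "c"])))
  expect_false(any(sc$flagged[is.na(sc$r)]))
  expect_error(correlation_screen(d[1:2, ]), "at least 3")

  # large-sample independence: no flags
  set.seed(13)
  ind <- data.frame(a = rnorm(1e4), b = rnorm(1e4))
  expect_false(any(correlation_screen(ind)$flagged))

  # absolute latitude against a latitudinally graded SST: flagged
  lats <- runif(300, 0, 30)
  sst <- 28.5 - 0.010 * lats^2 + rnorm(300, sd = 0.3)
  sc2 <- correlation_screen(data.frame(abs_latitude = lats, sst = sst))
  expect_true(all(sc2$flagged))
})
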