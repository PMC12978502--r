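# Growth-record reconstruction, filtering, and regional trends.

make_core <- function(study, core, ages, depths, region = "Asia") {
  data.frame(study = study, core = core, lon = 115, lat = 12,
             region = region, ocean = "Pacific", locality = "SiteX",
             reef_zone = "reef crest", age_ybp = ages, depth_mm = depths)
}

test_that("core uids concatenate study and core and stay injective", {
  expect_equal(build_core_uid("SmithEtAl", "C-1"), "SmithEtAl::C-1")
  expect_false(build_core_uid("StudyA", "P8") == build_core_uid("StudyB", "P8"))
  expect_error(build_core_uid("A", " "), "empty")
  expect_error(build_core_uid("AB", ""), "empty")
  # trimming happens before concatenation
  expect_equal(build_core_uid(" A ", "B"), "A::B")
})

test_that("read_core_points validates schema, ages and age-depth monotonicity", {
  ok <- make_core("S", "C1", c(1000, 2000, 3000), c(100, 600, 900))
  expect_silent(pts <- read_core_points(ok))
  expect_true("core_uid" %in% names(pts))

  bad <- make_core("S", "C2", c(1000, 3000, 2000), c(100, 600, 900))
  expect_error(read_core_points(bad), "monotonicity")
  expect_error(read_core_points(bad), "S::C2")

  young <- make_core("S", "C3", c(-150, 100), c(0, 100))
  expect_error(read_core_points(young), "floor")

  renamed <- ok
  names(renamed)[names(renamed) == "age_ybp"] <- "CalAge"
  expect_silent(read_core_points(renamed, mapping = c(age_ybp = "CalAge")))
  expect_error(read_core_points(ok[, -1]), "missing column")
})

test_that("segment reconstruction follows the shared-boundary rule", {
  one <- reconstruct_segments(make_core("S", "C", c(4000, 5000), c(1500, 2000)))
  expect_equal(nrow(one), 1L)
  expect_equal(one$rate, 0.5)
  expect_equal(one$mean_age, 4500)
  expect_equal(one$segment_years, 1000)

  three <- reconstruct_segments(make_core("S", "C", c(1000, 2500, 4000),
                                          c(0, 900, 1800)))
  expect_equal(nrow(three), 2L)
  expect_equal(three$T2_age[1], three$T1_age[2])  # middle date shared

  ages26 <- sort(runif(26, 0, 11000))
  d26 <- make_core("S", "C26", ages26, cumsum(c(0, diff(ages26) * 2)))
  expect_equal(nrow(reconstruct_segments(d26)), 25L)
})

test_that("tied ages are skipped with a warning, not an error", {
  tied <- make_core("S", "CT", c(1000, 1000, 3000), c(0, 200, 900))
  expect_warning(seg <- reconstruct_segments(tied), "tied")
  expect_equal(nrow(seg), 1L)
})

test_that("segment depths conserve the core's total depth span", {
  set.seed(42)
  for (k in 1:20) {
    n <- sample(3:15, 1)
    ages <- sort(runif(n, 0, 11000))
    depths <- cumsum(c(runif(1, 0, 100), diff(ages) * runif(n - 1, 0.3, 5)))
    seg <- reconstruct_segments(make_core("S", paste0("K", k), ages, depths))
    expect_identical(sum(seg$segment_mm), max(depths) - min(depths))
    expect_equal(nrow(seg), n - 1L)
  }
})

test_that("the Holocene age filter keeps the boundary and preserves order", {
  seg <- reconstruct_segments(make_core("S", "C",
                                        c(10000, 11700, 11701, 12500),
                                        c(0, 1000, 1001, 1600)))
  kept <- filter_max_age(seg)
  expect_equal(kept$T2_age, 11700)          # 11700 retained, 11701+ removed
  expect_identical(kept, seg[seg$T2_age <= 11700, ])
})

test_that("percentile filter matches the sort-based oracle and is idempotent", {
  set.seed(7)
  for (k in 1:1000) {
    n <- sample(10:80, 1)
    rates <- if (k %% 3 == 0) rlnorm(n, 0, 1) else runif(n, 0, 50)
    d <- data.frame(rate = rates, T2_age = runif(n, 0, 11000))
    keep <- oracle_percentile_keep(rates)
    expect_identical(percentile_filter(d)$rate, rates[keep])
  }
  # degenerate distribution: nothing removed
  d0 <- data.frame(rate = rep(3.3, 25))
  expect_equal(nrow(percentile_filter(d0)), 25L)
  # pipeline stability: deterministic, and the age filter has nothing left
  # to remove after the pipeline; a second percentile pass trims at most
  # the nominal tail mass of the already-trimmed set
  set.seed(8)
  d <- data.frame(rate = rlnorm(400), T2_age = runif(400, 0, 13000))
  once <- percentile_filter(filter_max_age(d))
  expect_identical(percentile_filter(filter_max_age(d)), once)
  expect_identical(filter_max_age(once), once)
  expect_gte(nrow(percentile_filter(once)), ceiling(0.965 * nrow(once)))
  expect_error(percentile_filter(d, total_mass = 1.2), "inside")
  expect_error(percentile_filter(d[1:5, , drop = FALSE]), "at least 10")
})

test_that("regional LOESS trend is exact on lines and flat on constants", {
  set.seed(1)
  ages <- runif(60, 500, 9000)
  lin <- data.frame(mean_age = ages, rate = 2 + 0.0004 * ages)
  tr <- regional_trend(lin)
  expect_lt(max(abs(tr$rate - (2 + 0.0004 * tr$mean_age))), 1e-8)

  flat <- data.frame(mean_age = ages, rate = rep(1.7, 60))
  tr2 <- regional_trend(flat)
  expect_lt(max(abs(tr2$rate - 1.7)), 1e-8)

  expect_error(regional_trend(lin[1:9, ]), "fewer than 10")
})

test_that("a bimodal regional mean function yields two recovered peaks", {
  set.seed(3)
  ages <- runif(800, 0, 11000)
  mu <- 1 + exp(-((ages - 3000) / 600)^2) + exp(-((ages - 8000) / 600)^2)
  d <- data.frame(mean_age = ages, rate = mu + rnorm(800, sd = 0.01))
  tr <- regional_trend(d, span = 0.25, n_grid = 100)
  pk <- local_maxima(tr$rate)
  pk <- pk[order(tr$rate[pk], decreasing = TRUE)]
  # the two most prominent, well-separated maxima
  sel <- pk[1]
  for (p in pk[-1]) {
    if (abs(tr$mean_age[p] - tr$mean_age[sel[1]]) > 2000) { sel <- c(sel, p); break }
  }
  peaks <- sort(tr$mean_age[sel])
  step <- diff(tr$mean_age[1:2])
  expect_equal(length(peaks), 2L)
  # one grid step, plus the half-step offset of the grid against the truth
  expect_lt(abs(peaks[1] - 3000), 1.25 * step)
  expect_lt(abs(peaks[2] - 8000), 1.25 * step)
})

test_that("regional_trends excludes Barbados and sparse regions from reporting", {
  set.seed(5)
  d <- data.frame(mean_age = runif(80, 0, 9000), rate = rlnorm(80),
                  region = rep(c("Asia", "Barbados", "Red Sea"), c(60, 15, 5)))
  trs <- regional_trends(d)
  expect_true("Asia" %in% names(trs))
  expect_false("Barbados" %in% names(trs))   # reported trends only
  expect_false("Red Sea" %in% names(trs))    # below the minimum sample count
})
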