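# Independent brute-force oracles used across test files. These deliberately
# re-derive each quantity with plain loops and sort-based logic, sharing no
# code with the package implementations they check.

# Two-tailed percentile filter by explicit sort-and-index quantiles
# (linear interpolation between order statistics, as documented).
oracle_percentile_keep <- function(rates, total_mass = 0.97) {
  a <- (1 - total_mass) / 2
  s <- sort(rates)
  n <- length(s)
  qq <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  lo <- qq(a); hi <- qq(1 - a)
  rates >= lo & rates <= hi
}

# Piecewise-linear interpolation with nearest-endpoint extrapolation.
oracle_interp <- function(ages, values, q) {
  out <- numeric(length(q))
  for (k in seq_along(q)) {
    x <- q[k]
    if (x <= ages[1]) { out[k] <- values[1]; next }
    if (x >= ages[length(ages)]) { out[k] <- values[length(values)]; next }
    i <- max(which(ages <= x))
    if (ages[i] == x) { out[k] <- values[i]; next }
    w <- (x - ages[i]) / (ages[i + 1] - ages[i])
    out[k] <- (1 - w) * values[i] + w * values[i + 1]
  }
  out
}

# Segment mean of a series on the native-step grid, loop form.
oracle_segment_mean <- function(ages, values, T1, T2, step) {
  g <- T1
  grid <- c()
  while (g <= T2) { grid <- c(grid, g); g <- g + step }
  if (grid[length(grid)] < T2) grid <- c(grid, T2)
  if (T2 - T1 < step) grid <- c(T1, T2)
  inr <- grid[grid >= ages[1] & grid <= ages[length(ages)]]
  if (length(inr) == 0) inr <- grid
  tot <- 0
  for (x in inr) tot <- tot + oracle_interp(ages, values, x)
  tot / length(inr)
}

# Mean year-to-year difference of the interpolated submergence, loop form.
oracle_sl_rate <- function(ages, sub_m, T1, T2) {
  years <- ceiling(T1):floor(T2)
  if (length(years) < 2) {
    s <- oracle_interp(ages, sub_m, c(T1, T2))
    return((s[2] - s[1]) / (T2 - T1) * 1000)
  }
  s <- oracle_interp(ages, sub_m, years)
  d <- 0
  for (i in 2:length(s)) d <- d + (s[i] - s[i - 1])
  d / (length(s) - 1) * 1000
}

# Rolling 20-yr cumulative volcanic forcing, fully nested-loop form.
oracle_volc <- function(month_ages, band_centers, saod_mat, latitude, T1, T2,
                        window = 20, scale = 25) {
  yr <- floor(month_ages)
  uy <- sort(unique(yr))
  ann <- matrix(NA_real_, length(uy), length(band_centers))
  for (j in seq_along(band_centers)) {
    for (i in seq_along(uy)) ann[i, j] <- mean(saod_mat[yr == uy[i], j])
  }
  lat_c <- min(max(band_centers), max(min(band_centers), latitude))
  at_site <- numeric(length(uy))
  for (i in seq_along(uy)) {
    j <- max(which(band_centers <= lat_c)); j <- min(j, length(band_centers) - 1)
    w <- (lat_c - band_centers[j]) / (band_centers[j + 1] - band_centers[j])
    at_site[i] <- (1 - w) * ann[i, j] + w * ann[i, j + 1]
  }
  years <- ceiling(T1):floor(T2)
  f <- oracle_interp(uy, at_site * scale, years)
  n <- length(f)
  if (n < window) return(sum(f))
  sums <- c()
  for (s in 1:(n - window + 1)) sums <- c(sums, sum(f[s:(s + window - 1)]))
  mean(sums)
}

# A small, quick synthetic environment + segment set for covariate tests.
tiny_series <- function(seed, n = 40, step = 20, start = 0) {
  set.seed(seed)
  paleo_series(start + (0:(n - 1)) * step, rnorm(n), native_step = step)
}

# indices of strict interior local maxima of a vector
local_maxima <- function(v) which(diff(sign(diff(v))) == -2) + 1L
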