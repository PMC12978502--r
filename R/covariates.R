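# Covariate engine: turns irregular paleo proxy records, a gridded SST
# reconstruction, and regional sea-level curves into one covariate vector
# per growth sample.

#' Construct a paleo proxy series
#'
#' @param ages strictly increasing ages in years BP.
#' @param values finite numeric values, one per age.
#' @param units unit label (free text).
#' @param native_step native temporal resolution in years (used as the
#'   default segment-grid step; e.g. 22 for the solar-irradiance record, 8
#'   for CO2, 70 for ice-rafted debris).
#' @return An object of class `paleo_series`.
#' @export
paleo_series <- function(ages, values, units = "", native_step = NULL) {
  ages <- as.numeric(ages); values <- as.numeric(values)
  if (length(ages) == 0L) stop_fmt("empty paleo series")
  if (length(ages) != length(values)) stop_fmt("ages and values differ in length")
  if (any(!is.finite(ages)) || any(!is.finite(values))) stop_fmt("non-finite entries in paleo series")
  if (is.unsorted(ages, strictly = TRUE)) stop_fmt("ages must be strictly increasing (no duplicates)")
  structure(list(ages = ages, values = values, units = units,
                 native_step = native_step), class = "paleo_series")
}

#' Read a two-column age/value CSV into a paleo series
#'
#' Expects columns `age_ybp` and `value`; lines starting with `#` are
#' treated as a units/provenance header.
#'
#' @param path CSV path.
#' @param units,native_step see [paleo_series()].
#' @return A `paleo_series`.
#' @export
read_paleo_series <- function(path, units = "", native_step = NULL) {
  d <- read.csv(path, comment.char = "#")
  d <- d[order(d$age_ybp), ]
  paleo_series(d$age_ybp, d$value, units = units, native_step = native_step)
}

#' Interpolate a paleo series at query ages
#'
#' Piecewise-linear inside the record (linear interpolation weighted by
#' temporal distance), constant nearest-endpoint extrapolation outside, and
#' exact at the record's own ages.
#'
#' @param series a `paleo_series`.
#' @param query_ages finite numeric ages in years BP.
#' @return Interpolated values.
#' @export
interp_at <- function(series, query_ages) {
  stopifnot(inherits(series, "paleo_series"))
  if (any(!is.finite(query_ages))) stop_fmt("non-finite query ages")
  if (length(series$ages) == 1L) return(rep(series$values, length(query_ages)))
  approx(series$ages, series$values, xout = query_ages, rule = 2)$y
}

#' Age grid spanning a core segment
#'
#' Ages `T1, T1 + step, ...` capped at `T2`, with `T2` always included; a
#' segment shorter than one step reduces to its two endpoints.
#'
#' @param T1,T2 younger and older segment bounds in years BP (`T2 > T1`).
#' @param step grid step in years (> 0).
#' @return Increasing vector of ages from `T1` to `T2`.
#' @export
#' @examples
#' segment_grid(0, 44, 22)      # 0, 22, 44
#' segment_grid(4000, 4010, 22) # endpoints only
segment_grid <- function(T1, T2, step) {
  stopifnot(is_one_number(T1), is_one_number(T2), is_one_number(step))
  if (T2 <= T1) stop_fmt("T2 must exceed T1")
  if (step <= 0) stop_fmt("step must be positive")
  if (T2 - T1 < step) return(c(T1, T2))
  g <- seq(T1, T2, by = step)
  if (tail(g, 1L) < T2) g <- c(g, T2)
  g
}

# Ages of the segment grid restricted to the record's span; empty when the
# segment lies wholly outside the record (callers then fall back to
# nearest-value extrapolation over the full grid).
.in_record <- function(grid, series) {
  grid[grid >= min(series$ages) & grid <= max(series$ages)]
}

#' Sample-level mean of a proxy series over a core segment
#'
#' Interpolates the series on the segment age grid at the record's native
#' step and averages. Grids partially overlapping the record use only the
#' in-record age points; segments wholly outside the record use
#' nearest-value extrapolation over the full grid.
#'
#' @param T1,T2 segment bounds in years BP.
#' @param series a `paleo_series` with a `native_step`.
#' @param step grid step; defaults to `series$native_step`.
#' @return Mean interpolated value over the segment.
#' @export
sample_mean_series <- function(T1, T2, series, step = series$native_step) {
  if (is.null(step)) stop_fmt("series has no native_step and no step was given")
  grid <- segment_grid(T1, T2, step)
  use <- .in_record(grid, series)
  if (length(use) == 0L) use <- grid
  mean(interp_at(series, use))
}

#' Sample-level mean annual insolation over a core segment
#'
#' Interpolates total solar irradiance on the segment grid at the TSI
#' record's native step (22 years by default), converts each age point's TSI
#' anomaly to an absolute value against 1365 W/m^2, evaluates the annual-mean
#' insolation at the site latitude for each age point, and averages.
#'
#' @param T1,T2 segment bounds in years BP.
#' @param latitude site latitude in degrees north.
#' @param tsi_series `paleo_series` of TSI anomalies (W/m^2 relative to
#'   1365).
#' @param tsi_reference reference irradiance added to the anomaly (1365).
#' @return List with `insolation` (mean annual insolation, W/m^2) and `tsi`
#'   (mean absolute TSI, W/m^2) over the segment.
#' @export
sample_insolation <- function(T1, T2, latitude, tsi_series, tsi_reference = 1365) {
  step <- tsi_series$native_step %||% 22
  grid <- segment_grid(T1, T2, step)
  use <- .in_record(grid, tsi_series)
  if (length(use) == 0L) use <- grid
  tsi_abs <- tsi_reference + interp_at(tsi_series, use)
  ins <- annual_mean_insolation(latitude, use, tsi_abs)
  list(insolation = mean(ins), tsi = mean(tsi_abs))
}

#' Construct a gridded SST reconstruction
#'
#' @param lat,lon grid-cell centre vectors (degrees), increasing.
#' @param ages time steps in years BP, increasing (native resolution of the
#'   emulated reconstruction is 200 years).
#' @param sst array `[lat, lon, age]` in degrees C, `NA` for missing cells.
#' @return An object of class `sst_grid`.
#' @export
sst_grid <- function(lat, lon, ages, sst) {
  stopifnot(length(dim(sst)) == 3L,
            dim(sst)[1] == length(lat), dim(sst)[2] == length(lon),
            dim(sst)[3] == length(ages))
  rng <- range(sst, na.rm = TRUE)
  if (rng[1] < -5 || rng[2] > 40) stop_fmt("SST values outside [-5, 40] C")
  structure(list(lat = lat, lon = lon, ages = ages, sst = sst,
                 cache = new.env(parent = emptyenv())),
            class = "sst_grid")
}

#' Read a long-format SST CSV into an [sst_grid()]
#'
#' Expects columns `lat, lon, age_ybp, sst` (one row per cell and time step;
#' missing cells may simply be absent or carry NA).
#'
#' @param path CSV path.
#' @return An `sst_grid`.
#' @export
read_sst_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  lat <- sort(unique(d$lat)); lon <- sort(unique(d$lon)); ages <- sort(unique(d$age_ybp))
  arr <- array(NA_real_, dim = c(length(lat), length(lon), length(ages)))
  arr[cbind(match(d$lat, lat), match(d$lon, lon), match(d$age_ybp, ages))] <- d$sst
  sst_grid(lat, lon, ages, arr)
}

# Cells with at least one non-missing time step, with their coordinates
# (computed once per grid and cached).
.valid_cells <- function(grid) {
  vc <- get0("valid_cells", envir = grid$cache)
  if (!is.null(vc)) return(vc)
  any_valid <- apply(!is.na(grid$sst), c(1, 2), any)
  idx <- which(any_valid, arr.ind = TRUE)
  vc <- list(idx = idx, lon = grid$lon[idx[, 2]], lat = grid$lat[idx[, 1]])
  assign("valid_cells", vc, envir = grid$cache)
  vc
}

#' Sample-level mean SST over a core segment
#'
#' Maps the site to the nearest grid cell holding data (great-circle
#' distance over all valid cells), then averages that cell's time series
#' over the segment: native time steps clipped to `[T1, T2]` plus linearly
#' interpolated endpoint values. Sub-resolution segments reduce to the mean
#' of the two interpolated endpoints.
#'
#' @param lon,lat site coordinates in degrees.
#' @param T1,T2 segment bounds in years BP.
#' @param grid an [sst_grid()].
#' @return Mean SST over the segment in degrees C.
#' @export
sample_sst <- function(lon, lat, T1, T2, grid) {
  stopifnot(inherits(grid, "sst_grid"))
  vc <- .valid_cells(grid)
  if (nrow(vc$idx) == 0L) stop_fmt("SST grid has no valid cells")
  d <- geosphere::distHaversine(c(lon, lat), cbind(vc$lon, vc$lat))
  k <- which.min(d)
  series_vals <- grid$sst[vc$idx[k, 1], vc$idx[k, 2], ]
  ok <- is.finite(series_vals)
  ser <- paleo_series(grid$ages[ok], series_vals[ok], units = "degC")
  native <- grid$ages[ok]
  inner <- native[native > T1 & native < T2]
  pts <- c(T1, inner, T2)
  use <- .in_record(pts, ser)
  if (length(use) == 0L) use <- pts
  mean(interp_at(ser, use))
}

#' Construct a regional relative sea-level curve
#'
#' Submergence is the sign-inverted relative sea level: positive values mean
#' deeper reef submergence, so a positive rate of change corresponds to
#' rising sea level.
#'
#' @param region region label.
#' @param ages strictly increasing ages in years BP.
#' @param submergence_m submergence in metres (positive = deeper).
#' @return An object of class `sea_level_curve`.
#' @export
sea_level_curve <- function(region, ages, submergence_m) {
  ages <- as.numeric(ages); submergence_m <- as.numeric(submergence_m)
  if (is.unsorted(ages, strictly = TRUE)) stop_fmt("sea-level ages must be strictly increasing")
  structure(list(region = region,
                 series = paleo_series(ages, submergence_m, units = "m")),
            class = "sea_level_curve")
}

#' Mean rate of sea-level change over a core segment
#'
#' Submergence is interpolated at every integer calendar year between
#' `ceiling(T1)` and `floor(T2)` (nearest-value extension beyond the curve),
#' and the rate is the mean of the year-to-year differences, converted to
#' mm/yr. Positive rates mean rising sea level. For sub-annual segments (or
#' a year grid with fewer than two points) the endpoint difference is used.
#'
#' @param T1,T2 segment bounds in years BP.
#' @param curve a [sea_level_curve()].
#' @return Rate of sea-level change in mm/yr.
#' @export
sea_level_rate <- function(T1, T2, curve) {
  stopifnot(inherits(curve, "sea_level_curve"))
  if (T2 <= T1) stop_fmt("T2 must exceed T1")
  years <- if (ceiling(T1) > floor(T2)) numeric(0) else seq(ceiling(T1), floor(T2), by = 1)
  if (length(years) < 2L) {
    s <- interp_at(curve$series, c(T1, T2))
    return((s[2] - s[1]) / (T2 - T1) * 1000)
  }
  s <- interp_at(curve$series, years)
  mean(diff(s)) * 1000
}

#' Construct a stratospheric aerosol optical depth record
#'
#' Monthly SAOD (dimensionless, 550 nm) resolved in 10-degree latitude
#' bands.
#'
#' @param ages monthly ages in years BP (decimal years; month m of calendar
#'   year y is `y + (m - 0.5)/12`), increasing.
#' @param band_centers latitude band centres in degrees.
#' @param saod matrix `[time, band]`, non-negative.
#' @return An object of class `saod_record`.
#' @export
saod_record <- function(ages, band_centers, saod) {
  saod <- as.matrix(saod)
  stopifnot(nrow(saod) == length(ages), ncol(saod) == length(band_centers))
  if (any(saod < 0)) stop_fmt("SAOD must be non-negative")
  if (is.unsorted(ages)) stop_fmt("SAOD ages must be increasing")
  structure(list(ages = ages, band_centers = band_centers, saod = saod,
                 cache = new.env(parent = emptyenv())),
            class = "saod_record")
}

#' Read a long-format SAOD CSV
#'
#' Expects columns `age_ybp, lat_band, saod`.
#'
#' @param path CSV path.
#' @return A [saod_record()].
#' @export
read_saod_csv <- function(path) {
  d <- read.csv(path, comment.char = "#")
  ages <- sort(unique(d$age_ybp)); bands <- sort(unique(d$lat_band))
  m <- matrix(0, length(ages), length(bands))
  m[cbind(match(d$age_ybp, ages), match(d$lat_band, bands))] <- d$saod
  saod_record(ages, bands, m)
}

# Annual SAOD per band (monthly values aggregated to calendar-year means;
# computed once per record and cached), then linearly interpolated between
# the two flanking band centres (clamped at the outermost bands).
.annual_saod_bands <- function(saod) {
  ann <- get0("annual_bands", envir = saod$cache)
  if (!is.null(ann)) return(ann)
  yr <- floor(saod$ages)
  uy <- sort(unique(yr))
  g <- match(yr, uy)
  cnt <- tabulate(g, nbins = length(uy))
  m <- apply(saod$saod, 2, function(col) {
    rowsum(col, g, reorder = TRUE)[, 1] / cnt
  })
  ann <- list(years = uy, saod = matrix(m, nrow = length(uy)))
  assign("annual_bands", ann, envir = saod$cache)
  ann
}

.annual_saod_at <- function(saod, latitude) {
  ann <- .annual_saod_bands(saod)
  bands <- saod$band_centers
  if (length(bands) == 1L) {
    at_site <- ann$saod[, 1]
  } else {
    lat_c <- pmin(max(bands), pmax(min(bands), latitude))
    j <- findInterval(lat_c, bands, all.inside = TRUE)
    w <- (lat_c - bands[j]) / (bands[j + 1] - bands[j])
    at_site <- (1 - w) * ann$saod[, j] + w * ann$saod[, j + 1]
  }
  list(years = ann$years, saod = at_site)
}

#' Rolling cumulative volcanic forcing over a core segment
#'
#' Monthly SAOD is aggregated to annual means, interpolated across latitude
#' bands to the site latitude, and scaled to radiative forcing at 25 W/m^2
#' per unit SAOD. Annual forcings are summed over 20-year windows at a
#' one-year stride lying fully inside the segment, and the sample-level
#' metric is the mean of the window sums. Segments shorter than the window
#' use a single window of all available years.
#'
#' @param latitude site latitude in degrees.
#' @param T1,T2 segment bounds in years BP.
#' @param saod a [saod_record()].
#' @param window window length in years (default 20).
#' @param scale forcing per unit SAOD in W/m^2 (default 25).
#' @return Mean 20-year cumulative volcanic forcing in W/m^2 (non-negative).
#' @export
volcanic_metric <- function(latitude, T1, T2, saod, window = 20L, scale = 25) {
  stopifnot(inherits(saod, "saod_record"))
  if (T2 <= T1) stop_fmt("T2 must exceed T1")
  ann <- .annual_saod_at(saod, latitude)
  years <- seq(ceiling(T1), floor(T2), by = 1)
  if (length(years) == 0L) years <- round((T1 + T2) / 2)
  ser <- paleo_series(ann$years, ann$saod * scale, units = "W/m2")
  forcing <- interp_at(ser, years)
  n <- length(forcing)
  if (n < window) return(sum(forcing))
  cs <- cumsum(c(0, forcing))
  sums <- cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]
  mean(sums)
}

#' Screen covariates for collinearity
#'
#' Pairwise Pearson correlations on complete cases; pairs exceeding the
#' threshold in absolute value are flagged for exclusion decisions.
#' Zero-variance columns yield undefined (NA) correlations, reported but
#' never flagged.
#'
#' @param covariates data frame of numeric covariates (at least 3 rows).
#' @param threshold absolute-correlation threshold (default 0.7).
#' @return Data frame with columns `var1`, `var2`, `r`, `flagged`.
#' @export
correlation_screen <- function(covariates, threshold = 0.7) {
  covariates <- as.data.frame(covariates)
  num <- covariates[vapply(covariates, is.numeric, logical(1))]
  if (nrow(num) < 3L) stop_fmt("need at least 3 rows to screen correlations")
  cc <- num[complete.cases(num), , drop = FALSE]
  r <- suppressWarnings(cor(cc))
  nm <- colnames(r)
  pairs <- which(upper.tri(r), arr.ind = TRUE)
  out <- data.frame(var1 = nm[pairs[, 1]], var2 = nm[pairs[, 2]],
                    r = r[pairs])
  out$flagged <- !is.na(out$r) & abs(out$r) > threshold
  out
}

#' Build the full covariate vector for every growth sample
#'
#' Applies the per-sample interpolation and windowing rules of each covariate
#' to a table of growth samples: mean annual insolation and mean absolute
#' TSI, mean CO2, mean ice-rafted debris, mean SST from the nearest valid
#' grid cell, mean rate of sea-level change from the sample's regional curve,
#' and the rolling cumulative volcanic forcing. Also adds `abs_latitude`.
#'
#' @param samples growth-sample data frame (needs `T1_age`, `T2_age`, `lon`,
#'   `lat`, `region`).
#' @param env list with elements `tsi`, `co2`, `ird` (each a
#'   [paleo_series()]), `saod` (a [saod_record()]), `sst` (an [sst_grid()]),
#'   and `sealevel` (named list of [sea_level_curve()] keyed by region).
#' @return `samples` with covariate columns appended (`insolation`, `tsi`,
#'   `co2`, `ird`, `sst`, `sl_rate`, `volc`, `abs_latitude`), all finite.
#' @export
build_covariates <- function(samples, env) {
  n <- nrow(samples)
  ins <- tsi <- co2 <- ird <- sstv <- slr <- volc <- numeric(n)
  for (i in seq_len(n)) {
    T1 <- samples$T1_age[i]; T2 <- samples$T2_age[i]
    si <- sample_insolation(T1, T2, samples$lat[i], env$tsi)
    ins[i] <- si$insolation; tsi[i] <- si$tsi
    co2[i] <- sample_mean_series(T1, T2, env$co2)
    ird[i] <- sample_mean_series(T1, T2, env$ird)
    sstv[i] <- sample_sst(samples$lon[i], samples$lat[i], T1, T2, env$sst)
    curve <- env$sealevel[[samples$region[i]]]
    if (is.null(curve)) stop_fmt("no sea-level curve for region '%s'", samples$region[i])
    slr[i] <- sea_level_rate(T1, T2, curve)
    volc[i] <- volcanic_metric(samples$lat[i], T1, T2, env$saod)
  }
  out <- cbind(samples,
               data.frame(insolation = ins, tsi = tsi, co2 = co2, ird = ird,
                          sst = sstv, sl_rate = slr, volc = volc,
                          abs_latitude = abs(samples$lat)))
  bad <- !stats::complete.cases(out[, c("insolation", "tsi", "co2", "ird",
                                        "sst", "sl_rate", "volc")])
  if (any(bad)) stop_fmt("non-finite covariates for sample row(s): %s",
                         paste(which(bad), collapse = ", "))
  out
}
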