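# Reef-core growth record: dated points, segment reconstruction, filters,
# and regional LOESS trends.

CORE_POINT_COLUMNS <- c("study", "core", "lon", "lat", "region", "ocean",
                        "locality", "reef_zone", "age_ybp", "depth_mm")

#' Build a unique core identifier
#'
#' Core names repeat across studies, so samples are linked to cores by a
#' study::core concatenation with a reserved separator.
#'
#' @param study_name,core_name character vectors (recycled); must be
#'   non-empty after whitespace trimming.
#' @return Character vector of core uids.
#' @export
#' @examples
#' build_core_uid("SmithEtAl", "C-1")
build_core_uid <- function(study_name, core_name) {
  study_name <- trimws(as.character(study_name))
  core_name <- trimws(as.character(core_name))
  bad <- !nzchar(study_name) | !nzchar(core_name) |
    is.na(study_name) | is.na(core_name)
  if (any(bad)) {
    stop_fmt("empty study or core name in record(s): %s",
             paste(which(bad), collapse = ", "))
  }
  paste0(study_name, "::", core_name)
}

#' Read and validate dated core points
#'
#' Accepts a CSV path or a data frame with columns `study, core, lon, lat,
#' region, ocean, locality, reef_zone, age_ybp, depth_mm` (one row per dated
#' point; ages in calibrated years BP, depths in mm increasing downward).
#' Within each core, sorting by depth must sort ages non-decreasingly;
#' violations are rejected at read time. An optional `mapping` renames
#' externally-named columns onto this schema.
#'
#' @param x CSV path or data frame.
#' @param mapping optional named character vector, `c(schema_name = external_name)`.
#' @param age_floor minimum admissible age in years BP (default -100,
#'   i.e. nothing younger than 2050 CE).
#' @return The validated data frame with an added `core_uid` column.
#' @export
read_core_points <- function(x, mapping = NULL, age_floor = -100) {
  pts <- if (is.character(x)) read.csv(x, comment.char = "#") else as.data.frame(x)
  if (!is.null(mapping)) {
    for (nm in names(mapping)) {
      if (!mapping[[nm]] %in% names(pts)) {
        stop_fmt("mapped column '%s' not found in input", mapping[[nm]])
      }
      names(pts)[names(pts) == mapping[[nm]]] <- nm
    }
  }
  missing_cols <- setdiff(CORE_POINT_COLUMNS, names(pts))
  if (length(missing_cols)) {
    stop_fmt("missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(pts$age_ybp)) || any(!is.finite(pts$depth_mm))) {
    stop_fmt("non-finite age or depth values")
  }
  if (any(pts$age_ybp < age_floor)) {
    stop_fmt("age below the admissible floor (%g yr BP) in row(s): %s",
             age_floor, paste(which(pts$age_ybp < age_floor), collapse = ", "))
  }
  if (any(pts$lon < -180 | pts$lon > 180) || any(abs(pts$lat) > 90)) {
    stop_fmt("coordinates outside valid ranges")
  }
  pts$core_uid <- build_core_uid(pts$study, pts$core)
  for (uid in unique(pts$core_uid)) {
    sub <- pts[pts$core_uid == uid, ]
    ord <- order(sub$depth_mm)
    if (is.unsorted(sub$age_ybp[ord])) {
      stop_fmt("core '%s' violates age-depth monotonicity", uid)
    }
  }
  pts
}

#' Reconstruct growth-rate segments within cores
#'
#' Within each core, consecutive dated points bound a segment: the deeper,
#' older date serves as T2 and the shallower, younger one as T1; the T2 of
#' one segment is the T1 of the next. The segment growth rate is the depth
#' difference divided by the age difference. Pairs with tied ages are skipped
#' with a warning (the rate is undefined) rather than discarding the core.
#'
#' @param points data frame of dated points as returned by
#'   [read_core_points()] (a `core_uid` column is added if absent). Cores
#'   with fewer than two points contribute no samples.
#' @return A data frame of growth samples with columns `core_uid`, `T1_age`,
#'   `T2_age`, `segment_mm`, `segment_years`, `rate` (mm/yr), `mean_age`, and
#'   the site columns carried from the core.
#' @export
reconstruct_segments <- function(points) {
  points <- as.data.frame(points)
  if (is.null(points$core_uid)) points$core_uid <- build_core_uid(points$study, points$core)
  carry <- intersect(c("study", "core", "lon", "lat", "region", "ocean",
                       "locality", "reef_zone"), names(points))
  out <- vector("list", length(unique(points$core_uid)))
  names(out) <- unique(points$core_uid)
  n_tied <- 0L
  for (uid in names(out)) {
    sub <- points[points$core_uid == uid, , drop = FALSE]
    if (nrow(sub) < 2L) next
    sub <- sub[order(sub$depth_mm, sub$age_ybp), , drop = FALSE]
    i1 <- seq_len(nrow(sub) - 1L)
    dt <- sub$age_ybp[i1 + 1L] - sub$age_ybp[i1]
    dz <- sub$depth_mm[i1 + 1L] - sub$depth_mm[i1]
    keep <- dt > 0
    n_tied <- n_tied + sum(!keep)
    if (!any(keep)) next
    seg <- data.frame(
      core_uid = uid,
      T1_age = sub$age_ybp[i1][keep],
      T2_age = sub$age_ybp[i1 + 1L][keep],
      segment_mm = dz[keep],
      segment_years = dt[keep],
      rate = dz[keep] / dt[keep],
      mean_age = (sub$age_ybp[i1][keep] + sub$age_ybp[i1 + 1L][keep]) / 2
    )
    for (cc in carry) seg[[cc]] <- sub[[cc]][1L]
    out[[uid]] <- seg
  }
  if (n_tied > 0L) {
    warning(sprintf("skipped %d segment(s) with tied ages (rate undefined)", n_tied),
            call. = FALSE)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    stop_fmt("no reconstructable segments (every core has <2 usable points)")
  }
  rownames(res) <- NULL
  res
}

#' Drop samples older than the Holocene boundary
#'
#' Removes samples whose older bound (T2) exceeds `max_age`; the boundary
#' itself is retained.
#'
#' @param samples growth-sample data frame from [reconstruct_segments()].
#' @param max_age maximum admissible T2 age in years BP (default 11,700, the
#'   start of the Holocene).
#' @return The retained samples, in the original order.
#' @export
filter_max_age <- function(samples, max_age = 11700) {
  stopifnot(is_one_number(max_age))
  samples[samples$T2_age <= max_age, , drop = FALSE]
}

#' Two-tailed percentile filter on growth rates
#'
#' Retains the central `total_mass` of the pooled growth-rate distribution,
#' cutting `(1 - total_mass)/2` from each tail. Quantiles use the default
#' linear-interpolation estimator (type 7), so retained counts are
#' reproducible bit-for-bit; samples strictly below the lower or strictly
#' above the upper quantile are removed.
#'
#' @param samples growth-sample data frame (at least 10 rows).
#' @param total_mass central probability mass to retain, in (0, 1);
#'   default 0.97.
#' @return The retained samples, order preserved.
#' @export
percentile_filter <- function(samples, total_mass = 0.97) {
  if (!is_one_number(total_mass) || total_mass <= 0 || total_mass >= 1) {
    stop_fmt("total_mass must lie strictly inside (0, 1)")
  }
  if (nrow(samples) < 10L) stop_fmt("need at least 10 samples for the percentile filter")
  a <- (1 - total_mass) / 2
  q <- quantile(samples$rate, probs = c(a, 1 - a), type = 7, names = FALSE)
  samples[samples$rate >= q[1] & samples$rate <= q[2], , drop = FALSE]
}

#' Regional LOESS trend in growth rate
#'
#' Local linear regression (tricube weights) of growth rate on sample mean
#' age, with a pointwise 95% band from the smoother's standard errors.
#'
#' @param samples growth samples of a single region (at least 10 rows).
#' @param span LOESS span (default 0.75).
#' @param n_grid number of evaluation ages (default 100).
#' @return A data frame of class `reef_trend` with columns `mean_age`,
#'   `rate`, `lower`, `upper`.
#' @export
regional_trend <- function(samples, span = 0.75, n_grid = 100L) {
  if (nrow(samples) < 10L) {
    stop_fmt("region has fewer than 10 samples; trend not estimated (sparse region)")
  }
  fit <- loess(rate ~ mean_age, data = samples, span = span, degree = 1,
               family = "gaussian",
               control = loess.control(surface = "direct"))
  grid <- seq(min(samples$mean_age), max(samples$mean_age), length.out = n_grid)
  pr <- predict(fit, newdata = data.frame(mean_age = grid), se = TRUE)
  out <- data.frame(mean_age = grid, rate = as.numeric(pr$fit),
                    lower = as.numeric(pr$fit - 1.96 * pr$se.fit),
                    upper = as.numeric(pr$fit + 1.96 * pr$se.fit))
  class(out) <- c("reef_trend", "data.frame")
  out
}

#' LOESS trends for every sufficiently sampled region
#'
#' @param samples growth-sample data frame with a `region` column.
#' @param span LOESS span passed to [regional_trend()].
#' @param exclude regions excluded from trend reporting (default
#'   `"Barbados"`, whose tectonically distinctive record is still used for
#'   model fitting but not for observational trend comparison).
#' @param min_n minimum samples per region (default 10).
#' @return Named list of `reef_trend` data frames.
#' @export
regional_trends <- function(samples, span = 0.75, exclude = "Barbados", min_n = 10L) {
  regions <- setdiff(unique(samples$region), exclude)
  out <- list()
  for (r in regions) {
    sub <- samples[samples$region == r, , drop = FALSE]
    if (nrow(sub) >= min_n) out[[r]] <- regional_trend(sub, span = span)
  }
  out
}

#' @importFrom stats loess.control
NULL

#' Write growth samples to CSV
#'
#' @param samples growth-sample data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_samples <- function(samples, path) {
  write.csv(samples, path, row.names = FALSE)
  invisible(path)
}
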