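# Scenario comparison: five-class suitability classification, area-weighted
# extent changes, range-expansion flag and monitoring-priority categories.

.THS_CLASSES <- c("Minimal", "Minor", "Moderate", "Major", "Massive")
.THS_BREAKS <- c(0.2, 0.4, 0.6, 0.8)
.EARTH_RADIUS_KM <- 6371

#' Classify a suitability grid into the five standard classes
#'
#' Equal 0.2-wide THS intervals: Minimal `[0, 0.2)`, Minor `[0.2, 0.4)`,
#' Moderate `[0.4, 0.6)`, Major `[0.6, 0.8)`, Massive `[0.8, 1]`.  Intervals
#' are left-closed/right-open with a closed top class, so every THS value
#' maps to exactly one class; nodata propagates.
#'
#' @param ths A `ths_grid`.
#' @return A `ths_class_grid`: `lat`, `lon`, `codes` (integer matrix 1-5,
#'   `NA` nodata), `labels` (class names by code).
#' @export
classify <- function(ths) {
  stopifnot(inherits(ths, "ths_grid"))
  v <- ths$values
  unmasked <- !is.na(v)
  if (any(v[unmasked] < 0 | v[unmasked] > 1)) {
    stop("THS values outside [0, 1]: upstream contract violation", call. = FALSE)
  }
  codes <- matrix(NA_integer_, nrow(v), ncol(v))
  codes[unmasked] <- findInterval(v[unmasked], .THS_BREAKS) + 1L
  structure(list(lat = ths$lat, lon = ths$lon, codes = codes,
                 labels = .THS_CLASSES),
            class = "ths_class_grid")
}

#' @export
print.ths_class_grid <- function(x, ...) {
  tab <- table(factor(x$labels[x$codes], levels = x$labels))
  cat("<ths_class_grid>\n")
  print(tab)
  invisible(x)
}

# Per-cell area in km^2 on a spherical Earth: proportional to cos(latitude)
# of the cell center.
.cell_area_km2 <- function(lat, dlat, dlon) {
  .EARTH_RADIUS_KM^2 * (dlat * pi / 180) * (dlon * pi / 180) *
    cos(lat * pi / 180)
}

.area_matrix <- function(lat, lon) {
  dlat <- .regular_centers(lat, "lat")
  dlon <- .regular_centers(lon, "lon")
  matrix(rep(.cell_area_km2(lat, dlat, dlon), length(lon)),
         length(lat), length(lon))
}

#' Area-weighted extent of each suitability class
#'
#' Cell areas are cosine-of-latitude weighted on a spherical Earth (radius
#' 6371 km) so extents are reported in km^2; raw cell counts are reported
#' alongside.  Classes absent from the grid get zero rows, and extents sum
#' to the total unmasked area.
#'
#' @param classes A `ths_class_grid`.
#' @return data.frame: `class`, `code`, `area_km2`, `n_cells`, with
#'   attribute `total_area_km2`.
#' @export
class_extents <- function(classes) {
  stopifnot(inherits(classes, "ths_class_grid"))
  area <- .area_matrix(classes$lat, classes$lon)
  out <- data.frame(class = .THS_CLASSES, code = 1:5,
                    area_km2 = 0, n_cells = 0L, stringsAsFactors = FALSE)
  for (k in 1:5) {
    sel <- !is.na(classes$codes) & classes$codes == k
    out$area_km2[k] <- sum(area[sel])
    out$n_cells[k] <- sum(sel)
  }
  attr(out, "total_area_km2") <- sum(area[!is.na(classes$codes)])
  out
}

# Area-weighted extent of cells meeting a THS threshold.
.threshold_extent <- function(ths, threshold = 0.6) {
  area <- .area_matrix(ths$lat, ths$lon)
  sel <- !is.na(ths$values) & ths$values >= threshold
  sum(area[sel])
}

#' Per-cell suitability change between scenarios
#'
#' `future - baseline` per cell, with mean/min/max over unmasked cells.
#' Grids must share extent, origin and masks.
#'
#' @param baseline,future `ths_grid` objects on the same grid.
#' @return List: `delta` (matrix), `mean`, `min`, `max`, plus `lat`/`lon`.
#' @export
delta_ths <- function(baseline, future) {
  stopifnot(inherits(baseline, "ths_grid"), inherits(future, "ths_grid"))
  .check_aligned(baseline, future, "baseline and future THS grids")
  if (!identical(is.na(baseline$values), is.na(future$values))) {
    stop("baseline and future THS grids have different nodata masks",
         call. = FALSE)
  }
  d <- future$values - baseline$values
  v <- d[!is.na(d)]
  list(delta = d, lat = baseline$lat, lon = baseline$lon,
       mean = if (length(v)) mean(v) else NA_real_,
       min = if (length(v)) min(v) else NA_real_,
       max = if (length(v)) max(v) else NA_real_)
}

#' Range-expansion flag
#'
#' A species is range-expanding when the area-weighted spatial extent of
#' moderate-to-high suitability (THS >= 0.6) strictly increases from the
#' baseline to the future scenario.
#'
#' @param baseline,future `ths_grid` objects on the same grid.
#' @param threshold Suitability threshold (default 0.6).
#' @return List: `expanding` (logical), `baseline_extent_km2`,
#'   `future_extent_km2`, `threshold`.
#' @export
range_expansion_flag <- function(baseline, future, threshold = 0.6) {
  .check_aligned(baseline, future, "baseline and future THS grids")
  if (!identical(is.na(baseline$values), is.na(future$values))) {
    stop("baseline and future THS grids have different nodata masks",
         call. = FALSE)
  }
  b <- .threshold_extent(baseline, threshold)
  f <- .threshold_extent(future, threshold)
  list(expanding = f > b, baseline_extent_km2 = b, future_extent_km2 = f,
       threshold = threshold)
}

#' Monitoring-priority category
#'
#' Heuristic screening on the sign-preserving percent change `r` of the
#' THS >= 0.6 extent: `|r| >= high_threshold` is Priority, `low_threshold <=
#' |r| < high_threshold` is Surveillance, otherwise NoIssue.  A species
#' whose qualifying extent appears from a zero baseline has `r = +Inf`
#' (Priority).  The numeric cutoffs (defaults 20% and 5%) are explicit,
#' configurable screening defaults; reported categories always carry them.
#'
#' @param summary A `change_summary` (see [change_summary()]) or a bare
#'   numeric percent change.
#' @param high_threshold,low_threshold Percent cutoffs, `0 < low < high`.
#' @return List: `category` (`"Priority"`, `"Surveillance"`, `"NoIssue"`),
#'   `percent_change`, `thresholds`.
#' @export
priority_category <- function(summary, high_threshold = 20,
                              low_threshold = 5) {
  if (!is.numeric(c(high_threshold, low_threshold)) ||
      low_threshold <= 0 || high_threshold <= 0 ||
      low_threshold >= high_threshold) {
    stop("thresholds must satisfy 0 < low_threshold < high_threshold",
         call. = FALSE)
  }
  r <- if (is.numeric(summary)) summary else summary$extent_ge_0_6_pct_change
  category <- if (is.na(r)) {
    NA_character_
  } else if (abs(r) >= high_threshold) {
    "Priority"
  } else if (abs(r) >= low_threshold) {
    "Surveillance"
  } else {
    "NoIssue"
  }
  list(category = category, percent_change = r,
       thresholds = c(low = low_threshold, high = high_threshold))
}

#' Full per-species change summary between scenarios
#'
#' Combines the five-class extents for both scenarios with absolute and
#' percent changes per class, the per-cell suitability change statistics,
#' the THS >= 0.6 extents, the range-expansion flag and the monitoring
#' priority.  Percent change is undefined (reported `NA`, "new") when the
#' baseline extent of a class is zero; the qualifying-extent percent change
#' is `+Inf` when suitable area appears from a zero baseline.
#'
#' @param species Species identifier.
#' @param baseline,future `ths_grid` objects on the same grid.
#' @param high_threshold,low_threshold Priority cutoffs (percent).
#' @return A `change_summary` list; `classes` is a data.frame with one row
#'   per suitability class.
#' @export
change_summary <- function(species, baseline, future,
                           high_threshold = 20, low_threshold = 5) {
  ext_b <- class_extents(classify(baseline))
  ext_f <- class_extents(classify(future))
  classes <- data.frame(
    class = ext_b$class, code = ext_b$code,
    baseline_km2 = ext_b$area_km2, future_km2 = ext_f$area_km2,
    abs_change_km2 = ext_f$area_km2 - ext_b$area_km2,
    pct_change = ifelse(ext_b$area_km2 > 0,
                        100 * (ext_f$area_km2 - ext_b$area_km2) /
                          ext_b$area_km2,
                        ifelse(ext_f$area_km2 > 0, NA_real_, 0)),
    stringsAsFactors = FALSE)
  d <- delta_ths(baseline, future)
  exp_flag <- range_expansion_flag(baseline, future)
  pct06 <- if (exp_flag$baseline_extent_km2 > 0) {
    100 * (exp_flag$future_extent_km2 - exp_flag$baseline_extent_km2) /
      exp_flag$baseline_extent_km2
  } else if (exp_flag$future_extent_km2 > 0) {
    Inf
  } else {
    0
  }
  out <- structure(
    list(species = species, classes = classes,
         delta_ths_mean = d$mean, delta_ths_min = d$min, delta_ths_max = d$max,
         extent_ge_0_6_baseline_km2 = exp_flag$baseline_extent_km2,
         extent_ge_0_6_future_km2 = exp_flag$future_extent_km2,
         extent_ge_0_6_pct_change = pct06,
         range_expanding = exp_flag$expanding),
    class = "change_summary")
  pr <- priority_category(out, high_threshold, low_threshold)
  out$priority <- pr$category
  out$priority_thresholds <- pr$thresholds
  out
}

#' @export
print.change_summary <- function(x, ...) {
  cat(sprintf("<change_summary> %s: %s, %s (dTHS mean %+.4f)\n",
              x$species,
              if (x$range_expanding) "range-expanding" else "non-expanding",
              x$priority, x$delta_ths_mean))
  print(x$classes, row.names = FALSE)
  invisible(x)
}
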