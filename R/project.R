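# Projection of fitted curves over monthly temperature grids to the
# normalized Thermal Habitat Suitability (THS) index.

#' Predict the feeding rate at a temperature from a fitted curve
#'
#' Evaluates the selected form and applies the projection-stage rules:
#' negative raw predictions are clamped to zero, and where both thermal
#' limits are defined the rate is forced to zero outside `[ctmin, ctmax]`.
#' Non-finite temperatures give `NA` (nodata).
#'
#' @param fit A `fitted_tpc`.
#' @param temperature Numeric vector (degrees C).
#' @return Numeric vector of non-negative rates.
#' @export
predict_rate <- function(fit, temperature) {
  stopifnot(inherits(fit, "fitted_tpc"))
  out <- evaluate_form(fit$form, fit$params, temperature)
  out <- pmax(out, 0)
  if (is.finite(fit$ctmin) && is.finite(fit$ctmax)) {
    outside <- !is.na(temperature) &
      (temperature < fit$ctmin | temperature > fit$ctmax)
    out[outside] <- 0
  }
  out[!is.finite(temperature)] <- NA_real_
  out
}

#' Thermal Habitat Suitability at a temperature
#'
#' `THS = FR_t / FR_opt`: the predicted feeding rate scaled by the species'
#' peak rate at the thermal optimum, giving values in `[0, 1]` with 1
#' attained at the optimum.  Values are clipped into `[0, 1]` to guard
#' grid-refinement rounding at the peak (the raw ratio can exceed 1 by at
#' most ~1e-9).
#'
#' @param fit A `fitted_tpc` with `rmax > 0`.
#' @param temperature Numeric vector (degrees C).
#' @return Numeric vector of THS values in `[0, 1]` (`NA` for non-finite
#'   temperatures).
#' @export
compute_ths <- function(fit, temperature) {
  stopifnot(inherits(fit, "fitted_tpc"))
  if (!is.finite(fit$rmax) || fit$rmax <= 0) {
    stop("THS is undefined for a fit with non-positive peak rate", call. = FALSE)
  }
  pmin(pmax(predict_rate(fit, temperature) / fit$rmax, 0), 1)
}

#' Project a fitted curve over a monthly temperature stack
#'
#' Applies [compute_ths()] cell-wise to each of the twelve monthly layers.
#' Nodata cells propagate.
#'
#' @param fit A `fitted_tpc`.
#' @param stack A `temp_grid_stack`.
#' @return Numeric array `[n_lat, n_lon, 12]` of monthly THS values.
#' @export
project_monthly <- function(fit, stack) {
  stopifnot(inherits(stack, "temp_grid_stack"))
  dims <- dim(stack$months)
  ths <- compute_ths(fit, as.numeric(stack$months))
  array(ths, dims)
}

#' Annual mean of monthly THS layers
#'
#' Arithmetic per-cell mean over the twelve months.  Nodata propagation is
#' strict: a cell missing in any month is nodata in the annual grid.
#'
#' @param monthly Array `[n_lat, n_lon, 12]` from [project_monthly()].
#' @param lat,lon Cell-center coordinates of the grid.
#' @return A `ths_grid`.
#' @export
annual_mean <- function(monthly, lat, lon) {
  if (length(dim(monthly)) != 3 || dim(monthly)[3] != 12) {
    stop("annual_mean requires exactly 12 monthly layers", call. = FALSE)
  }
  vals <- rowMeans(matrix(monthly, prod(dim(monthly)[1:2]), 12))
  ths_grid(lat, lon, matrix(vals, dim(monthly)[1], dim(monthly)[2]))
}

#' Restrict a suitability grid to a species' realm
#'
#' Marine species are masked to sea cells; freshwater and terrestrial
#' species to land cells.  The mask source must be aligned to the grid: no
#' implicit resampling is performed, a mismatched grid is an error.
#'
#' @param grid A `ths_grid`.
#' @param realm `"freshwater"`, `"marine"` or `"terrestrial"`.
#' @param mask_source A `temp_grid_stack` providing the land-sea mask, or a
#'   list with `lat`, `lon` and logical matrix `land`.
#' @return A `ths_grid` with out-of-realm cells set to nodata.
#' @export
apply_realm_mask <- function(grid, realm, mask_source) {
  stopifnot(inherits(grid, "ths_grid"))
  realm <- match.arg(realm, .REALMS)
  .check_aligned(grid, mask_source, "suitability grid and realm mask")
  land <- mask_source$land
  keep <- if (realm == "marine") !land else land
  vals <- grid$values
  vals[!keep] <- NA_real_
  ths_grid(grid$lat, grid$lon, vals)
}

#' Project a species to an annual realm-masked THS grid
#'
#' Convenience wrapper: monthly projection, annual aggregation and realm
#' masking in one step.
#'
#' @param fit A `fitted_tpc`.
#' @param stack A `temp_grid_stack`.
#' @param realm Species realm (defaults to none: no realm masking).
#' @return A `ths_grid`.
#' @export
project_annual_ths <- function(fit, stack, realm = NULL) {
  monthly <- project_monthly(fit, stack)
  annual <- annual_mean(monthly, stack$lat, stack$lon)
  if (is.null(realm)) return(annual)
  apply_realm_mask(annual, realm, stack)
}
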