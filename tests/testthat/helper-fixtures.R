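# Shared fixtures built in code: canonical fitted curves and small grids.

# Zero-noise observations from a registry form, fitted with that same form,
# returning the package's fitted-curve object.
make_fit <- function(form_name, true_params, trange, n = 15, seed = 1) {
  spec <- synthetic_tpc_spec(form_name, true_params, n, trange, noise_cv = 0,
                             seed = seed)
  obs <- generate_tpc_observations(spec)
  form <- tpc_form(form_name)
  res <- fit_single_form(obs, form, n_starts = 3, seed = seed)
  stopifnot(res$converged)
  d <- derive_parameters(form, res$params, range(obs$temperature))
  thermshift:::.fitted_tpc(obs$species, form, res$params, res$aicc, res$rss, d)
}

# The canonical parabola -0.01 (T - 10)(T - 30), expanded coefficients;
# vertex (20, 1), roots 10 and 30.
QUAD_TRUE <- c(a = -3, b = 0.4, c = -0.01)

quad_fit <- function() make_fit("quadratic", QUAD_TRUE, c(10, 30))

gauss_fit <- function() make_fit("gaussian", c(1, 20, 5), c(5, 35))

# A uniform-temperature monthly stack (every cell, every month = temp_c).
uniform_stack <- function(temp_c, n_lat = 6, n_lon = 6,
                          land = matrix(TRUE, n_lat, n_lon)) {
  lat <- rev(seq(-75, 75, length.out = n_lat))
  lon <- seq(-150, 150, length.out = n_lon)
  temp_grid_stack(lat, lon, array(temp_c, c(n_lat, n_lon, 12)), land)
}

# A suitability grid holding given values on a small regular grid.
small_ths <- function(values) {
  values <- as.matrix(values)
  nlat <- nrow(values); nlon <- ncol(values)
  dlat <- 150 / nlat
  ths_grid(rev(seq(-75 + dlat / 2, 75 - dlat / 2, length.out = nlat)),
           seq_len(nlon) * dlat - dlat / 2, values)
}
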