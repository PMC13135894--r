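# Synthetic-data generators: trait observations drawn from known TPC forms,
# and paired baseline/future monthly temperature grids.  These define the
# study conditions every downstream stage is tested against.

# Evaluate code with a local RNG state; the caller's .Random.seed is
# restored afterwards.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic trait-observation experiment
#'
#' Defines the generating curve and sampling design for
#' [generate_tpc_observations()]: a registry form with known (true)
#' parameters, evenly spaced test temperatures, and additive Gaussian noise
#' with standard deviation `noise_cv * rmax_true`, truncated below at zero
#' (measured feeding rates are non-negative).
#'
#' @param form_name Registry model form used as the generating curve.
#' @param true_params Parameter vector in the form's native parameterization.
#' @param n_temperatures Number of distinct test temperatures (`>= 4`).
#' @param temperature_range `c(Tlow, Thigh)` in degrees C, `Tlow < Thigh`.
#' @param noise_cv Noise standard deviation as a fraction of the true peak
#'   rate (`>= 0`).
#' @param replicates_per_temperature Replicates at each temperature (`>= 1`).
#' @param seed Integer seed; all outputs are deterministic under it.
#' @param species,realm,trait Metadata attached to the generated set.
#' @return A `synthetic_tpc_spec` object.
#' @export
synthetic_tpc_spec <- function(form_name, true_params, n_temperatures,
                               temperature_range, noise_cv = 0,
                               replicates_per_temperature = 1, seed = 1,
                               species = paste0(form_name, "_synthetic"),
                               realm = "marine", trait = "ingestion_rate") {
  form <- tpc_form(form_name)  # registry error if unknown
  if (length(true_params) != form$n_params) {
    stop(sprintf("form '%s' expects %d parameters", form_name, form$n_params),
         call. = FALSE)
  }
  if (n_temperatures < 4) {
    stop("n_temperatures must be >= 4 (fewer cannot identify a 4-parameter form)",
         call. = FALSE)
  }
  if (length(temperature_range) != 2 ||
      temperature_range[1] >= temperature_range[2]) {
    stop("temperature_range must be c(Tlow, Thigh) with Tlow < Thigh",
         call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  if (replicates_per_temperature < 1) {
    stop("replicates_per_temperature must be >= 1", call. = FALSE)
  }
  structure(
    list(form_name = form_name, true_params = as.numeric(true_params),
         n_temperatures = as.integer(n_temperatures),
         temperature_range = as.numeric(temperature_range),
         noise_cv = noise_cv,
         replicates_per_temperature = as.integer(replicates_per_temperature),
         seed = as.integer(seed), species = species,
         realm = match.arg(realm, .REALMS), trait = trait),
    class = "synthetic_tpc_spec"
  )
}

# True peak rate of the generating curve, by dense scan over the sampled
# temperature range (0.01 C steps).
.true_rmax <- function(form, params, temperature_range) {
  grid <- seq(temperature_range[1], temperature_range[2], by = 0.01)
  max(form$fun(grid, params))
}

#' Generate trait observations from a known curve
#'
#' Temperatures are evenly spaced over the spec's range; each rate is the
#' generating curve's value plus `Normal(0, noise_cv * rmax_true)` noise,
#' truncated below at zero.  Deterministic under the spec's seed.
#'
#' @param spec A `synthetic_tpc_spec`.
#' @return A `trait_obs` object with attribute `"truth"` carrying the
#'   generating form, parameters and true peak rate.
#' @export
#' @examples
#' sp <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 15, c(5, 35))
#' obs <- generate_tpc_observations(sp)
generate_tpc_observations <- function(spec) {
  stopifnot(inherits(spec, "synthetic_tpc_spec"))
  form <- tpc_form(spec$form_name)
  temps <- seq(spec$temperature_range[1], spec$temperature_range[2],
               length.out = spec$n_temperatures)
  temps <- rep(temps, each = spec$replicates_per_temperature)
  mu <- form$fun(temps, spec$true_params)
  rmax_true <- .true_rmax(form, spec$true_params, spec$temperature_range)
  rate <- .with_seed(spec$seed, {
    mu + stats::rnorm(length(mu), 0, spec$noise_cv * rmax_true)
  })
  rate <- pmax(rate, 0)
  obs <- trait_observations(spec$species, spec$realm, spec$trait, temps, rate)
  attr(obs, "truth") <- list(form_name = spec$form_name,
                             true_params = spec$true_params,
                             rmax_true = rmax_true)
  obs
}

#' Specify a synthetic climate world
#'
#' Defines paired baseline/future monthly temperature grids: a latitudinal
#' gradient from equator to poles, a 12-month sinusoidal seasonal cycle whose
#' phase flips between hemispheres (boreal vs austral seasons), additive
#' spatial noise, a random land-sea mask, and a spatially uniform warming
#' offset producing the future scenario.
#'
#' @param n_lat,n_lon Grid dimensions (both `>= 2`).
#' @param lat_range,lon_range Extents in degrees.
#' @param mean_equator_temp,mean_pole_temp Annual-mean temperatures (C) at
#'   the equator and poles defining the latitudinal gradient.
#' @param seasonal_amplitude Amplitude (C) of the monthly sinusoid.
#' @param warming_offset Uniform offset (C) added to every cell and month to
#'   produce the future scenario.
#' @param land_fraction Fraction of cells marked land.
#' @param noise_sd Standard deviation (C) of per-cell, per-month noise
#'   (shared between scenarios, so future minus baseline is exactly the
#'   warming offset).
#' @param seed Integer seed.
#' @return A `synthetic_climate_spec` object.
#' @export
synthetic_climate_spec <- function(n_lat = 36, n_lon = 72,
                                   lat_range = c(-90, 90),
                                   lon_range = c(-180, 180),
                                   mean_equator_temp = 27,
                                   mean_pole_temp = -20,
                                   seasonal_amplitude = 8,
                                   warming_offset = 2,
                                   land_fraction = 0.3,
                                   noise_sd = 0.5,
                                   seed = 1) {
  if (n_lat < 2 || n_lon < 2) {
    stop("grid dimensions must be at least 2 x 2", call. = FALSE)
  }
  if (land_fraction < 0 || land_fraction > 1) {
    stop("land_fraction must be in [0, 1]", call. = FALSE)
  }
  if (seasonal_amplitude < 0 || noise_sd < 0) {
    stop("seasonal_amplitude and noise_sd must be >= 0", call. = FALSE)
  }
  structure(
    list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
         lat_range = as.numeric(lat_range), lon_range = as.numeric(lon_range),
         mean_equator_temp = mean_equator_temp,
         mean_pole_temp = mean_pole_temp,
         seasonal_amplitude = seasonal_amplitude,
         warming_offset = warming_offset,
         land_fraction = land_fraction, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synthetic_climate_spec"
  )
}

#' Generate paired baseline/future monthly temperature grids
#'
#' Cell temperature is `gradient(lat) + s(lat) * A * sin(2 pi month / 12) +
#' noise`, where the gradient interpolates linearly in `|lat|` between the
#' equator and pole means, `A` is the seasonal amplitude and `s(lat)` flips
#' sign across the equator.  The future stack equals the baseline plus the
#' warming offset at every cell and month; masks are identical across months
#' and scenarios.
#'
#' @param spec A `synthetic_climate_spec`.
#' @return List with `temp_grid_stack` elements `baseline` and `future`.
#' @export
generate_temperature_grids <- function(spec) {
  stopifnot(inherits(spec, "synthetic_climate_spec"))
  dlat <- diff(spec$lat_range) / spec$n_lat
  dlon <- diff(spec$lon_range) / spec$n_lon
  lat <- rev(spec$lat_range[1] + dlat * (seq_len(spec$n_lat) - 0.5))
  lon <- spec$lon_range[1] + dlon * (seq_len(spec$n_lon) - 0.5)

  gradient <- spec$mean_equator_temp +
    (spec$mean_pole_temp - spec$mean_equator_temp) * abs(lat) / 90
  hemi <- ifelse(lat >= 0, 1, -1)

  out <- .with_seed(spec$seed, {
    land <- matrix(stats::runif(spec$n_lat * spec$n_lon) < spec$land_fraction,
                   spec$n_lat, spec$n_lon)
    noise <- array(stats::rnorm(spec$n_lat * spec$n_lon * 12, 0, spec$noise_sd),
                   c(spec$n_lat, spec$n_lon, 12))
    list(land = land, noise = noise)
  })

  months <- array(NA_real_, c(spec$n_lat, spec$n_lon, 12))
  for (m in 1:12) {
    seasonal <- hemi * spec$seasonal_amplitude * sin(2 * pi * m / 12)
    months[, , m] <- outer(gradient + seasonal, rep(1, spec$n_lon)) +
      out$noise[, , m]
  }
  baseline <- temp_grid_stack(lat, lon, months, out$land)
  future <- temp_grid_stack(lat, lon, months + spec$warming_offset, out$land)
  list(baseline = baseline, future = future)
}

# Species archetypes used by the study fixture: unimodal generating forms
# with realm-typical thermal optima.
.FIXTURE_FORMS <- c("gaussian", "quadratic", "modifiedgaussian", "deutsch")

.fixture_true_params <- function(form_name, rmax, topt, width) {
  switch(form_name,
    gaussian = c(rmax, topt, width),
    quadratic = {
      cc <- -rmax / width^2
      c(rmax + cc * topt^2, -2 * cc * topt, cc)
    },
    modifiedgaussian = c(rmax, topt, width, 2.5),
    deutsch = c(rmax, topt, topt + width, width),
    stop("no fixture parameterization for form ", form_name)
  )
}

#' Generate a complete synthetic study fixture
#'
#' Builds trait tables for species across the three realms (mixed generating
#' forms, realm-typical thermal optima) together with one paired
#' baseline/future climate world shared by all realms (realm-appropriate
#' masking is applied at projection time).  Reproducible under `seed`.
#'
#' @param n_species_per_realm Single count or length-3 vector in the order
#'   freshwater, marine, terrestrial.  `c(4, 16, 8)` reproduces the
#'   28-species composition used for the package's worked examples.
#' @param seed Integer seed.
#' @param climate_spec Optional `synthetic_climate_spec` overriding the
#'   default world.
#' @return List with `traits` (data.frame: species, realm, trait,
#'   temperature_C, rate), `truth` (data.frame of generating parameters),
#'   `baseline` and `future` (`temp_grid_stack`).
#' @export
generate_study_fixture <- function(n_species_per_realm = c(4, 16, 8),
                                   seed = 1, climate_spec = NULL) {
  n <- n_species_per_realm
  if (length(n) == 1) n <- rep(n, 3)
  if (length(n) != 3 || any(n < 1)) {
    stop("n_species_per_realm must be a positive count or length-3 vector",
         call. = FALSE)
  }
  realms <- rep(.REALMS, times = n)
  topt_range <- list(freshwater = c(12, 24), marine = c(8, 26),
                     terrestrial = c(22, 36))

  draws <- .with_seed(seed, {
    lapply(seq_along(realms), function(i) {
      realm <- realms[i]
      tr <- topt_range[[realm]]
      list(
        topt = stats::runif(1, tr[1], tr[2]),
        rmax = exp(stats::runif(1, log(0.5), log(20))),
        width = stats::runif(1, 4, 9),
        obs_seed = sample.int(1e6, 1)
      )
    })
  })

  traits <- list()
  truth <- list()
  for (i in seq_along(realms)) {
    d <- draws[[i]]
    form_name <- .FIXTURE_FORMS[(i - 1) %% length(.FIXTURE_FORMS) + 1]
    sp_name <- sprintf("%s_sp%02d", realms[i], i)
    spec <- synthetic_tpc_spec(
      form_name = form_name,
      true_params = .fixture_true_params(form_name, d$rmax, d$topt, d$width),
      n_temperatures = 12,
      temperature_range = c(d$topt - 1.6 * d$width, d$topt + 1.4 * d$width),
      noise_cv = 0.05, replicates_per_temperature = 2,
      seed = d$obs_seed, species = sp_name, realm = realms[i])
    obs <- generate_tpc_observations(spec)
    traits[[i]] <- data.frame(
      species = sp_name, realm = realms[i], trait = obs$trait,
      temperature_C = obs$temperature, rate = obs$rate,
      stringsAsFactors = FALSE)
    truth[[i]] <- data.frame(
      species = sp_name, realm = realms[i], form = form_name,
      rmax_true = d$rmax, topt_true = d$topt, width_true = d$width,
      stringsAsFactors = FALSE)
  }

  if (is.null(climate_spec)) {
    climate_spec <- synthetic_climate_spec(seed = seed + 1L)
  }
  grids <- generate_temperature_grids(climate_spec)
  list(traits = do.call(rbind, traits), truth = do.call(rbind, truth),
       baseline = grids$baseline, future = grids$future)
}
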