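test_that("zero-noise observations lie exactly on the generating curve", {
  # 13 evenly spaced temperatures over [5, 35]: step 2.5, includes 20 and 25
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 13, c(5, 35),
                             noise_cv = 0)
  obs <- generate_tpc_observations(spec)
  expect_equal(obs$rate[obs$temperature == 20], 1.0)
  expect_equal(obs$rate[abs(obs$temperature - 25) < 1e-9], exp(-0.5))
  truth <- evaluate_form(tpc_form("gaussian"), c(1, 20, 5), obs$temperature)
  expect_equal(max(abs(obs$rate - truth)), 0)
})

test_that("noisy generation is deterministic under a fixed seed and truncated at zero", {
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 15, c(5, 35),
                             noise_cv = 0.5, replicates_per_temperature = 3,
                             seed = 1)
  a <- generate_tpc_observations(spec)
  b <- generate_tpc_observations(spec)
  expect_identical(a$rate, b$rate)
  expect_true(all(a$rate >= 0))
  expect_length(a$rate, 45)
})

test_that("trait spec validation rejects degenerate designs", {
  expect_error(synthetic_tpc_spec("gaussian", c(1, 20, 5), 3, c(5, 35)),
               "n_temperatures")
  expect_error(synthetic_tpc_spec("gaussian", c(1, 20, 5), 10, c(35, 5)),
               "Tlow < Thigh")
  expect_error(synthetic_tpc_spec("gaussian", c(1, 20, 5), 10, c(5, 35),
                                  noise_cv = -0.1), "noise_cv")
  expect_error(synthetic_tpc_spec("notaform", c(1, 2), 10, c(5, 35)),
               "unknown TPC model form")
  expect_error(synthetic_tpc_spec("gaussian", c(1, 20), 10, c(5, 35)),
               "expects 3 parameters")
})

test_that("future grids equal baseline plus the warming offset everywhere", {
  spec <- synthetic_climate_spec(n_lat = 10, n_lon = 16, warming_offset = 2,
                                 seed = 3)
  g <- generate_temperature_grids(spec)
  expect_equal(g$future$months - g$baseline$months,
               array(2, dim(g$baseline$months)))
  expect_identical(g$baseline$land, g$future$land)

  g0 <- generate_temperature_grids(
    synthetic_climate_spec(n_lat = 10, n_lon = 16, warming_offset = 0,
                           seed = 3))
  expect_identical(g0$baseline, g0$future)
})

test_that("without seasonality and noise all monthly layers are equal", {
  spec <- synthetic_climate_spec(n_lat = 8, n_lon = 8, seasonal_amplitude = 0,
                                 noise_sd = 0, seed = 5)
  g <- generate_temperature_grids(spec)
  for (m in 2:12) {
    expect_equal(g$baseline$months[, , m], g$baseline$months[, , 1])
  }
  # latitudinal gradient: equator warmer than poles
  mid <- g$baseline$months[, 1, 1]
  expect_gt(mid[which.min(abs(g$baseline$lat))], mid[1])
})

test_that("climate generation is seeded and validates dimensions", {
  spec <- synthetic_climate_spec(n_lat = 6, n_lon = 6, seed = 9)
  expect_identical(generate_temperature_grids(spec),
                   generate_temperature_grids(spec))
  expect_error(synthetic_climate_spec(n_lat = 1), "at least 2 x 2")
  expect_error(synthetic_climate_spec(land_fraction = 1.5), "land_fraction")
})

test_that("study fixture reproduces the requested realm composition", {
  fx <- generate_study_fixture(1, seed = 2)
  expect_length(unique(fx$traits$species), 3)
  expect_s3_class(fx$baseline, "temp_grid_stack")
  expect_s3_class(fx$future, "temp_grid_stack")

  fx28 <- generate_study_fixture(c(4, 16, 8), seed = 2)
  comp <- table(fx28$truth$realm)
  expect_identical(as.integer(comp[c("freshwater", "marine", "terrestrial")]),
                   c(4L, 16L, 8L))
  expect_length(unique(fx28$traits$species), 28)

  expect_identical(fx28$traits, generate_study_fixture(c(4, 16, 8), seed = 2)$traits)
})
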