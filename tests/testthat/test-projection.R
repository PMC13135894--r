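test_that("predicted rates are clamped at zero and inside thermal limits", {
  fit <- quad_fit()  # vertex (20, 1), roots 10 and 30
  expect_equal(predict_rate(fit, 5), 0)        # raw -1.0, clamped
  expect_equal(predict_rate(fit, 20), 1, tolerance = 1e-6)
  expect_equal(predict_rate(fit, 15), 0.75, tolerance = 1e-6)
  expect_equal(predict_rate(fit, c(9.9, 30.1)), c(0, 0))
  expect_true(is.na(predict_rate(fit, NA_real_)))

  g <- gauss_fit()
  expect_equal(predict_rate(g, g$topt), g$rmax)
})

test_that("THS is the rate normalized by the peak, in [0, 1]", {
  fit <- quad_fit()
  expect_equal(compute_ths(fit, fit$topt), 1.0)
  expect_equal(compute_ths(fit, 15), 0.75, tolerance = 1e-6)
  expect_equal(compute_ths(fit, 5), 0)   # outside [ctmin, ctmax]
  grid <- seq(-10, 50, by = 0.01)
  raw <- predict_rate(fit, grid) / fit$rmax
  expect_lte(max(raw), 1 + 1e-9)         # clip guard tolerance
  expect_true(all(compute_ths(fit, grid) >= 0 & compute_ths(fit, grid) <= 1))

  broken <- fit
  broken$rmax <- 0
  expect_error(compute_ths(broken, 20), "non-positive peak rate")
})

test_that("monthly projection is cell-wise and propagates nodata", {
  fit <- quad_fit()
  stack <- uniform_stack(20)
  monthly <- project_monthly(fit, stack)
  expect_equal(dim(monthly), c(6, 6, 12))
  expect_equal(as.numeric(monthly), rep(1, 6 * 6 * 12), tolerance = 1e-9)

  stack$months[2, 3, ] <- NA
  m2 <- project_monthly(fit, stack)
  expect_true(all(is.na(m2[2, 3, ])))
  expect_false(anyNA(m2[1, 1, ]))
})

test_that("annual mean averages months with strict nodata propagation", {
  lat <- rev(seq(-60, 60, length.out = 4)); lon <- seq(-60, 60, length.out = 4)
  arr <- array(0.4, c(4, 4, 12))
  expect_equal(annual_mean(arr, lat, lon)$values, matrix(0.4, 4, 4))

  arr2 <- array(rep(c(1, 0), each = 16 * 6), c(4, 4, 12))
  expect_equal(annual_mean(arr2, lat, lon)$values, matrix(0.5, 4, 4))

  arr[1, 1, 7] <- NA
  out <- annual_mean(arr, lat, lon)
  expect_true(is.na(out$values[1, 1]))
  expect_false(is.na(out$values[2, 2]))

  expect_error(annual_mean(arr[, , 1:11], lat, lon), "12 monthly layers")
})

test_that("realm masking keeps the right cells and refuses misaligned masks", {
  fit <- gauss_fit()
  land <- matrix(FALSE, 6, 6); land[1:3, ] <- TRUE
  stack <- uniform_stack(20, land = land)
  annual <- annual_mean(project_monthly(fit, stack), stack$lat, stack$lon)

  marine <- apply_realm_mask(annual, "marine", stack)
  expect_true(all(is.na(marine$values[1:3, ])))
  expect_false(anyNA(marine$values[4:6, ]))

  terr <- apply_realm_mask(annual, "terrestrial", stack)
  expect_false(anyNA(terr$values[1:3, ]))
  expect_true(all(is.na(terr$values[4:6, ])))

  all_land <- uniform_stack(20, land = matrix(TRUE, 6, 6))
  expect_true(all(is.na(
    apply_realm_mask(annual, "marine", all_land)$values)))

  shifted <- all_land
  shifted$lat <- shifted$lat + 1  # same shape, shifted origin
  expect_error(apply_realm_mask(annual, "marine", shifted), "not aligned")
})

test_that("a grid held at the optimum yields annual THS 1 everywhere unmasked", {
  for (fit in list(gauss_fit(), quad_fit())) {
    stack <- uniform_stack(fit$topt)
    annual <- project_annual_ths(fit, stack)
    expect_equal(annual$values, matrix(1, 6, 6), tolerance = 1e-9)
  }
})

test_that("warming below the optimum never decreases annual THS", {
  fit <- gauss_fit()  # topt 20
  base_t <- 8
  base <- project_annual_ths(fit, uniform_stack(base_t))
  for (delta in c(0, 1, 4, 8, 12)) {  # base_t + delta <= topt
    warmed <- project_annual_ths(fit, uniform_stack(base_t + delta))
    expect_true(all(warmed$values >= base$values),
                label = sprintf("monotone at delta=%g", delta))
    base <- warmed
  }
})

test_that("projection is deterministic: same stack twice, identical grids", {
  fit <- gauss_fit()
  fx <- generate_temperature_grids(
    synthetic_climate_spec(n_lat = 8, n_lon = 10, seed = 21))
  a <- project_annual_ths(fit, fx$baseline, "marine")
  b <- project_annual_ths(fit, fx$baseline, "marine")
  expect_identical(a, b)
})
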