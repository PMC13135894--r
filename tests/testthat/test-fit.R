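test_that("observation filtering applies the data-quality rules", {
  raw <- data.frame(
    species = c(rep("a", 6), rep("b", 3)),
    realm = "marine", trait = "ingestion_rate",
    temperature_C = c(5, 10, 15, 20, 20, NA, 5, 10, 15),
    rate = c(0.1, -0.5, 0.8, 1.0, 1.0, 0.4, 0.2, 0.5, 0.3))
  out <- filter_observations(raw)
  # species a: negative-rate row, missing-temperature row and the duplicate
  # (20, 1.0) are dropped, leaving 3 distinct temperatures -> insufficient
  expect_false("a" %in% names(out$observations))
  expect_identical(out$excluded$reason,
                   rep("insufficient_data", nrow(out$excluded)))
  expect_true(all(c("a", "b") %in% out$excluded$species))

  clean <- data.frame(species = "c", realm = "freshwater", trait = "t",
                      temperature_C = c(5, 10, 15, 20), rate = 1:4 / 4)
  kept <- filter_observations(clean)
  expect_identical(kept$observations$c$temperature, c(5, 10, 15, 20))
  expect_identical(kept$n_rows_dropped, 0L)

  expect_error(filter_observations(clean[-1]), "missing required column")
})

test_that("negative-rate rows are removed but other rows survive", {
  raw <- data.frame(species = "a", realm = "marine", trait = "t",
                    temperature_C = c(5, 10, 15, 20, 25),
                    rate = c(0.1, -0.2, 0.8, 1.0, 0.6))
  out <- filter_observations(raw)
  expect_identical(out$observations$a$temperature, c(5, 15, 20, 25))
  expect_identical(out$n_rows_dropped, 1L)
})

test_that("zero-noise Gaussian data recovers the true optimum to 1e-3 C", {
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 15, c(5, 35),
                             noise_cv = 0)
  obs <- generate_tpc_observations(spec)
  res <- fit_single_form(obs, tpc_form("gaussian"), n_starts = 5, seed = 1)
  expect_true(res$converged)
  d <- derive_parameters(tpc_form("gaussian"), res$params,
                         range(obs$temperature))
  expect_equal(d$topt, 20, tolerance = 1e-3)
  expect_equal(d$rmax, 1, tolerance = 1e-3)
})

test_that("fits are deterministic under a fixed seed", {
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 12, c(5, 35),
                             noise_cv = 0.1, seed = 4)
  obs <- generate_tpc_observations(spec)
  r1 <- fit_single_form(obs, tpc_form("gaussian"), n_starts = 8, seed = 7)
  r2 <- fit_single_form(obs, tpc_form("gaussian"), n_starts = 8, seed = 7)
  expect_identical(r1$params, r2$params)
})

test_that("forms without AICc degrees of freedom are marked non-converged", {
  obs <- trait_observations("sp", "marine", "t",
                            c(5, 12, 20, 28, 35), c(0.2, 0.6, 1.0, 0.7, 0.1))
  # n = 5, 4-parameter form: n - k - 1 = 5 - 5 - 1 < 0
  res <- fit_single_form(obs, tpc_form("modifiedgaussian"), n_starts = 3,
                         seed = 1)
  expect_false(res$converged)
  expect_true(is.na(res$aicc))
})

test_that("derived parameters match the parabola's closed-form vertex and roots", {
  quad <- tpc_form("quadratic")
  d <- derive_parameters(quad, c(-3, 0.4, -0.01), c(10, 30))
  expect_equal(d$topt, 20, tolerance = 0.01)
  expect_equal(d$rmax, 1, tolerance = 1e-6)
  expect_equal(d$ctmin, 10, tolerance = 0.01)
  expect_equal(d$ctmax, 30, tolerance = 0.01)
  expect_true(is.na(d$q10))  # rate is exactly 0 at topt - 10
})

test_that("Gaussian Q10 matches its closed form and limits stay undefined", {
  g <- tpc_form("gaussian")
  d <- derive_parameters(g, c(1, 20, 5), c(5, 35))
  expect_equal(d$q10, exp(2), tolerance = 1e-6)  # 1 / exp(-0.5 * (10/5)^2)
  expect_true(is.na(d$ctmin))
  expect_true(is.na(d$ctmax))
  expect_error(derive_parameters(g, c(NA, 20, 5), c(5, 35)), "non-converged")
})

test_that("plausibility filter rejects the documented pathologies", {
  obs <- trait_observations("sp", "marine", "t",
                            c(5, 15, 25, 35), c(0.2, 0.8, 1.0, 0.3))
  healthy <- list(rmax = 1, topt = 24, ctmin = NA_real_, ctmax = NA_real_)
  expect_true(plausibility_filter(healthy, obs)$keep)

  flat <- list(rmax = 0, topt = 20, ctmin = NA_real_, ctmax = NA_real_)
  expect_false(plausibility_filter(flat, obs)$keep)
  expect_identical(plausibility_filter(flat, obs)$reason,
                   "implausible_parameters")

  hot <- list(rmax = 1, topt = 46, ctmin = NA_real_, ctmax = NA_real_)
  expect_false(plausibility_filter(hot, obs)$keep)  # 46 > 35 + 10

  wide <- list(rmax = 1, topt = 20, ctmin = -45, ctmax = 40)
  expect_false(plausibility_filter(wide, obs)$keep)  # window 85 > 80
})

test_that("model selection scores all 22 forms and encodes exclusions", {
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 12, c(5, 35),
                             noise_cv = 0.05, seed = 2)
  obs <- generate_tpc_observations(spec)
  sel <- fit_all_forms(obs, n_starts = 4, seed = 1)
  expect_identical(nrow(sel$table), 22L)
  expect_false(is.na(sel$selected))
  expect_true(is.na(sel$exclusion_reason))
  idx <- which(sel$table$form == sel$selected)
  cand <- sel$table$converged & sel$table$plausible
  expect_equal(sel$table$aicc[idx], min(sel$table$aicc[cand]))

  # n = 4: every registry form (all >= 3 params) lacks AICc dof
  tiny <- trait_observations("sp", "marine", "t",
                             c(5, 15, 25, 35), c(1, 2, 2, 1))
  sel2 <- fit_all_forms(tiny, n_starts = 2, seed = 1)
  expect_true(is.na(sel2$selected))
  expect_identical(sel2$exclusion_reason, "no_convergence")
})

test_that("AICc ties break by fewer parameters, then registry order", {
  tab <- data.frame(
    form = c("f6", "g4", "h4", "k3"), n_params = c(6L, 4L, 4L, 3L),
    aicc = c(-10, -20, -20, -15), rss = 1,
    converged = TRUE, plausible = TRUE, registry_order = 1:4)
  expect_identical(thermshift:::.select_best(tab), 2L)  # tie at -20: first 4-param
  tab$aicc <- c(-20, -20, -20, -20 + 5e-10)  # all tied to machine precision
  expect_identical(thermshift:::.select_best(tab), 4L)  # fewest params wins
  tab$converged <- FALSE
  expect_true(is.na(thermshift:::.select_best(tab)))
})

test_that("model selection is invariant to observation order", {
  spec <- synthetic_tpc_spec("gaussian", c(2, 18, 6), 12, c(4, 32),
                             noise_cv = 0.05, seed = 6)
  obs <- generate_tpc_observations(spec)
  perm <- thermshift:::.with_seed(99, sample(seq_along(obs$temperature)))
  obs2 <- trait_observations(obs$species, obs$realm, obs$trait,
                             obs$temperature[perm], obs$rate[perm])
  s1 <- fit_all_forms(obs, n_starts = 4, seed = 3)
  s2 <- fit_all_forms(obs2, n_starts = 4, seed = 3)
  expect_identical(s1$selected, s2$selected)
  expect_equal(s1$fit$params, s2$fit$params, tolerance = 1e-6)
  expect_equal(s1$table$aicc, s2$table$aicc, tolerance = 1e-6)
})

test_that("bootstrap echoes its level, is seeded, and degenerates to zero width", {
  fit <- gauss_fit()
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 15, c(5, 35),
                             noise_cv = 0)
  obs <- generate_tpc_observations(spec)
  b <- bootstrap_ci(obs, fit, n_resamples = 100, level = 0.95, seed = 5)
  expect_equal(b$nominal_level, 0.95)
  ci <- b$intervals[b$intervals$parameter == "topt", ]
  expect_equal(ci$low, ci$high, tolerance = 1e-6)  # zero-noise residuals
  expect_equal(ci$low, 20, tolerance = 1e-3)

  b2 <- bootstrap_ci(obs, fit, n_resamples = 100, level = 0.95, seed = 5)
  expect_identical(b$draws, b2$draws)
  expect_error(bootstrap_ci(obs, fit, n_resamples = 50), "n_resamples")
})

test_that("noisy-data bootstrap intervals bracket the point estimate", {
  spec <- synthetic_tpc_spec("gaussian", c(1, 20, 5), 20, c(5, 35),
                             noise_cv = 0.05, seed = 11)
  obs <- generate_tpc_observations(spec)
  g <- tpc_form("gaussian")
  res <- fit_single_form(obs, g, n_starts = 5, seed = 11)
  d <- derive_parameters(g, res$params, range(obs$temperature))
  fit <- thermshift:::.fitted_tpc("sp", g, res$params, res$aicc, res$rss, d)
  b <- bootstrap_ci(obs, fit, n_resamples = 200, level = 0.95, seed = 12)
  ci <- b$intervals[b$intervals$parameter == "topt", ]
  expect_lte(ci$low, fit$topt)
  expect_gte(ci$high, fit$topt)
  expect_gt(ci$high, ci$low)
  expect_false(b$warning)
})
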