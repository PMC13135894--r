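# Curve fitting and model selection: every registry form is fitted to each
# species by bounded multi-start nonlinear least squares, the best form is
# chosen by small-sample AICc, thermal parameters are derived from the
# selected curve, and implausible fits are excluded.

# Half-width (degrees C) of the derived-parameter search window beyond the
# observed temperature span; wide enough to locate limits slightly outside
# the design without chasing asymptotes.
.DERIVE_WINDOW_PAD <- 25

# AICc for least squares: residual variance counts as a parameter.
.aicc <- function(rss, n, n_params, correction = TRUE) {
  k <- n_params + 1
  if (n - k - 1 <= 0) return(NA_real_)
  rss <- max(rss, 1e-300)
  base <- n * log(rss / n) + 2 * k
  if (correction) base + 2 * k * (k + 1) / (n - k - 1) else base
}

.fit_residual_fn <- function(form, temps, rates) {
  function(p) {
    r <- rates - form$fun(temps, p)
    r[!is.finite(r)] <- 1e10
    r
  }
}

# One Levenberg-Marquardt run from a given start; NULL on failure.
.lm_run <- function(form, temps, rates, start) {
  # warnings from exploratory starts (singular gradients, NaN trial steps)
  # are expected during multi-start search; failure is encoded in the result
  res <- tryCatch(
    suppressWarnings(minpack.lm::nls.lm(
      par = start, lower = form$lower, upper = form$upper,
      fn = .fit_residual_fn(form, temps, rates),
      control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(res)) return(NULL)
  if (!res$info %in% 1:4) return(NULL)
  rss <- sum(res$fvec^2)
  if (!is.finite(rss)) return(NULL)
  list(params = as.numeric(res$par), rss = rss)
}

#' Fit one model form to one species
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) from `n_starts`
#' seeded initial-value sets: the heuristic start plus jittered copies
#' (roughly +/-20% of each start value).  The converged run with the lowest
#' residual sum of squares is kept.  AICc is
#' `n ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)` with `k = n_params + 1` (the
#' residual variance is counted); a form whose AICc denominator is
#' non-positive, or for which every start fails, is reported non-converged.
#'
#' @param obs A `trait_obs` object (already quality-filtered).
#' @param form A `tpc_form` object.
#' @param n_starts Number of starts (`>= 1`).
#' @param seed Integer seed for the start jitter.
#' @param correction Use the small-sample AICc correction (default) or raw
#'   AIC.
#' @return List: `params` (named), `aicc`, `rss`, `converged`.
#' @export
fit_single_form <- function(obs, form, n_starts = 10, seed = 1,
                            correction = TRUE) {
  obs <- as_trait_obs(obs)
  stopifnot(inherits(form, "tpc_form"), n_starts >= 1)
  n <- length(obs$temperature)
  p0 <- start_values(form, obs)
  scale <- pmax(abs(p0), 0.1)
  starts <- .with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1) return(as.numeric(p0))
      pmin(pmax(p0 + stats::runif(form$n_params, -0.2, 0.2) * scale,
                form$lower), form$upper)
    })
  })
  best <- NULL
  for (st in starts) {
    run <- .lm_run(form, obs$temperature, obs$rate, st)
    if (!is.null(run) && (is.null(best) || run$rss < best$rss)) best <- run
  }
  failed <- list(params = stats::setNames(rep(NA_real_, form$n_params),
                                          form$param_names),
                 aicc = NA_real_, rss = NA_real_, converged = FALSE)
  if (is.null(best)) return(failed)
  aicc <- .aicc(best$rss, n, form$n_params, correction)
  if (is.na(aicc)) return(failed)
  list(params = stats::setNames(best$params, form$param_names),
       aicc = aicc, rss = best$rss, converged = TRUE)
}

#' Derive thermal parameters from a fitted curve
#'
#' The thermal optimum is located by a dense 0.01 C grid scan over the
#' extended window `[Tobs_min - 25, Tobs_max + 25]` followed by local
#' refinement; `rmax` is the curve value at the refined optimum.  `ctmin`
#' and `ctmax` are the nearest zero-crossings of the fitted curve below and
#' above the optimum, found by bisection, and are `NA` when the curve never
#' reaches zero inside the window.  `q10 = rmax / rate(topt - 10)`, `NA`
#' when the rate 10 C below the optimum is non-positive.
#'
#' @param form A `tpc_form`.
#' @param params Fitted parameter vector.
#' @param obs_range `c(Tobs_min, Tobs_max)` of the observations fitted.
#' @return List: `topt`, `rmax`, `ctmin`, `ctmax`, `q10`, `window`.
#' @export
derive_parameters <- function(form, params, obs_range) {
  params <- as.numeric(params)
  if (anyNA(params)) {
    stop("cannot derive parameters from a non-converged fit", call. = FALSE)
  }
  window <- c(obs_range[1] - .DERIVE_WINDOW_PAD,
              obs_range[2] + .DERIVE_WINDOW_PAD)
  grid <- seq(window[1], window[2], by = 0.01)
  f <- function(t) form$fun(t, params)
  v <- f(grid)
  i <- which.max(v)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  topt <- opt$maximum
  rmax <- f(topt)

  ctmin <- NA_real_
  below <- which(grid < topt & v <= 0)
  if (length(below) > 0) {
    j <- max(below)
    if (j < length(grid) && v[j + 1] > 0) {
      ctmin <- stats::uniroot(f, c(grid[j], grid[j + 1]), tol = 1e-8)$root
    } else {
      ctmin <- grid[j]
    }
  }
  ctmax <- NA_real_
  above <- which(grid > topt & v <= 0)
  if (length(above) > 0) {
    j <- min(above)
    if (j > 1 && v[j - 1] > 0) {
      ctmax <- stats::uniroot(f, c(grid[j - 1], grid[j]), tol = 1e-8)$root
    } else {
      ctmax <- grid[j]
    }
  }
  r10 <- f(topt - 10)
  q10 <- if (is.finite(r10) && r10 > 0) rmax / r10 else NA_real_
  list(topt = topt, rmax = rmax, ctmin = ctmin, ctmax = ctmax, q10 = q10,
       window = window)
}

#' Plausibility filter for a fitted curve
#'
#' Encodes the exclusion of fits with unrealistic parameter estimates: the
#' fit is excluded when the peak rate is non-positive (or non-finite), when
#' the thermal optimum falls more than 10 C outside the observed temperature
#' span, or when the thermal window `ctmax - ctmin` (both defined) exceeds
#' 80 C.
#'
#' @param derived Output of [derive_parameters()].
#' @param obs The `trait_obs` the curve was fitted to.
#' @return List: `keep` (logical), `reason` (`NA` or
#'   `"implausible_parameters"`).
#' @export
plausibility_filter <- function(derived, obs) {
  obs <- as_trait_obs(obs)
  tr <- range(obs$temperature)
  bad <- !is.finite(derived$rmax) || derived$rmax <= 0 ||
    derived$topt < tr[1] - 10 || derived$topt > tr[2] + 10 ||
    (is.finite(derived$ctmin) && is.finite(derived$ctmax) &&
       (derived$ctmax - derived$ctmin) > 80)
  list(keep = !bad,
       reason = if (bad) "implausible_parameters" else NA_character_)
}

.fitted_tpc <- function(species, form, params, aicc, rss, derived) {
  structure(
    list(species = species, form_name = form$name, form = form,
         params = params, aicc = aicc, rss = rss, converged = TRUE,
         topt = derived$topt, rmax = derived$rmax,
         ctmin = derived$ctmin, ctmax = derived$ctmax, q10 = derived$q10,
         window = derived$window),
    class = "fitted_tpc"
  )
}

#' @export
print.fitted_tpc <- function(x, ...) {
  cat(sprintf(
    "<fitted_tpc> %s: %s (AICc %.2f)\n  rmax=%.4g  Topt=%.2f C  CTmin=%s  CTmax=%s  Q10=%s\n",
    x$species, x$form_name, x$aicc, x$rmax, x$topt,
    ifelse(is.na(x$ctmin), "undef", sprintf("%.2f C", x$ctmin)),
    ifelse(is.na(x$ctmax), "undef", sprintf("%.2f C", x$ctmax)),
    ifelse(is.na(x$q10), "undef", sprintf("%.3f", x$q10))))
  invisible(x)
}

# Selection rule on a per-form score table: minimum AICc among converged,
# plausible fits; ties (within 1e-9) broken by fewer parameters, then by
# registry order.  Returns the selected row index, or NA.
.select_best <- function(table) {
  cand <- which(table$converged & table$plausible & is.finite(table$aicc))
  if (length(cand) == 0) return(NA_integer_)
  amin <- min(table$aicc[cand])
  tied <- cand[table$aicc[cand] <= amin + 1e-9]
  tied <- tied[order(table$n_params[tied], table$registry_order[tied])]
  tied[1]
}

#' Fit every registry form and select the best by AICc
#'
#' Fits all 22 registry forms, derives thermal parameters for each converged
#' fit, applies the plausibility filter, and selects the converged plausible
#' fit with the lowest AICc.  Ties (within 1e-9) are broken by fewer
#' parameters, then by registry order.  Species for which no form converges
#' are excluded with reason `no_convergence`; species where forms converge
#' but none is plausible carry `implausible_parameters`.
#'
#' @param obs A `trait_obs` object.
#' @param registry A `tpc_registry` (default [tpc_forms()]).
#' @param n_starts Starts per form.
#' @param seed Integer seed (each form gets a derived sub-seed).
#' @param correction Use AICc (default) or raw AIC.
#' @return A `model_selection` list: `species`, `table` (one row per form),
#'   `selected` (form name or `NA`), `fit` (a `fitted_tpc` or `NULL`),
#'   `exclusion_reason` (`NA`, `"no_convergence"` or
#'   `"implausible_parameters"`).
#' @export
fit_all_forms <- function(obs, registry = tpc_forms(), n_starts = 10,
                          seed = 1, correction = TRUE) {
  obs <- as_trait_obs(obs)
  tr <- range(obs$temperature)
  rows <- vector("list", length(registry))
  fits <- vector("list", length(registry))
  for (i in seq_along(registry)) {
    form <- registry[[i]]
    res <- fit_single_form(obs, form, n_starts = n_starts,
                           seed = seed + i, correction = correction)
    plausible <- FALSE
    derived <- NULL
    if (res$converged) {
      derived <- derive_parameters(form, res$params, tr)
      plausible <- plausibility_filter(derived, obs)$keep
    }
    rows[[i]] <- data.frame(
      form = form$name, n_params = form$n_params, aicc = res$aicc,
      rss = res$rss, converged = res$converged, plausible = plausible,
      stringsAsFactors = FALSE)
    fits[[i]] <- list(res = res, derived = derived, form = form)
  }
  table <- do.call(rbind, rows)
  table$registry_order <- seq_len(nrow(table))

  sel <- .select_best(table)
  selected <- NA_character_
  fit <- NULL
  reason <- NA_character_
  if (is.na(sel)) {
    reason <- if (!any(table$converged)) "no_convergence"
              else "implausible_parameters"
  } else {
    selected <- table$form[sel]
    fit <- .fitted_tpc(obs$species, fits[[sel]]$form, fits[[sel]]$res$params,
                       fits[[sel]]$res$aicc, fits[[sel]]$res$rss,
                       fits[[sel]]$derived)
  }
  structure(list(species = obs$species, table = table, selected = selected,
                 fit = fit, exclusion_reason = reason),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat(sprintf("<model_selection> %s: ", x$species))
  if (is.na(x$selected)) {
    cat(sprintf("excluded (%s)\n", x$exclusion_reason))
  } else {
    cat(sprintf("selected %s (AICc %.2f), %d/%d forms converged\n",
                x$selected, x$fit$aicc, sum(x$table$converged),
                nrow(x$table)))
  }
  invisible(x)
}

#' Residual-bootstrap confidence intervals for derived thermal parameters
#'
#' Centered residuals from the selected fit are resampled with replacement,
#' added to the fitted values and truncated below at zero; the selected form
#' only is refitted to each resample (single start at the point estimates)
#' and the derived parameters recomputed.  Percentile intervals are taken at
#' the nominal level.  Resamples whose refit fails are dropped and counted;
#' more than 50% failures sets a warning flag.
#'
#' @param obs A `trait_obs`.
#' @param fit The selected `fitted_tpc`.
#' @param n_resamples Number of bootstrap resamples (`>= 100`).
#' @param level Nominal coverage (default 0.95).
#' @param seed Integer seed; results are reproducible under it.
#' @return A `bootstrap_result` list: `species`, `n_resamples`,
#'   `nominal_level`, `intervals` (data.frame parameter/point/low/high),
#'   `n_failed`, `warning`, `seed`, `draws` (matrix of resampled derived
#'   parameters).
#' @export
bootstrap_ci <- function(obs, fit, n_resamples = 500, level = 0.95,
                         seed = 1) {
  obs <- as_trait_obs(obs)
  stopifnot(inherits(fit, "fitted_tpc"), n_resamples >= 100,
            level > 0, level < 1)
  form <- fit$form
  temps <- obs$temperature
  fitted_vals <- form$fun(temps, fit$params)
  resid <- obs$rate - fitted_vals
  resid <- resid - mean(resid)
  tr <- range(temps)

  draws <- .with_seed(seed, {
    out <- matrix(NA_real_, n_resamples, 5,
                  dimnames = list(NULL, c("topt", "rmax", "ctmin", "ctmax",
                                          "q10")))
    for (b in seq_len(n_resamples)) {
      ystar <- pmax(fitted_vals + sample(resid, length(resid), replace = TRUE),
                    0)
      run <- .lm_run(form, temps, ystar, as.numeric(fit$params))
      if (is.null(run)) next
      d <- derive_parameters(form, run$params, tr)
      out[b, ] <- c(d$topt, d$rmax, d$ctmin, d$ctmax, d$q10)
    }
    out
  })

  n_failed <- sum(is.na(draws[, "topt"]))
  alpha <- (1 - level) / 2
  point <- c(topt = fit$topt, rmax = fit$rmax, ctmin = fit$ctmin,
             ctmax = fit$ctmax, q10 = fit$q10)
  intervals <- do.call(rbind, lapply(colnames(draws), function(p) {
    x <- draws[, p]
    x <- x[is.finite(x)]
    if (length(x) == 0) {
      data.frame(parameter = p, point = point[[p]], low = NA_real_,
                 high = NA_real_, stringsAsFactors = FALSE)
    } else {
      q <- stats::quantile(x, c(alpha, 1 - alpha), names = FALSE)
      data.frame(parameter = p, point = point[[p]], low = q[1], high = q[2],
                 stringsAsFactors = FALSE)
    }
  }))
  structure(
    list(species = fit$species, n_resamples = n_resamples,
         nominal_level = level, intervals = intervals,
         n_failed = n_failed, warning = n_failed > n_resamples / 2,
         seed = seed, draws = draws),
    class = "bootstrap_result"
  )
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: %d resamples (%d failed), %.0f%% percentile intervals\n",
              x$species, x$n_resamples, x$n_failed, 100 * x$nominal_level))
  print(x$intervals, row.names = FALSE)
  invisible(x)
}
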