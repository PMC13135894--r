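# Registry of nonlinear thermal-performance-curve (TPC) model forms.
#
# Each form maps temperature (degrees C) to a trait rate given a parameter
# vector in its native parameterization.  Forms are evaluated RAW: several
# (quadratic, Briere, Thomas, Rezende, Deutsch, Spain, Hinshelwood, Lactin)
# can return negative rates outside their thermal window.  Clamping to zero
# is a projection-stage concern, so least-squares fitting sees the true
# functional form.
#
# Registry order is fixed and versioned: it participates in AICc
# tie-breaking (fewer parameters first, then registry order).

# Boltzmann constant in eV/K, and the reference temperature (degrees C) used
# by the Arrhenius-type forms.
.K_BOLTZ <- 8.617333262e-5
.T_REF_C <- 20

.c_to_k <- function(t_c) t_c + 273.15

# exp() with the argument capped so in-bounds parameters can never overflow
# double precision; the cap is far above any biologically sensible exponent.
.exp_safe <- function(x) exp(pmin(x, 300))

new_tpc_form <- function(name, param_names, lower, upper, citation, fun, start) {
  stopifnot(
    length(param_names) == length(lower),
    length(param_names) == length(upper),
    all(lower < upper)
  )
  structure(
    list(
      name = name,
      n_params = length(param_names),
      param_names = param_names,
      lower = lower,
      upper = upper,
      citation = citation,
      fun = fun,
      start = start
    ),
    class = "tpc_form"
  )
}

#' @export
print.tpc_form <- function(x, ...) {
  cat(sprintf(
    "<tpc_form> %s (%d params: %s)\n  %s\n",
    x$name, x$n_params, paste(x$param_names, collapse = ", "), x$citation
  ))
  invisible(x)
}

# Summary statistics of an observation set used by start-value heuristics.
# Tie-break for the observed optimum: lowest qualifying temperature.
.obs_summary <- function(obs) {
  tt <- obs$temperature
  rr <- obs$rate
  i_max <- which(rr == max(rr))
  topt0 <- min(tt[i_max])
  list(
    rmax0 = max(rr),
    topt0 = topt0,
    tmin = min(tt),
    tmax = max(tt),
    span = max(diff(range(tt)), 1)
  )
}

.registry_builders <- list(

  quadratic = function() new_tpc_form(
    name = "quadratic",
    param_names = c("a", "b", "c"),
    lower = c(-1e6, -1e6, -1e6),
    upper = c(1e6, 1e6, 1e6),
    citation = "Second-order polynomial rate model (e.g. Montagnes et al. 2008)",
    fun = function(temp, p) p[1] + p[2] * temp + p[3] * temp^2,
    start = function(obs) {
      s <- .obs_summary(obs)
      if (length(unique(obs$temperature)) >= 3) {
        cf <- stats::coef(stats::lm(rate ~ temperature + I(temperature^2),
                                    data = data.frame(temperature = obs$temperature,
                                                      rate = obs$rate)))
        cf[is.na(cf)] <- 0
        as.numeric(cf)
      } else {
        cc <- -s$rmax0 / (s$span / 2)^2
        c(s$rmax0 + cc * s$topt0^2, -2 * cc * s$topt0, cc)
      }
    }
  ),

  gaussian = function() new_tpc_form(
    name = "gaussian",
    param_names = c("rmax", "topt", "a"),
    lower = c(1e-10, -100, 1e-2),
    upper = c(1e6, 150, 100),
    citation = "Gaussian thermal response (Lynch & Gabriel 1987)",
    fun = function(temp, p) p[1] * exp(-0.5 * ((temp - p[2]) / p[3])^2),
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0, s$topt0, s$span / 4)
    }
  ),

  modifiedgaussian = function() new_tpc_form(
    name = "modifiedgaussian",
    param_names = c("rmax", "topt", "a", "b"),
    lower = c(1e-10, -100, 1e-2, 0.1),
    upper = c(1e6, 150, 100, 10),
    citation = "Gaussian with free shape exponent (Angilletta 2006)",
    fun = function(temp, p) p[1] * exp(-0.5 * (abs(temp - p[2]) / p[3])^p[4]),
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0, s$topt0, s$span / 4, 2)
    }
  ),

  briere1 = function() new_tpc_form(
    name = "briere1",
    param_names = c("a", "tmin", "tmax"),
    lower = c(1e-8, -100, -99),
    upper = c(10, 149, 150),
    citation = "Briere et al. 1999, model 1",
    fun = function(temp, p) {
      p[1] * temp * (temp - p[2]) * sqrt(pmax(p[3] - temp, 0))
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      tmin0 <- s$tmin - 5
      tmax0 <- s$tmax + 5
      shape <- s$topt0 * (s$topt0 - tmin0) * sqrt(max(tmax0 - s$topt0, 1e-6))
      c(s$rmax0 / max(abs(shape), 1e-6), tmin0, tmax0)
    }
  ),

  briere2 = function() new_tpc_form(
    name = "briere2",
    param_names = c("a", "tmin", "tmax", "b"),
    lower = c(1e-8, -100, -99, 0.3),
    upper = c(10, 149, 150, 10),
    citation = "Briere et al. 1999, model 2 (free root exponent)",
    fun = function(temp, p) {
      p[1] * temp * (temp - p[2]) * pmax(p[3] - temp, 0)^(1 / p[4])
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      tmin0 <- s$tmin - 5
      tmax0 <- s$tmax + 5
      shape <- s$topt0 * (s$topt0 - tmin0) * max(tmax0 - s$topt0, 1e-6)^(1 / 2)
      c(s$rmax0 / max(abs(shape), 1e-6), tmin0, tmax0, 2)
    }
  ),

  lactin2 = function() new_tpc_form(
    name = "lactin2",
    param_names = c("a", "b", "tmax", "dt"),
    lower = c(1e-4, -1e3, -99, 0.05),
    upper = c(0.5, 1e3, 150, 60),
    citation = "Lactin et al. 1995, two-parameter extension",
    fun = function(temp, p) {
      .exp_safe(p[1] * temp) -
        .exp_safe(p[1] * p[3] - (p[3] - temp) / p[4]) + p[2]
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(0.1, -0.2, s$tmax + 2, s$span / 8)
    }
  ),

  ratkowsky = function() new_tpc_form(
    name = "ratkowsky",
    param_names = c("a", "b", "tmin", "tmax"),
    lower = c(1e-6, 1e-4, -100, -99),
    upper = c(10, 1, 149, 150),
    citation = "Ratkowsky et al. 1983 (square-root model)",
    fun = function(temp, p) {
      (p[1] * (temp - p[3]) * (1 - exp(p[2] * (temp - p[4]))))^2
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      tmin0 <- s$tmin - 5
      c(sqrt(s$rmax0) / max(s$topt0 - tmin0, 1), 0.1, tmin0, s$tmax + 2)
    }
  ),

  sharpeschoolfull = function() new_tpc_form(
    name = "sharpeschoolfull",
    param_names = c("rtref", "e", "el", "tl", "eh", "th"),
    lower = c(1e-10, 0.05, 0.1, -80, 0.1, -79),
    upper = c(1e6, 4, 15, 140, 20, 150),
    citation = "Sharpe & DeMichele 1977 / Schoolfield et al. 1981, full model",
    fun = function(temp, p) {
      tk <- .c_to_k(temp)
      tref <- .c_to_k(.T_REF_C)
      num <- p[1] * exp(-p[2] / .K_BOLTZ * (1 / tk - 1 / tref))
      den <- 1 +
        .exp_safe(-p[3] / .K_BOLTZ * (1 / .c_to_k(p[4]) - 1 / tk)) +
        .exp_safe(p[5] / .K_BOLTZ * (1 / .c_to_k(p[6]) - 1 / tk))
      num / den
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0 / 2, 0.6, 2, s$tmin + 0.2 * s$span, 5, s$tmax - 0.1 * s$span)
    }
  ),

  sharpeschoolhigh = function() new_tpc_form(
    name = "sharpeschoolhigh",
    param_names = c("rtref", "e", "eh", "th"),
    lower = c(1e-10, 0.05, 0.1, -79),
    upper = c(1e6, 4, 20, 150),
    citation = "Schoolfield et al. 1981, high-temperature inactivation only",
    fun = function(temp, p) {
      tk <- .c_to_k(temp)
      tref <- .c_to_k(.T_REF_C)
      num <- p[1] * exp(-p[2] / .K_BOLTZ * (1 / tk - 1 / tref))
      den <- 1 + .exp_safe(p[3] / .K_BOLTZ * (1 / .c_to_k(p[4]) - 1 / tk))
      num / den
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0 / 2, 0.6, 5, s$tmax - 0.1 * s$span)
    }
  ),

  sharpeschoollow = function() new_tpc_form(
    name = "sharpeschoollow",
    param_names = c("rtref", "e", "el", "tl"),
    lower = c(1e-10, 0.05, 0.1, -80),
    upper = c(1e6, 4, 15, 140),
    citation = "Schoolfield et al. 1981, low-temperature inactivation only",
    fun = function(temp, p) {
      tk <- .c_to_k(temp)
      tref <- .c_to_k(.T_REF_C)
      num <- p[1] * exp(-p[2] / .K_BOLTZ * (1 / tk - 1 / tref))
      den <- 1 + .exp_safe(-p[3] / .K_BOLTZ * (1 / .c_to_k(p[4]) - 1 / tk))
      num / den
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0 / 2, 0.6, 2, s$tmin + 0.2 * s$span)
    }
  ),

  weibull = function() new_tpc_form(
    name = "weibull",
    param_names = c("a", "topt", "b", "c"),
    lower = c(1e-10, -100, 0.5, 1.01),
    upper = c(1e6, 150, 300, 30),
    citation = "Weibull-type TPC (Angilletta 2006)",
    fun = function(temp, p) {
      cc <- p[4]
      k1 <- ((cc - 1) / cc)
      z <- (temp - p[2]) / p[3] + k1^(1 / cc)
      out <- numeric(length(temp))
      pos <- z > 0
      zp <- z[pos]
      out[pos] <- p[1] * k1^((1 - cc) / cc) * zp^(cc - 1) *
        exp(-zp^cc + k1)
      out
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0, s$topt0, s$span / 2, 3)
    }
  ),

  thomas1 = function() new_tpc_form(
    name = "thomas1",
    param_names = c("a", "b", "topt", "w"),
    lower = c(1e-10, 0, -100, 1),
    upper = c(1e6, 0.5, 150, 120),
    citation = "Thomas et al. 2012 (exponential-quadratic)",
    fun = function(temp, p) {
      p[1] * exp(p[2] * temp) * (1 - ((temp - p[3]) / (p[4] / 2))^2)
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      b0 <- 0.05
      c(s$rmax0 / exp(b0 * s$topt0), b0, s$topt0, s$span * 1.2)
    }
  ),

  logan6 = function() new_tpc_form(
    name = "logan6",
    param_names = c("a", "b", "tmax", "dt"),
    lower = c(1e-10, 1e-4, -99, 0.05),
    upper = c(1e6, 0.5, 150, 60),
    citation = "Logan et al. 1976, model 6",
    fun = function(temp, p) {
      p[1] * (.exp_safe(p[2] * temp) -
                .exp_safe(p[2] * p[3] - (p[3] - temp) / p[4]))
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      b0 <- 0.1
      tmax0 <- s$tmax + 2
      dt0 <- max(s$span / 10, 0.5)
      shape <- exp(b0 * s$topt0) - exp(b0 * tmax0 - (tmax0 - s$topt0) / dt0)
      c(s$rmax0 / max(abs(shape), 1e-6), b0, tmax0, dt0)
    }
  ),

  rezende = function() new_tpc_form(
    name = "rezende",
    param_names = c("a", "q10", "tth", "c"),
    lower = c(1e-10, 1.01, -100, 1e-6),
    upper = c(1e6, 10, 150, 10),
    citation = "Rezende & Bozinovic 2019 (Q10-rise with quadratic decline)",
    fun = function(temp, p) {
      rise <- p[1] * 10^(log10(p[2]) * temp / 10)
      rise * (1 - p[4] * pmax(temp - p[3], 0)^2)
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      q0 <- 2.5
      c(s$rmax0 / 10^(log10(q0) * s$topt0 / 10), q0, s$topt0, 0.01)
    }
  ),

  oneill = function() new_tpc_form(
    name = "oneill",
    param_names = c("rmax", "ctmax", "topt", "q10"),
    lower = c(1e-10, -90, -100, 1.01),
    upper = c(1e6, 150, 149, 10),
    citation = "O'Neill et al. 1972",
    fun = function(temp, p) {
      d <- p[2] - p[3]
      if (d <= 0) return(numeric(length(temp)))
      w <- (p[4] - 1) * d
      x <- (w^2 / 400) * (1 + sqrt(1 + 40 / w))^2
      out <- numeric(length(temp))
      ok <- temp < p[2]
      ratio <- (p[2] - temp[ok]) / d
      # log-space: exponent <= 0 for all temp < ctmax, so never overflows
      out[ok] <- p[1] * exp(x * (log(ratio) + (temp[ok] - p[3]) / d))
      out
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0, s$tmax + 3, s$topt0, 2.5)
    }
  ),

  johnsonlewin = function() new_tpc_form(
    name = "johnsonlewin",
    param_names = c("r0", "e", "eh", "topt"),
    lower = c(1e-10, 0.05, 2.001, -100),
    upper = c(1e30, 2, 20, 150),
    citation = "Johnson & Lewin 1946",
    fun = function(temp, p) {
      tk <- .c_to_k(temp)
      toptk <- .c_to_k(p[4])
      m <- p[3] / toptk + .K_BOLTZ * log(p[2] / (p[3] - p[2]))
      num <- p[1] * exp(-p[2] / (.K_BOLTZ * tk))
      den <- 1 + .exp_safe(-(p[3] - m * tk) / (.K_BOLTZ * tk))
      num / den
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      e0 <- 0.6
      c(2 * s$rmax0 * exp(e0 / (.K_BOLTZ * .c_to_k(s$topt0))), e0, 5, s$topt0)
    }
  ),

  flinn = function() new_tpc_form(
    name = "flinn",
    param_names = c("a", "b", "c"),
    lower = c(-100, -10, -1),
    upper = c(100, 10, 1),
    citation = "Flinn 1991 (logistic-quadratic)",
    fun = function(temp, p) {
      1 / (1 + .exp_safe(p[1] + p[2] * temp + p[3] * temp^2))
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c0 <- 0.02
      b0 <- -2 * c0 * s$topt0
      qmin <- if (s$rmax0 < 1) log(1 / s$rmax0 - 1) else -5
      c(qmin + c0 * s$topt0^2, b0, c0)
    }
  ),

  joehnk = function() new_tpc_form(
    name = "joehnk",
    param_names = c("rmax", "topt", "a", "b", "c"),
    lower = c(1e-10, -100, 0, 1.0001, 1.0002),
    upper = c(1e6, 150, 50, 2, 3),
    citation = "Joehnk et al. 2008",
    fun = function(temp, p) {
      u <- temp - p[2]
      p[1] * (1 + p[3] * ((p[4]^u - 1) - (log(p[4]) / log(p[5])) * (p[5]^u - 1)))
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0, s$topt0, 2, 1.1, 1.15)
    }
  ),

  boatman = function() new_tpc_form(
    name = "boatman",
    param_names = c("rmax", "tmin", "tmax", "a", "b"),
    lower = c(1e-10, -100, -99, 0.1, 0.1),
    upper = c(1e6, 149, 150, 5, 10),
    citation = "Boatman et al. 2017",
    fun = function(temp, p) {
      s <- pmin(pmax((temp - p[2]) / (p[3] - p[2]), 0), 1)
      p[1] * sin(pi * s^p[4])^p[5]
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      tmin0 <- s$tmin - 5
      tmax0 <- s$tmax + 5
      sopt <- min(max((s$topt0 - tmin0) / (tmax0 - tmin0), 0.05), 0.95)
      a0 <- min(max(log(0.5) / log(sopt), 0.2), 4)
      c(s$rmax0, tmin0, tmax0, a0, 1)
    }
  ),

  spain = function() new_tpc_form(
    name = "spain",
    param_names = c("r0", "a", "b", "c"),
    lower = c(1e-10, -0.5, 1e-10, -0.5),
    upper = c(1e6, 0.5, 10, 0.5),
    citation = "Spain 1982",
    fun = function(temp, p) {
      p[1] * exp(p[2] * temp) * (1 - p[3] * exp(p[4] * temp))
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      a0 <- 0.1
      c0 <- 0.15
      b0 <- exp(-c0 * (s$tmax + 3))
      denom <- exp(a0 * s$topt0) * (1 - b0 * exp(c0 * s$topt0))
      c(s$rmax0 / max(abs(denom), 1e-6), a0, b0, c0)
    }
  ),

  deutsch = function() new_tpc_form(
    name = "deutsch",
    param_names = c("rmax", "topt", "ctmax", "a"),
    lower = c(1e-10, -100, -99, 0.5),
    upper = c(1e6, 149, 150, 60),
    citation = "Deutsch et al. 2008 (Gaussian rise, quadratic fall)",
    fun = function(temp, p) {
      d <- p[3] - p[2]
      out <- numeric(length(temp))
      lo <- temp <= p[2]
      out[lo] <- p[1] * exp(-((temp[lo] - p[2]) / (2 * p[4]))^2)
      if (d > 1e-8) {
        out[!lo] <- p[1] * (1 - ((temp[!lo] - p[2]) / d)^2)
      }
      out
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(s$rmax0, s$topt0, s$tmax + 3, s$span / 3)
    }
  ),

  hinshelwood = function() new_tpc_form(
    name = "hinshelwood",
    param_names = c("a", "e", "b", "eh"),
    lower = c(1e-10, 0.05, 1e-12, 0.1),
    upper = c(1e6, 5, 1e6, 20),
    citation = "Hinshelwood 1947 (two Arrhenius terms, centered at 20 C)",
    fun = function(temp, p) {
      tk <- .c_to_k(temp)
      tref <- .c_to_k(.T_REF_C)
      p[1] * exp(-(p[2] / .K_BOLTZ) * (1 / tk - 1 / tref)) -
        p[3] * exp(-(p[4] / .K_BOLTZ) * (1 / tk - 1 / tref))
    },
    start = function(obs) {
      s <- .obs_summary(obs)
      c(2 * s$rmax0, 0.6, s$rmax0 / 2, 5)
    }
  )
)

#' List the registry of TPC model forms
#'
#' Returns the fixed, ordered registry of the 22 nonlinear thermal performance
#' curve forms scored during model selection.  Each form carries its
#' parameter names, box bounds, a literature citation, an evaluation function
#' and a start-value heuristic.  The order is part of the package contract:
#' AICc ties are broken by fewer parameters first, then by registry order.
#'
#' @return A named list of `tpc_form` objects, class `tpc_registry`.
#' @export
#' @examples
#' reg <- tpc_forms()
#' length(reg)          # 22
#' names(reg)[1:4]
tpc_forms <- function() {
  reg <- lapply(.registry_builders, function(b) b())
  structure(reg, class = "tpc_registry")
}

#' @export
print.tpc_registry <- function(x, ...) {
  cat(sprintf("<tpc_registry> %d model forms\n", length(x)))
  for (f in x) {
    cat(sprintf("  %-18s k=%d  %s\n", f$name, f$n_params, f$citation))
  }
  invisible(x)
}

#' Retrieve a single model form by name
#'
#' @param name Form identifier (see `names(tpc_forms())`).
#' @return A `tpc_form` object.
#' @export
tpc_form <- function(name) {
  reg <- tpc_forms()
  if (!name %in% names(reg)) {
    stop(sprintf("unknown TPC model form '%s'; see names(tpc_forms())", name),
         call. = FALSE)
  }
  reg[[name]]
}

#' Evaluate a model form at given temperatures
#'
#' Evaluates the raw functional form: no clamping at zero and no truncation
#' outside thermal limits (that is a projection concern, see
#' [predict_rate()]).
#'
#' @param form A `tpc_form` object.
#' @param params Numeric parameter vector of length `form$n_params`.
#' @param temperature Numeric vector of temperatures (degrees C).
#' @return Numeric vector of rates, same length as `temperature`.
#' @export
#' @examples
#' f <- tpc_form("gaussian")
#' evaluate_form(f, c(rmax = 2, topt = 15, a = 4), 15)  # 2
evaluate_form <- function(form, params, temperature) {
  stopifnot(inherits(form, "tpc_form"))
  params <- as.numeric(params)
  if (length(params) != form$n_params) {
    stop(sprintf("form '%s' expects %d parameters, got %d",
                 form$name, form$n_params, length(params)), call. = FALSE)
  }
  out <- rep(NA_real_, length(temperature))
  ok <- is.finite(temperature)
  if (any(ok)) out[ok] <- form$fun(temperature[ok], params)
  out
}

#' Heuristic start values for a model form
#'
#' Initial parameter values derived from the observations (peak rate, its
#' temperature, the observed temperature span), clipped into the form's box
#' bounds.  When the maximum observed rate is tied across temperatures, the
#' lowest qualifying temperature is used.
#'
#' @param form A `tpc_form` object.
#' @param obs A `trait_obs` object (see [trait_observations()]).
#' @return Named numeric vector of length `form$n_params`, within bounds.
#' @export
start_values <- function(form, obs) {
  stopifnot(inherits(form, "tpc_form"))
  obs <- as_trait_obs(obs)
  if (length(obs$temperature) == 0) {
    stop("cannot compute start values from empty observations", call. = FALSE)
  }
  p0 <- as.numeric(form$start(obs))
  p0[!is.finite(p0)] <- (form$lower + form$upper)[!is.finite(p0)] / 2
  p0 <- pmin(pmax(p0, form$lower), form$upper)
  stats::setNames(p0, form$param_names)
}
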