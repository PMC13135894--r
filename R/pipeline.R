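# File formats, configuration and the end-to-end pipeline driver:
# filter -> fit/select -> bootstrap -> project (baseline, future) ->
# classify -> change/priority, with a machine-readable run report.

#' Read and validate a trait CSV table
#'
#' Expects a header `species, realm, trait, temperature_C, rate`, decimal
#' points (not commas) and realm values restricted to the three realms.
#' Schema violations are reported with the offending row number.
#'
#' @param path CSV file path.
#' @return data.frame of typed rows.
#' @export
#' @examples
#' path <- system.file("extdata", "example_traits.csv", package = "thermshift")
#' head(read_trait_table(path))
read_trait_table <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  req <- c("species", "realm", "trait", "temperature_C", "rate")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("trait table %s is missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad_realm <- which(!raw$realm %in% .REALMS)
  if (length(bad_realm) > 0) {
    stop(sprintf("unknown realm '%s' at row %d (expected %s)",
                 raw$realm[bad_realm[1]], bad_realm[1],
                 paste(.REALMS, collapse = "|")), call. = FALSE)
  }
  temp <- suppressWarnings(as.numeric(raw$temperature_C))
  bad_t <- which(is.na(temp) & !is.na(raw$temperature_C) &
                   nzchar(raw$temperature_C))
  if (length(bad_t) > 0) {
    stop(sprintf("non-numeric temperature_C '%s' at row %d",
                 raw$temperature_C[bad_t[1]], bad_t[1]), call. = FALSE)
  }
  rate <- suppressWarnings(as.numeric(raw$rate))
  bad_r <- which(is.na(rate) & !is.na(raw$rate) & nzchar(raw$rate))
  if (length(bad_r) > 0) {
    stop(sprintf("non-numeric rate '%s' at row %d", raw$rate[bad_r[1]],
                 bad_r[1]), call. = FALSE)
  }
  data.frame(species = raw$species, realm = raw$realm, trait = raw$trait,
             temperature_C = temp, rate = rate, stringsAsFactors = FALSE)
}

#' Write a trait table as CSV
#'
#' Numeric columns are written with six significant digits so identical
#' configurations and seeds reproduce byte-identical files.
#'
#' @param traits data.frame with the standard trait columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trait_table <- function(traits, path) {
  out <- traits
  out$temperature_C <- signif(out$temperature_C, 6)
  out$rate <- signif(out$rate, 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' All stages read their options from this object; the seed is mandatory for
#' every stochastic stage.  `traits`, `baseline` and `future` may be file
#' paths (trait CSV, monthly-stack directories) or in-memory objects
#' (data.frame, `temp_grid_stack`).
#'
#' @param traits Trait table (path or data.frame).
#' @param baseline,future Monthly climate stacks (paths or
#'   `temp_grid_stack`).
#' @param out_dir Output directory, or `NULL` to skip writing artifacts.
#' @param n_starts Multi-start count for fitting.
#' @param boot Bootstrap resamples (0 disables the bootstrap stage).
#' @param level Nominal bootstrap coverage.
#' @param seed Integer seed.
#' @param aic `"aicc"` (default, small-sample corrected) or `"aic"`.
#' @param high_threshold,low_threshold Priority cutoffs (percent).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(traits, baseline, future, out_dir = NULL,
                            n_starts = 10, boot = 200, level = 0.95,
                            seed = 1, aic = c("aicc", "aic"),
                            high_threshold = 20, low_threshold = 5) {
  aic <- match.arg(aic)
  if (is.null(seed) || !is.finite(seed)) {
    stop("a seed is mandatory for the stochastic stages", call. = FALSE)
  }
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)", call. = FALSE)
  if (boot != 0 && boot < 100) {
    stop("boot must be 0 (disabled) or >= 100 resamples", call. = FALSE)
  }
  if (low_threshold <= 0 || low_threshold >= high_threshold) {
    stop("thresholds must satisfy 0 < low_threshold < high_threshold",
         call. = FALSE)
  }
  for (nm in c("traits", "baseline", "future")) {
    x <- get(nm)
    if (is.character(x) && !file.exists(x)) {
      stop(sprintf("%s path does not exist: %s", nm, x), call. = FALSE)
    }
  }
  structure(
    list(traits = traits, baseline = baseline, future = future,
         out_dir = out_dir, n_starts = n_starts, boot = boot, level = level,
         seed = as.integer(seed), aic = aic,
         high_threshold = high_threshold, low_threshold = low_threshold),
    class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `traits`, `baseline`
#' and `future` must be paths.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

.stage <- function(stage, species = NULL, expr) {
  tryCatch(expr, error = function(e) {
    ctx <- if (is.null(species)) stage else sprintf("%s [%s]", stage, species)
    stop(sprintf("pipeline stage '%s' failed: %s", ctx, conditionMessage(e)),
         call. = FALSE)
  })
}

.resolve_stack <- function(x, what) {
  if (inherits(x, "temp_grid_stack")) return(x)
  .stage(paste0("read_", what), NULL, read_monthly_stack(x))
}

#' Run the end-to-end feeding-suitability pipeline
#'
#' Executes filtering, per-species model fitting and selection, optional
#' bootstrap, baseline and future THS projection with realm masking,
#' classification, and the change/priority analysis.  Every input species
#' appears exactly once in the report, either fitted or excluded with a
#' reason.  Identical configuration and seed reproduce identical outputs.
#'
#' @param config A `pipeline_config`.
#' @return A `pipeline_report` list: `species` (one summary row per input
#'   species), `selections`, `bootstraps`, `ths` (per species: baseline and
#'   future `ths_grid`), `summaries` (`change_summary` per fitted species),
#'   `config` echo and package version.  If `config$out_dir` is set, also
#'   writes the fit report CSV, change-summary CSV, bootstrap-interval JSON,
#'   THS grids (`.asc`) and a JSON run report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  baseline <- .resolve_stack(config$baseline, "baseline")
  future <- .resolve_stack(config$future, "future")
  .stage("validate_climate", NULL, .check_aligned(baseline, future,
         "baseline and future climate stacks"))

  traits <- if (is.character(config$traits)) {
    .stage("read_traits", NULL, read_trait_table(config$traits))
  } else {
    config$traits
  }
  filt <- .stage("filter", NULL, filter_observations(traits))

  species_rows <- list()
  selections <- list()
  bootstraps <- list()
  ths_grids <- list()
  summaries <- list()

  for (sp in filt$excluded$species) {
    species_rows[[sp]] <- data.frame(
      species = sp, realm = traits$realm[match(sp, traits$species)],
      status = "excluded",
      reason = filt$excluded$reason[filt$excluded$species == sp],
      selected_form = NA_character_, aicc = NA_real_, rmax = NA_real_,
      topt = NA_real_, ctmin = NA_real_, ctmax = NA_real_, q10 = NA_real_,
      range_expanding = NA, priority = NA_character_,
      stringsAsFactors = FALSE)
  }

  sp_index <- 0L
  for (sp in names(filt$observations)) {
    sp_index <- sp_index + 1L
    obs <- filt$observations[[sp]]
    sel <- .stage("fit", sp, fit_all_forms(
      obs, n_starts = config$n_starts,
      seed = config$seed + 100L * sp_index,
      correction = config$aic == "aicc"))
    selections[[sp]] <- sel

    if (is.na(sel$selected)) {
      species_rows[[sp]] <- data.frame(
        species = sp, realm = obs$realm, status = "excluded",
        reason = sel$exclusion_reason, selected_form = NA_character_,
        aicc = NA_real_, rmax = NA_real_, topt = NA_real_, ctmin = NA_real_,
        ctmax = NA_real_, q10 = NA_real_, range_expanding = NA,
        priority = NA_character_, stringsAsFactors = FALSE)
      next
    }
    fit <- sel$fit

    if (config$boot > 0) {
      bootstraps[[sp]] <- .stage("bootstrap", sp, bootstrap_ci(
        obs, fit, n_resamples = config$boot, level = config$level,
        seed = config$seed + 100L * sp_index + 1L))
    }

    ths_b <- .stage("project_baseline", sp,
                    project_annual_ths(fit, baseline, obs$realm))
    ths_f <- .stage("project_future", sp,
                    project_annual_ths(fit, future, obs$realm))
    ths_grids[[sp]] <- list(baseline = ths_b, future = ths_f)

    summ <- .stage("change", sp, change_summary(
      sp, ths_b, ths_f, config$high_threshold, config$low_threshold))
    summaries[[sp]] <- summ

    species_rows[[sp]] <- data.frame(
      species = sp, realm = obs$realm, status = "fitted",
      reason = NA_character_, selected_form = fit$form_name,
      aicc = fit$aicc, rmax = fit$rmax, topt = fit$topt, ctmin = fit$ctmin,
      ctmax = fit$ctmax, q10 = fit$q10,
      range_expanding = summ$range_expanding, priority = summ$priority,
      stringsAsFactors = FALSE)
  }

  report <- structure(
    list(species = do.call(rbind, unname(species_rows)),
         selections = selections, bootstraps = bootstraps,
         ths = ths_grids, summaries = summaries,
         seed = config$seed, aic = config$aic,
         thresholds = c(low = config$low_threshold,
                        high = config$high_threshold),
         package_version = as.character(utils::packageVersion("thermshift"))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) {
    .write_pipeline_artifacts(report, config)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> %d species (%d fitted, %d excluded), seed %d\n",
              nrow(x$species), sum(x$species$status == "fitted"),
              sum(x$species$status == "excluded"), x$seed))
  print(x$species[c("species", "realm", "status", "selected_form",
                    "range_expanding", "priority")], row.names = FALSE)
  invisible(x)
}

.signif_df <- function(df, digits = 6) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], digits)
  }
  df
}

.write_pipeline_artifacts <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(.signif_df(report$species),
                   file.path(config$out_dir, "fit_report.csv"),
                   row.names = FALSE, quote = FALSE)

  class_rows <- lapply(report$summaries, function(s) {
    cbind(data.frame(species = s$species, stringsAsFactors = FALSE),
          s$classes)
  })
  if (length(class_rows) > 0) {
    utils::write.csv(.signif_df(do.call(rbind, unname(class_rows))),
                     file.path(config$out_dir, "class_changes.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if (length(report$bootstraps) > 0) {
    boot <- lapply(report$bootstraps, function(b) {
      list(n_resamples = b$n_resamples, nominal_level = b$nominal_level,
           n_failed = b$n_failed, warning = b$warning,
           intervals = .signif_df(b$intervals))
    })
    jsonlite::write_json(boot,
                         file.path(config$out_dir, "bootstrap_intervals.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ths_dir <- file.path(config$out_dir, "ths")
  dir.create(ths_dir, showWarnings = FALSE)
  for (sp in names(report$ths)) {
    for (scen in c("baseline", "future")) {
      g <- report$ths[[sp]][[scen]]
      write_ascii_grid(g$values, g$lat, g$lon,
                       file.path(ths_dir, sprintf("%s_%s.asc", sp, scen)))
    }
  }

  run <- list(
    seed = report$seed, aic = report$aic,
    thresholds = as.list(report$thresholds),
    package_version = report$package_version,
    species = lapply(seq_len(nrow(report$species)), function(i) {
      as.list(.signif_df(report$species[i, ]))
    }))
  jsonlite::write_json(run, file.path(config$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(config$out_dir)
}
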