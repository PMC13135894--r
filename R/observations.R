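# Trait observation container and the data-quality filter applied before
# curve fitting.

.REALMS <- c("freshwater", "marine", "terrestrial")

#' Construct a trait observation set
#'
#' One species' (temperature, rate) measurements for a feeding-related trait,
#' with realm metadata.  Rates must be non-negative (negative measured rates
#' are a data-quality failure and are removed upstream by
#' [filter_observations()]).
#'
#' @param species Species identifier.
#' @param realm One of `"freshwater"`, `"marine"`, `"terrestrial"`.
#' @param trait Trait name (e.g. `"ingestion_rate"`).
#' @param temperature Numeric vector, degrees C.
#' @param rate Numeric vector of trait values, same length, `>= 0`.
#' @return A `trait_obs` object.
#' @export
trait_observations <- function(species, realm, trait, temperature, rate) {
  realm <- match.arg(realm, .REALMS)
  temperature <- as.numeric(temperature)
  rate <- as.numeric(rate)
  if (length(temperature) != length(rate)) {
    stop("temperature and rate must have the same length", call. = FALSE)
  }
  if (anyNA(temperature) || anyNA(rate)) {
    stop("missing temperature or rate values; run filter_observations() first",
         call. = FALSE)
  }
  if (any(rate < 0)) {
    stop("negative rates are not allowed; run filter_observations() first",
         call. = FALSE)
  }
  structure(
    list(species = as.character(species), realm = realm,
         trait = as.character(trait),
         temperature = temperature, rate = rate),
    class = "trait_obs"
  )
}

as_trait_obs <- function(x) {
  if (inherits(x, "trait_obs")) return(x)
  stop("expected a 'trait_obs' object; see trait_observations()", call. = FALSE)
}

#' @export
print.trait_obs <- function(x, ...) {
  cat(sprintf("<trait_obs> %s (%s, %s): %d points over %.1f-%.1f C\n",
              x$species, x$realm, x$trait, length(x$temperature),
              min(x$temperature), max(x$temperature)))
  invisible(x)
}

#' Number of distinct test temperatures in an observation set
#' @param obs A `trait_obs` object.
#' @return Integer count.
#' @export
n_distinct_temperatures <- function(obs) {
  length(unique(as_trait_obs(obs)$temperature))
}

#' Quality-filter a raw trait table into per-species observation sets
#'
#' Applies the data-quality rules used before any fitting: rows with missing
#' temperature or rate are dropped, negative rates (unrealistic performance
#' values) are dropped, exact duplicate (species, temperature, rate) rows are
#' collapsed to one, and species left with fewer than four distinct test
#' temperatures are flagged `insufficient_data` (fewer cannot identify a
#' four-parameter curve).
#'
#' @param raw A data.frame with columns `species`, `realm`, `trait`,
#'   `temperature_C`, `rate`.
#' @return A list with elements:
#'   \describe{
#'     \item{observations}{named list of `trait_obs`, one per retained species}
#'     \item{excluded}{data.frame (`species`, `reason`) for species dropped
#'       with reason `insufficient_data`}
#'     \item{n_rows_dropped}{rows removed by the missing/negative/duplicate
#'       rules}
#'   }
#' @export
filter_observations <- function(raw) {
  req <- c("species", "realm", "trait", "temperature_C", "rate")
  missing_cols <- setdiff(req, names(raw))
  if (length(missing_cols) > 0) {
    stop(sprintf("trait table is missing required column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  raw <- as.data.frame(raw)[req]
  n0 <- nrow(raw)
  keep <- !is.na(raw$temperature_C) & !is.na(raw$rate) & raw$rate >= 0
  raw <- raw[keep, , drop = FALSE]
  raw <- raw[!duplicated(raw[c("species", "temperature_C", "rate")]), ,
             drop = FALSE]

  observations <- list()
  excluded <- data.frame(species = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  for (sp in unique(raw$species)) {
    sub <- raw[raw$species == sp, , drop = FALSE]
    if (length(unique(sub$temperature_C)) < 4) {
      excluded <- rbind(excluded, data.frame(
        species = sp, reason = "insufficient_data", stringsAsFactors = FALSE))
      next
    }
    observations[[sp]] <- trait_observations(
      species = sp, realm = sub$realm[1], trait = sub$trait[1],
      temperature = sub$temperature_C, rate = sub$rate)
  }
  list(observations = observations, excluded = excluded,
       n_rows_dropped = n0 - nrow(raw))
}
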