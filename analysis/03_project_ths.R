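#!/usr/bin/env Rscript
# Stage 3: project Thermal Habitat Suitability.
#
# Re-derives each species' selected curve (same seeds as stage 2, so fits
# are identical), evaluates THS = FR_t / FR_opt cell-wise for each of the
# twelve monthly layers in both scenarios, averages to annual means, and
# applies realm masking (marine species to sea cells, freshwater and
# terrestrial to land).  One ASCII raster per species and scenario.

suppressPackageStartupMessages(library(thermshift))

SEED <- 20260923L
traits <- read_trait_table("results/study/traits.csv")
baseline <- read_monthly_stack("results/study/baseline")
future <- read_monthly_stack("results/study/future")
dir.create("results/ths", recursive = TRUE, showWarnings = FALSE)

filt <- filter_observations(traits)
n_written <- 0
for (i in seq_along(filt$observations)) {
  obs <- filt$observations[[i]]
  sel <- fit_all_forms(obs, n_starts = 10, seed = SEED + 100L * i)
  if (is.na(sel$selected)) next
  for (scen in c("baseline", "future")) {
    stack <- get(scen)
    g <- project_annual_ths(sel$fit, stack, obs$realm)
    write_ascii_grid(g$values, g$lat, g$lon,
                     sprintf("results/ths/%s_%s.asc", obs$species, scen))
    n_written <- n_written + 1
  }
  g_b <- read_ascii_grid(sprintf("results/ths/%s_baseline.asc", obs$species))
  cat(sprintf("%-18s mean annual THS (baseline) %.3f over %d %s cells\n",
              obs$species, mean(g_b$values, na.rm = TRUE),
              sum(!is.na(g_b$values)), obs$realm))
}
cat(sprintf("wrote %d THS rasters to results/ths/\n", n_written))
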