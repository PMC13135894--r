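#!/usr/bin/env Rscript
# Stage 4: scenario comparison and monitoring priorities.
#
# Reads the per-species annual THS rasters from stage 3, classifies them
# into the five suitability classes (Minimal ... Massive), computes
# area-weighted extent changes per class, the per-cell suitability change,
# the THS >= 0.6 range-expansion flag, and the screening priority (cutoffs
# 5% and 20% change in qualifying extent).  Ends with the species-by-status
# concern matrix.

suppressPackageStartupMessages(library(thermshift))

files <- list.files("results/ths", pattern = "_baseline\\.asc$")
species <- sub("_baseline\\.asc$", "", files)
dir.create("results/change", recursive = TRUE, showWarnings = FALSE)

class_rows <- list()
summary_rows <- list()
for (sp in species) {
  b <- read_ascii_grid(sprintf("results/ths/%s_baseline.asc", sp))
  f <- read_ascii_grid(sprintf("results/ths/%s_future.asc", sp))
  # clip file-precision rounding back into [0, 1]
  gb <- ths_grid(b$lat, b$lon, pmin(pmax(b$values, 0), 1))
  gf <- ths_grid(f$lat, f$lon, pmin(pmax(f$values, 0), 1))
  s <- change_summary(sp, gb, gf)
  class_rows[[sp]] <- cbind(species = sp, s$classes)
  summary_rows[[sp]] <- data.frame(
    species = sp, delta_ths_mean = s$delta_ths_mean,
    extent_ge_0_6_baseline_km2 = s$extent_ge_0_6_baseline_km2,
    extent_ge_0_6_future_km2 = s$extent_ge_0_6_future_km2,
    extent_ge_0_6_pct_change = s$extent_ge_0_6_pct_change,
    range_expanding = s$range_expanding, priority = s$priority)
  cat(sprintf("%-18s dTHS %+0.3f  THS>=0.6 extent %+.1f%%  %s, %s\n",
              sp, s$delta_ths_mean,
              s$extent_ge_0_6_pct_change,
              ifelse(s$range_expanding, "range-expanding", "non-expanding"),
              s$priority))
}

classes <- do.call(rbind, unname(class_rows))
summaries <- do.call(rbind, unname(summary_rows))
for (df_name in c("classes", "summaries")) {
  df <- get(df_name)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 6)
  }
  utils::write.csv(df, sprintf("results/change/%s.csv", df_name),
                   row.names = FALSE, quote = FALSE)
}

cat("\nConcern matrix (species counts):\n")
print(table(priority = summaries$priority,
            expanding = ifelse(summaries$range_expanding,
                               "range-expanding", "non-expanding")))
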