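#!/usr/bin/env Rscript
# Step 1: generate every synthetic input the downstream steps consume, with
# the generators' exact ground truth saved alongside. All randomness flows
# from one seed so the whole workflow is reproducible end to end.

suppressMessages(library(biomovr))

seed <- 2026
out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

species <- gen_species_table(seed = seed)
write.csv(species$data, file.path(out, "species.csv"), row.names = FALSE)

tracks <- gen_tracks(seed = seed, config = list(n_individuals = 8,
                                                forage_days = 5))
fixes <- do.call(rbind, lapply(tracks$data, as.data.frame))
fixes$timestamp <- format(fixes$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC")
write.csv(fixes, file.path(out, "track_fixes.csv"), row.names = FALSE)

countries <- gen_country_table(seed = seed, config = list(mask_fraction = 0.3))
write.csv(countries$data$countries, file.path(out, "countries.csv"),
          row.names = FALSE)
write.csv(countries$data$demands, file.path(out, "demand_raw.csv"),
          row.names = FALSE)

history <- gen_historical_series(seed = seed)
write.csv(history$data, file.path(out, "historical_series.csv"),
          row.names = FALSE)

truth <- list(
  species = species$truth[c("total_biomass_t", "total_movement_t_km_yr",
                            "weighted_daily_km")],
  tracks = tracks$truth$per_individual,
  mobility_total_gt_km_yr = countries$truth$total_gt_km_yr,
  history = history$truth,
  seed = seed)
jsonlite::write_json(truth, file.path(out, "truth.json"),
                     auto_unbox = TRUE, digits = NA)

cat(sprintf(
  "simulated %d species (%.1f Gt km/yr true movement), %d bird tracks,\n",
  nrow(species$data), species$truth$total_movement_t_km_yr / 1e9,
  length(tracks$data)))
cat(sprintf("%d countries with %.0f%% of demand entries masked, and a %d-year series\n",
            nrow(countries$data$countries), 30,
            diff(history$config$years) + 1))
cat("inputs + truth written to", out, "\n")
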