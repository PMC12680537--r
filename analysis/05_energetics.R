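#!/usr/bin/env Rscript
# Step 5: locomotion energy and mean power per group from biomass movement
# and group-average cost of transport, at raw and headline precision.

suppressMessages(library(biomovr))

fx <- load_fixtures()
rows <- do.call(rbind, lapply(fx$energy_table, function(r)
  data.frame(group = r$group, movement_gt_km_yr = r$movement_gt_km_yr,
             cot_avg = r$cot_avg, analogue_label = r$analogue_label)))

tbl <- build_energy_table(rows)
write.csv(tbl, "results/energy_table.csv", row.names = FALSE)
jsonlite::write_json(tbl, "results/energy_table.json",
                     auto_unbox = TRUE, digits = NA)

cat("locomotion energy (TWh/yr) and mean power (GW), raw -> 1 sig fig:\n")
print(data.frame(group = tbl$group,
                 energy = sprintf("%.0f -> %.0f", tbl$energy_twh_yr,
                                  tbl$energy_twh_yr_1sf),
                 power = sprintf("%.1f -> %.0f", tbl$power_gw,
                                 tbl$power_gw_1sf)), row.names = FALSE)
walker <- cot(70, cot_registry()$walk_run)
cat(sprintf("default 70-kg walker COT: %.2f J/kg/m = %.2f kcal/kg/km\n",
            walker, cot_to_kcal_per_kg_km(walker)))
land_vert <- sum(tbl$energy_twh_yr[tbl$group %in% c("wild_land_mammals",
                                                    "wild_birds")])
cat(sprintf("human transport uses ~%.0fx the locomotion energy of wild land vertebrates\n",
            tbl$energy_twh_yr[tbl$group == "humans_all_transport"] / land_vert))
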