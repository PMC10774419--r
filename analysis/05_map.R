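#!/usr/bin/env Rscript
# Stage 5: allocate effort to the grid ------------------------------------
#
# Prorates each national segment onto half-degree cells against the mapped
# catch (gear cascade: exact gear, gear family, country), applies the
# coastal constraint for the unpowered sector, spreads with a one-cell
# Gaussian kernel, and writes the published layout: one file per (year,
# sector) under results/mapped/effort_mapped/ and one per country under
# results/mapped/effort_mapped_country/. Conservation of every national
# segment total is checked before writing.

suppressMessages({library(effortr); library(dplyr)})

cfg <- world_config_from_file("analysis/config.json")
world <- generate_world(cfg)
res <- run_pipeline(world, sigma = 1)

got <- res$effort |>
  group_by(Year, SAUP, Sector, Length_Category, Gear) |>
  summarise(tot = sum(NomActive), .groups = "drop")
want <- res$segments |>
  transmute(Year = year, SAUP = saup, Sector = sector,
            Length_Category = length_class, Gear = gear, nom = nom_active)
chk <- inner_join(got, want,
                  by = c("Year", "SAUP", "Sector", "Length_Category", "Gear"))
dev <- max(abs(chk$tot - chk$nom) / pmax(chk$nom, 1e-12))
stopifnot(dev < 1e-6)

manifest <- write_effort_outputs(res$effort, "results/mapped",
                                 registry = world$registry)
write.csv(manifest, "results/mapped/manifest.csv", row.names = FALSE)

message(sprintf("mapped %d records; conservation max rel dev %.1e",
                nrow(res$effort), dev))
message(sprintf("%d per-year-per-sector files, %d country files",
                sum(manifest$folder == "effort_mapped"),
                sum(manifest$folder == "effort_mapped_country")))
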