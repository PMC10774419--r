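#!/usr/bin/env Rscript
# Stage 3: disaggregate fleets into length classes and gears --------------
#
# Smooths the sparse observed compositions onto every year (additive
# log-ratio interpolation, renormalized to the simplex) and apportions the
# reconstructed national counts into the five length classes and the gear
# types with largest-remainder rounding, so segment counts sum exactly to
# the national totals.

suppressMessages({library(effortr); library(dplyr)})

cfg <- world_config_from_file("analysis/config.json")
world <- generate_world(cfg)
rec <- reconstruct_fleet_table(world$fleet_obs, world$covariates, cfg$years)

smooth_all <- function(obs, key) {
  obs |>
    group_by(saup, sector) |>
    group_modify(function(d, k) smooth_share_series(d, cfg$years, key = key)) |>
    ungroup()
}
length_shares <- smooth_all(world$length_share_obs, "length_class")
gear_shares <- smooth_all(world$gear_share_obs, "gear")
skeleton <- disaggregate_fleet(rec$series, length_shares, gear_shares)

dir.create("results", showWarnings = FALSE)
write.csv(length_shares, "results/length_shares.csv", row.names = FALSE)
write.csv(gear_shares, "results/gear_shares.csv", row.names = FALSE)
write.csv(skeleton, "results/fleet_segments.csv", row.names = FALSE)

chk <- skeleton |>
  group_by(saup, sector, year) |>
  summarise(nv = sum(nv), .groups = "drop") |>
  inner_join(rec$series, by = c("saup", "sector", "year"))
stopifnot(all(chk$nv == round(chk$n_vessels)))
message(sprintf("%d fleet segments; vessel conservation holds exactly",
                nrow(skeleton)))
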