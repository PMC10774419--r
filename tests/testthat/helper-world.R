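# shared fixtures, all built in code

small_world <- function(n = 3, seed = 11, ...) {
  generate_world(world_config(n_countries = n, rng_seed = seed, ...))
}

# a clean logistic observation series
logistic_obs <- function(years, K, r, t0) {
  tibble::tibble(year = years, n_vessels = K / (1 + exp(-r * (years - t0))))
}

# tiny Table-1 style effort grid on the given cells
toy_effort <- function(lat, lon, nom, sector = "I", gear = "gillnets",
                       fgroup = "pelagics", year = 2000L, saup = 101L,
                       length_category = length_classes()[3]) {
  tibble::tibble(
    Year = year, SAUP = saup, NV = nom / 100, P = nom / 10, GT = nom / 20,
    NomActive = nom, EffActive = nom * 1.2,
    Length_Category = length_category, Gear = gear,
    Lat = lat, Lon = lon, FGroup = fgroup, Sector = sector
  )
}

# value-grid helper for the comparison metrics
toy_grid_values <- function(lat, lon, value) {
  tibble::tibble(lat = lat, lon = lon, value = value)
}

expect_sums_to <- function(x, total, tol = 1e-9) {
  expect_lt(abs(sum(x) - total), tol * max(1, abs(total)))
}
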