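test_that("gear cascade resolves exact, family and country levels", {
  fam <- default_gear_families()
  ex <- match_gear("gillnets", c("gillnets", "lines"), fam)
  expect_equal(ex$level, "exact")
  expect_equal(ex$gears, "gillnets")

  fa <- match_gear("liftnets", c("gillnets", "seines"), fam)
  expect_equal(fa$level, "family")
  expect_setequal(fa$gears, c("gillnets", "seines"))

  co <- match_gear("longlines", c("gillnets", "seines"), fam)
  expect_equal(co$level, "country")
  expect_setequal(co$gears, c("gillnets", "seines"))

  expect_error(match_gear("ray guns", c("gillnets"), fam), "unmapped gear")
})

test_that("functional-group proration is the renormalized outer product", {
  one <- allocate_to_functional_groups(
    100, tibble::tibble(fgroup = "pelagics", catch = 42))
  expect_equal(one$effort, 100)

  two <- allocate_to_functional_groups(
    100, tibble::tibble(fgroup = c("a", "b"), catch = c(75, 25)))
  expect_equal(two$effort[two$fgroup == "a"], 75)
  expect_equal(two$effort[two$fgroup == "b"], 25)

  four <- allocate_to_functional_groups(
    100, tibble::tibble(fgroup = c("a", "b"), catch = c(50, 50)),
    tonnage_shares = c(big = 0.6, small = 0.4))
  expect_equal(sort(four$effort), c(20, 20, 30, 30))
  expect_sums_to(four$effort, 100)

  expect_warning(
    zero <- allocate_to_functional_groups(
      60, tibble::tibble(fgroup = c("a", "b"), catch = c(0, 0))),
    "all-zero catch")
  expect_equal(zero$effort, c(30, 30))
})

test_that("cell proration follows relative catch", {
  cells <- tibble::tibble(fgroup = "a", lat = c(0.25, 0.75, 1.25),
                          lon = 0.25, catch = c(10, 0, 30))
  out <- allocate_to_cells(tibble::tibble(fgroup = "a", effort = 80), cells)
  expect_equal(out$effort, c(20, 0, 60))

  even <- allocate_to_cells(
    tibble::tibble(fgroup = "a", effort = 10),
    dplyr::mutate(cells, catch = c(5, 5, 0)))
  expect_equal(even$effort, c(5, 5, 0))
})

test_that("constraints zero disallowed cells and conserve segment totals", {
  grid <- set_coastal_columns(
    make_grid(c(0, 1), c(0, 2), 0.5), coast_cols = 1)
  # 4 cells along lon at lat 0.25: only lon 0.25 is coastal
  e <- toy_effort(lat = rep(0.25, 4), lon = c(0.25, 0.75, 1.25, 1.75),
                  nom = c(10, 20, 30, 40), sector = "UP", gear = "gillnets",
                  length_category = length_classes()[1])
  out <- apply_constraints(e, grid)
  expect_equal(nrow(out), 1)
  expect_equal(out$NomActive, 100)
  expect_equal(out$Lon, 0.25)

  # trawl ban: banned cell mass redistributed proportionally
  grid2 <- make_grid(c(0, 0.5), c(0, 1.5), 0.5)
  grid2$trawl_ban <- grid2$lon == 0.25
  e2 <- toy_effort(lat = 0.25, lon = c(0.25, 0.75, 1.25),
                   nom = c(60, 30, 10), gear = "bottom trawls")
  out2 <- apply_constraints(e2, grid2)
  expect_equal(out2$NomActive, c(75, 25))
  expect_sums_to(out2$NomActive, 100)

  # no masks: identity
  out3 <- apply_constraints(e2, make_grid(c(0, 0.5), c(0, 1.5), 0.5))
  expect_equal(out3$NomActive, e2$NomActive)

  # everything disallowed: error naming the segment
  grid4 <- grid
  grid4$coastal <- FALSE
  expect_error(apply_constraints(e, grid4), "all cells disallowed")
})

test_that("gaussian spreading conserves totals and is the identity at width 0", {
  grid <- make_grid(c(0, 2.5), c(0, 2.5), 0.5)  # open 5x5
  centre <- toy_effort(lat = 1.25, lon = 1.25, nom = 100)
  expect_identical(smooth_spread(centre, grid, sigma = 0), centre)

  sm <- smooth_spread(centre, grid, sigma = 1)
  expect_sums_to(sm$NomActive, 100, tol = 1e-9)
  # centre cell keeps the maximum; symmetric spread
  expect_equal(sm$Lat[which.max(sm$NomActive)], 1.25)
  expect_equal(sm$Lon[which.max(sm$NomActive)], 1.25)
  at <- function(lat, lon) sm$NomActive[sm$Lat == lat & sm$Lon == lon]
  expect_equal(at(0.75, 1.25), at(1.75, 1.25))
  expect_equal(at(1.25, 0.75), at(1.25, 1.75))
  expect_equal(at(0.75, 0.75), at(1.75, 1.75))

  # independent oracle: truncated discrete gaussian renormalized on 5x5
  k1 <- exp(-(-2:2)^2 / 2); k1 <- k1 / sum(k1)
  expected_centre <- 100 * k1[3]^2 /
    sum(outer(k1, k1))  # renormalized over the open 5x5 window
  expect_equal(max(sm$NomActive), expected_centre, tolerance = 1e-9)
})

test_that("spreading never re-enters banned cells", {
  grid <- set_coastal_columns(make_grid(c(0, 2.5), c(0, 2.5), 0.5),
                              coast_cols = 2)
  e <- toy_effort(lat = 1.25, lon = c(0.25, 0.75), nom = c(50, 50),
                  sector = "UP", gear = "gillnets",
                  length_category = length_classes()[1])
  sm <- smooth_spread(e, grid, sigma = 1)
  expect_true(all(sm$Lon <= 0.75))  # coastal strip only
  expect_sums_to(sm$NomActive, 100, tol = 1e-9)
})

test_that("regional aggregation partitions the global total", {
  e <- toy_effort(lat = c(0.25, 0.25, 0.75), lon = c(0.25, 0.75, 0.25),
                  nom = c(10, 20, 30))
  regions <- tibble::tibble(lat = c(0.25, 0.25), lon = c(0.25, 0.75),
                            region = c("north", "south"))
  agg <- aggregate_by_region(e, regions)
  expect_setequal(agg$region, c("north", "south", "none"))
  expect_equal(sum(agg$NomActive), 60)
  expect_equal(agg$NomActive[agg$region == "north"], 10)

  all_one <- aggregate_by_region(
    e, tibble::tibble(lat = e$Lat, lon = e$Lon, region = "world"))
  expect_equal(all_one$NomActive, 60)
})

test_that("full mapping conserves every national segment total at all stages", {
  w <- small_world(n = 3, seed = 29)
  res <- run_pipeline(w, map = FALSE)
  for (sig in c(0, 1)) {
    eff <- map_effort(res$segments, w$catch, w$grid, sigma = sig)
    expect_true(all(eff$NomActive >= 0))
    got <- eff |>
      dplyr::group_by(.data$Year, .data$SAUP, .data$Sector,
                      .data$Length_Category, .data$Gear) |>
      dplyr::summarise(tot = sum(.data$NomActive), .groups = "drop")
    want <- res$segments |>
      dplyr::transmute(Year = .data$year, SAUP = .data$saup,
                       Sector = .data$sector,
                       Length_Category = .data$length_class,
                       Gear = .data$gear, nom = .data$nom_active)
    chk <- dplyr::inner_join(got, want,
                             by = c("Year", "SAUP", "Sector",
                                    "Length_Category", "Gear"))
    expect_equal(nrow(chk), nrow(want))
    expect_lt(max(abs(chk$tot - chk$nom) / pmax(chk$nom, 1e-12)), 1e-6)
  }
})

test_that("every effort gear resolves through the cascade on synthetic data", {
  w <- small_world(n = 2, seed = 37)
  res <- run_pipeline(w, sigma = 0)
  # unpowered 'pole and line' has no lines-family catch: country-level match
  up_line <- res$effort |>
    dplyr::filter(.data$Sector == "UP", .data$Gear == "pole and line")
  expect_gt(nrow(up_line), 0)
  # motorized 'lines' matches longlines catch via the lines family
  apw_line <- res$effort |>
    dplyr::filter(.data$Sector == "APW", .data$Gear == "lines")
  expect_gt(nrow(apw_line), 0)
})
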