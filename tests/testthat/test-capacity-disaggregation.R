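test_that("constant observed composition is carried identically", {
  sh <- tidyr::crossing(year = c(1950, 1980, 2017),
                        length_class = length_classes()) |>
    dplyr::mutate(share = 0.2)
  out <- smooth_share_series(sh, 1950:2017)
  expect_true(all(abs(out$share - 0.2) < 1e-12))
  sums <- tapply(out$share, out$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("linear drift between two compositions interpolates monotonically on the simplex", {
  cls <- c("a", "b")
  sh <- tibble::tibble(
    year = c(1, 1, 5, 5), length_class = rep(cls, 2),
    share = c(0.2, 0.8, 0.4, 0.6)
  )
  out <- smooth_share_series(sh, 1:5)
  # independent arithmetic: linear ALR against the larger class b
  alr <- seq(log(0.2 / 0.8), log(0.4 / 0.6), length.out = 5)
  expected_a <- exp(alr) / (1 + exp(alr))
  got_a <- out$share[out$length_class == "a"]
  expect_equal(got_a, expected_a, tolerance = 1e-9)
  expect_true(all(diff(got_a) > 0))
  sums <- tapply(out$share, out$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("structural zeros are preserved across years", {
  sh <- tibble::tibble(
    year = rep(c(1, 10), each = 3),
    length_class = rep(c("a", "b", "c"), 2),
    share = c(0.3, 0.7, 0, 0.6, 0.4, 0)
  )
  out <- smooth_share_series(sh, 1:10)
  expect_true(all(out$share[out$length_class == "c"] == 0))
  sums <- tapply(out$share, out$year, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("single observed composition is carried flat with a warning", {
  sh <- tibble::tibble(year = 5, length_class = c("a", "b"),
                       share = c(0.3, 0.7))
  expect_warning(out <- smooth_share_series(sh, 1:10), "single")
  expect_true(all(out$share[out$length_class == "a"] == 0.3))
})

test_that("donor imputation averages and renormalizes", {
  donors1 <- tibble::tibble(donor = "d1", year = 1:2,
                            length_class = "a", share = c(0.4, 0.6))
  one <- impute_from_similar(donors1)
  expect_equal(one$share, c(1, 1))  # renormalized single class

  donors2 <- tidyr::crossing(donor = c("d1", "d2"), year = 1,
                             length_class = c("a", "b")) |>
    dplyr::mutate(share = c(1, 0, 0, 1)[match(
      paste(.data$donor, .data$length_class),
      c("d1 a", "d1 b", "d2 a", "d2 b"))])
  two <- impute_from_similar(donors2)
  expect_equal(sort(two$share), c(0.5, 0.5))

  # three donors, one missing a year: mean of those available, count kept
  donors3 <- tibble::tibble(
    donor = c("d1", "d2", "d3", "d1", "d2"),
    year = c(1, 1, 1, 2, 2),
    length_class = "a",
    share = c(10, 20, 30, 40, 60)
  )
  three <- impute_from_similar(donors3, compositional = FALSE)
  expect_equal(three$share[three$year == 1], 20)
  expect_equal(three$share[three$year == 2], 50)
  expect_equal(three$n_donors, c(3L, 2L))

  expect_error(impute_from_similar(donors1[0, ]), "no similar countries")
})

test_that("largest-remainder apportionment conserves the total exactly", {
  expect_equal(apportion_largest_remainder(10, c(1, 1, 1)), c(4L, 3L, 3L))
  # quotas 3.5/1.75/1.75 -> floors 3/1/1, remainders .5/.75/.75
  expect_equal(apportion_largest_remainder(7, c(0.5, 0.25, 0.25)),
               c(3L, 2L, 2L))
  expect_equal(apportion_largest_remainder(0, c(0.3, 0.7)), c(0L, 0L))
  set.seed(3)
  for (i in 1:50) {
    total <- sample(0:5000, 1)
    shares <- runif(sample(2:6, 1))
    out <- apportion_largest_remainder(total, shares)
    expect_equal(sum(out), total)
    expect_true(all(out >= 0))
  }
})

test_that("disaggregated vessel counts sum exactly to the national totals", {
  w <- small_world(n = 3, seed = 23)
  rec <- reconstruct_fleet_table(w$fleet_obs, w$covariates, w$config$years)
  ls <- w$length_share_obs |>
    dplyr::group_by(.data$saup, .data$sector) |>
    dplyr::group_modify(function(d, k) {
      smooth_share_series(d, w$config$years)
    }) |>
    dplyr::ungroup()
  gs <- w$gear_share_obs |>
    dplyr::group_by(.data$saup, .data$sector) |>
    dplyr::group_modify(function(d, k) {
      smooth_share_series(d, w$config$years, key = "gear")
    }) |>
    dplyr::ungroup()
  seg <- disaggregate_fleet(rec$series, ls, gs)
  chk <- seg |>
    dplyr::group_by(.data$saup, .data$sector, .data$year) |>
    dplyr::summarise(nv = sum(.data$nv), .groups = "drop") |>
    dplyr::inner_join(rec$series, by = c("saup", "sector", "year"))
  expect_true(all(chk$nv == round(chk$n_vessels)))
})

test_that("power smooths between observations and tonnage is period-constant", {
  skel <- tibble::tibble(
    saup = 1L, country = "A", sector = "I", year = rep(1950:2000, 2),
    length_class = length_classes()[3],
    gear = rep(c("gillnets", "lines"), each = 51), nv = 10L
  )
  pw <- tibble::tibble(saup = 1L, sector = "I",
                       length_class = length_classes()[3],
                       year = c(1960, 2000), mean_kw = c(40, 80))
  gt <- tibble::tibble(saup = 1L, sector = "I",
                       length_class = length_classes()[3],
                       year = c(1955, 1985), mean_gt = c(50, 70))
  out <- attach_power_tonnage(skel, pw, gt, years = 1950:2000,
                              period_breaks = 1980)
  one <- out[out$gear == "gillnets", ]
  expect_equal(one$mean_kw[one$year <= 1960], rep(40, 11))
  expect_true(all(diff(one$mean_kw[one$year >= 1960]) > 0))
  expect_equal(one$mean_kw[one$year == 2000], 80)
  expect_equal(unique(one$mean_gt[one$year < 1980]), 50)
  expect_equal(unique(one$mean_gt[one$year >= 1980]), 70)
  expect_equal(out$p_total, out$mean_kw * out$nv)
  expect_equal(out$gt_total, out$mean_gt * out$nv)

  # single observation: flat series
  out2 <- attach_power_tonnage(skel, pw[1, ], gt[1, ], years = 1950:2000)
  expect_true(all(out2$mean_kw == 40))

  # orphan segment with no donor errors
  skel_orphan <- dplyr::mutate(skel, length_class = length_classes()[5])
  expect_error(attach_power_tonnage(skel_orphan, pw, gt, 1950:2000),
               "no engine power")
})
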