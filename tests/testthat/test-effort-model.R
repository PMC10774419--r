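test_that("motor equivalence is exact on noise-free constructed data", {
  years <- 1960:2000
  nvu <- 5000 * 0.95^(years - 1960)              # unmotorized declining
  nvm <- 8000 / (1 + exp(-0.15 * (years - 1980)))  # motorized logistic
  p <- nvm * 20
  catch <- 0.1 * (nvu * 5 + p)                   # PPV_eq = 5, q = 0.1
  me <- solve_motor_equivalence(
    tibble::tibble(year = years, catch = catch),
    tibble::tibble(year = years, n_vessels = nvu),
    tibble::tibble(year = years, n_vessels = nvm),
    tibble::tibble(year = years, p_total = p)
  )
  expect_equal(me$ppv_eq, 5, tolerance = 1e-9)
  share <- nvu / (nvu + nvm)
  expect_setequal(me$years_used, years[share >= 0.2 & share <= 0.8])
})

test_that("selection window is closed and filters as specified", {
  years <- 1:10
  nvu <- rep(900, 10); nvm <- rep(100, 10)  # share 0.9 throughout
  args <- list(
    tibble::tibble(year = years, catch = runif(10, 10, 20)),
    tibble::tibble(year = years, n_vessels = nvu),
    tibble::tibble(year = years, n_vessels = nvm),
    tibble::tibble(year = years, p_total = nvm * 10)
  )
  expect_error(do.call(solve_motor_equivalence, args),
               "insufficient motorization overlap")

  # boundary share exactly 0.20 is included
  nvu2 <- c(rep(20, 5), 30, 40, 50, 60, 70)
  nvm2 <- rep(80, 10)
  p2 <- nvm2 * 10
  catch2 <- 0.2 * (nvu2 * 3 + p2)
  me <- solve_motor_equivalence(
    tibble::tibble(year = years, catch = catch2),
    tibble::tibble(year = years, n_vessels = nvu2),
    tibble::tibble(year = years, n_vessels = nvm2),
    tibble::tibble(year = years, p_total = p2)
  )
  expect_true(all(years[nvu2 / (nvu2 + nvm2) >= 0.2] %in% me$years_used))
  expect_false(any(nvu2[match(me$years_used, years)] /
                     (nvu2 + nvm2)[match(me$years_used, years)] < 0.2))
})

test_that("nominal effort is the triple product with guardrails", {
  expect_equal(nominal_effort(100, 200, 0.72), 14400)
  expect_equal(nominal_effort(0, 200, 0.5), 0)
  expect_equal(nominal_effort(100, 0, 0.5), 0)
  expect_equal(nominal_effort(1, 1, 1), 1)
  expect_equal(default_activity_ratio(), 0.72)
  expect_error(nominal_effort(100, 200, 1.2), "greater than 1")
  expect_error(nominal_effort(-1, 200, 0.5), "non-negative")
})

test_that("days-at-sea lookup relaxes keys in the documented order", {
  das <- tibble::tibble(
    saup = c(1L, 1L, 1L, 2L),
    sector = "I",
    gear = c("gillnets", "gillnets", "lines", "gillnets"),
    year = c(2000L, 2005L, 2000L, 2000L),
    das = c(100, 120, 200, 300),
    r_act = c(0.8, NA, 0.7, 0.6)
  )
  exact <- fill_days_at_sea(1L, "I", "gillnets", 2000L, das)
  expect_equal(exact$das, 100)
  expect_equal(exact$provenance, "exact")

  seg <- fill_days_at_sea(1L, "I", "gillnets", 1990L, das)
  expect_equal(seg$das, 110)  # mean of the two gillnet years
  expect_equal(seg$provenance, "segment")

  ctry <- fill_days_at_sea(1L, "I", "trawls", 1990L, das)
  expect_equal(ctry$das, mean(c(100, 120, 200)))
  expect_equal(ctry$provenance, "country")

  reg <- fill_days_at_sea(9L, "I", "gillnets", 2000L, das)
  expect_equal(reg$das, mean(c(100, 120, 200, 300)))
  expect_equal(reg$provenance, "region")

  expect_error(fill_days_at_sea(1L, "I", "gillnets", 2000L, das[0, ]),
               "empty")

  # vectorized variant agrees with the scalar one
  keys <- tibble::tibble(saup = c(1L, 1L, 1L, 9L), sector = "I",
                         gear = c("gillnets", "gillnets", "trawls",
                                  "gillnets"),
                         year = c(2000L, 1990L, 1990L, 2000L))
  v <- fill_das_table(keys, das)
  expect_equal(v$das, c(100, 110, mean(c(100, 120, 200)),
                        mean(c(100, 120, 200, 300))))
  expect_equal(v$das_provenance, c("exact", "segment", "country", "region"))
})

test_that("creep estimation matches the geometric growth rate", {
  years <- 1990:2010
  cpue <- 50 * 1.035^(years - 1990)
  cm <- estimate_creep(years, cpue)
  expect_equal(cm$rate, 0.035, tolerance = 1e-9)

  flat <- estimate_creep(years, rep(4, length(years)))
  expect_equal(flat$rate, 0, tolerance = 1e-12)

  expect_equal(default_creep_rates(),
               c(I = 0.014, APW = 0.05, UP = 0.05))

  expect_warning(
    expect_error(estimate_creep(1:6, c(1, 2, -1, 0, -2, 3)), "fewer than 5"),
    "non-positive"
  )

  # biomass covariate removal: CPUE riding on a biomass cycle
  set.seed(5)
  biomass <- 100 * exp(0.3 * sin(seq(0, 3 * pi, length.out = 30)))
  years2 <- seq_len(30) + 1979
  cpue2 <- 10 * 1.02^(seq_len(30)) * biomass^0.8
  cm2 <- estimate_creep(years2, cpue2, biomass_index = biomass)
  expect_equal(cm2$rate, 0.02, tolerance = 1e-6)
  expect_true(cm2$biomass_adjusted)
})

test_that("effective effort compounds creep from the 1949 baseline", {
  expect_equal(effective_effort(1949, 1000, creep_model(0.05)), 1000)
  years <- 1949:1960
  nom <- rep(1, length(years))
  expect_equal(effective_effort(years, nom, creep_model(0)), nom)
  eff <- effective_effort(years, nom, creep_model(0.014))
  expect_equal(eff[years == 1951], 1.014^2, tolerance = 1e-12)
  expect_equal(eff[years == 1949], 1)
  # non-decreasing effective/nominal ratio under non-negative creep
  expect_true(all(diff(eff / nom) >= 0))
  expect_error(effective_effort(1940, 10, creep_model(0.014)), "baseline")
  expect_error(creep_model(-1.5), "> -1")
})

test_that("per-year creep vectors are honoured", {
  rates <- setNames(c(0, 0.1, 0.2, 0), as.character(1949:1952))
  eff <- effective_effort(1949:1952, rep(1, 4), creep_model(rates))
  expect_equal(eff, c(1, 1.1, 1.1 * 1.2, 1.1 * 1.2))
})
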