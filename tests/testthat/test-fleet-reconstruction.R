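test_that("logistic fit recovers parameters from clean 10-point series", {
  years <- round(seq(1950, 2017, length.out = 10))
  obs <- logistic_obs(years, K = 1000, r = 0.2, t0 = 1980)
  res <- fit_logistic_series(obs, years = 1950:2017)
  fit <- res$fits[[1]]
  expect_equal(fit$type, "nls")
  expect_lt(abs(fit$K - 1000) / 1000, 0.01)
  expect_lt(abs(fit$r - 0.2), 0.01)
  expect_lt(abs(fit$t0 - 1980), 0.5)
  expect_equal(nrow(res$series), 68)
  expect_true(all(res$series$n_vessels >= 0))
  expect_setequal(res$series$provenance[res$series$year %in% years],
                  "observed")
})

test_that("constant series reconstructs flat; refit of complete series is idempotent", {
  obs <- tibble::tibble(year = c(1950, 1960, 1980, 2000), n_vessels = 50)
  res <- fit_logistic_series(obs, years = 1950:2000)
  expect_true(all(res$series$n_vessels == 50))

  # idempotence: a complete clean logistic series comes back unchanged
  years <- 1950:2017
  full <- logistic_obs(years, K = 800, r = 0.15, t0 = 1975)
  res2 <- fit_logistic_series(full, years = years)
  expect_equal(res2$series$n_vessels, full$n_vessels, tolerance = 1e-6)
  expect_equal(res2$series$fitted, full$n_vessels, tolerance = 1e-4)
})

test_that("disruption years split the series into independent segments", {
  years1 <- seq(1950, 1974, by = 3)
  years2 <- seq(1975, 2010, by = 3)
  obs <- dplyr::bind_rows(
    logistic_obs(years1, K = 2000, r = 0.3, t0 = 1960),
    logistic_obs(years2, K = 500, r = 0.25, t0 = 1985)
  )
  res <- fit_logistic_series(obs, disruption_years = 1975,
                             years = 1950:2010)
  expect_length(res$fits, 2)
  expect_lt(abs(res$fits[[1]]$K - 2000) / 2000, 0.05)
  expect_lt(abs(res$fits[[2]]$K - 500) / 500, 0.05)
  expect_equal(res$fits[[1]]$segment, c(1950, 1974))
  expect_equal(res$fits[[2]]$segment, c(1975, 2010))
})

test_that("too few points in a segment signals insufficient data", {
  obs <- tibble::tibble(year = c(1950, 1990), n_vessels = c(10, 20))
  expect_error(fit_logistic_series(obs, years = 1950:2000),
               class = "effortr_insufficient_data")
})

test_that("population proxy scales from the nearest anchor, earlier on ties", {
  cov <- tibble::tibble(year = 1991:1995,
                        population = c(1000, 1100, 1200, 1300, 1400))
  partial <- tibble::tibble(year = c(1991, 1995), n_vessels = c(100, 300))
  out <- reconstruct_by_proxy(partial, cov, years = 1991:1995)
  # 1993 is equidistant: anchored at the earlier year 1991
  expect_equal(out$n_vessels,
               c(100, 100 * 1100 / 1000, 100 * 1200 / 1000,
                 300 * 1300 / 1400, 300))
  expect_equal(out$provenance, c("observed", "reconstructed",
                                 "reconstructed", "reconstructed",
                                 "observed"))

  flat <- tibble::tibble(year = 1991:1995, population = 500)
  out2 <- reconstruct_by_proxy(partial[1, ], flat, years = 1991:1995)
  expect_true(all(out2$n_vessels == 100))

  expect_error(reconstruct_by_proxy(partial[0, ], cov, 1991:1995),
               "no data")
})

test_that("population doubling doubles the proxy-reconstructed count", {
  cov <- tibble::tibble(year = 1990:2010,
                        population = 1000 * 2^((0:20) / 20))
  partial <- tibble::tibble(year = 1990, n_vessels = 100)
  out <- reconstruct_by_proxy(partial, cov, years = 1990:2010)
  expect_equal(out$n_vessels[out$year == 2010], 200)
})

test_that("unmotorized rules: rise with population to the peak, coupled decline after", {
  years <- 1975:1983
  pop <- 1000 * 1.02^(years - 1975)
  cov <- tibble::tibble(year = years, population = pop,
                        gdp_per_capita = 10000)
  mot <- tibble::tibble(
    year = years,
    n_vessels = c(rep(200, 6), 200 * 1.1, 200 * 1.1^2, 200 * 1.1^3)
  )
  partial <- tibble::tibble(year = 1975, n_vessels = 100)
  out <- reconstruct_unmotorized(partial, mot, cov, ymax = 1980,
                                 coupling = -1, years = years)
  # hand-computed: population growth to 1980, then -10%/yr
  pre <- 100 * 1.02^(0:5)
  expect_equal(out$n_vessels[1:6], pre)
  expect_equal(out$n_vessels[7:9], pre[6] * 0.9^(1:3))

  # flat population and flat motorized fleet: constant series
  cov_flat <- tibble::tibble(year = years, population = 1000,
                             gdp_per_capita = 10000)
  mot_flat <- tibble::tibble(year = years, n_vessels = 300)
  out2 <- reconstruct_unmotorized(partial, mot_flat, cov_flat, ymax = 1980,
                                  years = years)
  expect_true(all(out2$n_vessels == 100))

  expect_error(reconstruct_unmotorized(partial, mot[0, ], cov, ymax = 1980,
                                       years = years),
               "motorized")
})

test_that("Y_max-GDP relation: exact on collinear points, degenerate designs error", {
  d <- tibble::tibble(gdp = c(1000, 2000, 3000),
                      ymax = 2010 - 0.002 * c(1000, 2000, 3000))
  m <- fit_ymax_gdp_relation(d)
  expect_equal(m$slope, -0.002, tolerance = 1e-9)
  expect_equal(m$intercept, 2010, tolerance = 1e-6)
  expect_equal(max(abs(m$residuals)), 0, tolerance = 1e-9)

  expect_error(fit_ymax_gdp_relation(d[1:2, ]), "at least 3")
  d2 <- tibble::tibble(gdp = rep(5000, 4), ymax = c(1980, 1985, 1990, 1995))
  expect_error(fit_ymax_gdp_relation(d2), "degenerate")
})

test_that("Y_max-GDP slope is recovered within 2 standard errors from noisy data", {
  set.seed(31)
  gdp <- runif(40, 2000, 40000)
  ymax <- 2010 - 0.002 * gdp + rnorm(40, 0, 3)
  m <- fit_ymax_gdp_relation(tibble::tibble(gdp = gdp, ymax = ymax))
  se <- summary(lm(ymax ~ gdp))$coefficients[2, 2]
  expect_lt(abs(m$slope - (-0.002)), 2 * se)

  # predictive use: the year minimizing |y - (b + m gdp(y))|
  cov <- tibble::tibble(year = 1950:2017,
                        gdp_per_capita = 5000 * 1.02^(0:67))
  y <- predict_ymax(m, cov)
  resid <- abs(cov$year - (m$intercept + m$slope * cov$gdp_per_capita))
  expect_equal(y, cov$year[which.min(resid)])
})

test_that("whole-table reconstruction is complete, non-negative, and flags provenance", {
  w <- small_world(n = 4, seed = 17)
  rec <- reconstruct_fleet_table(w$fleet_obs, w$covariates, w$config$years)
  counts <- dplyr::count(rec$series, .data$saup, .data$sector)
  expect_true(all(counts$n == length(w$config$years)))
  expect_true(all(rec$series$n_vessels >= 0))
  expect_setequal(unique(rec$series$provenance),
                  c("observed", "reconstructed"))
  expect_true(all(rec$series$method[rec$series$sector == "UP"] ==
                    "unmotorized_rules"))
})
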