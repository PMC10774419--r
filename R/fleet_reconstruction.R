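#' Fit logistic growth to a gappy national fleet series
#'
#' Fishing fleets tend to follow carrying-capacity-limited exponential
#' growth, so missing years of a national vessel-count series are
#' reconstructed with a three-parameter logistic curve
#' `NV(t) = K / (1 + exp(-r (t - t0)))` fitted to the observed points by
#' nonlinear least squares. Countries whose fleet was drastically
#' restructured (war, cyclone) are handled by splitting the series at the
#' supplied disruption years and fitting each segment independently; a
#' discontinuity at a disruption year is allowed.
#'
#' Fitting strategy per segment: nonlinear least squares (Levenberg-
#' Marquardt) initialized at `K = 1.2 * max(obs)`, `r = 0.1`, `t0` = year
#' nearest half-maximum; if that fails, a linear fit on the logit of
#' `NV / K-hat` with `K-hat = 1.05 * max(obs)`; as a last resort, monotone
#' linear interpolation between observations (flagged in the fit type).
#' A zero-variance segment is reproduced as a constant.
#'
#' @param observations Tibble with columns `year` and `n_vessels` for one
#'   (country, sector); gaps are simply absent rows.
#' @param disruption_years Optional integer years; each starts a new segment.
#' @param years Full year range to reconstruct over (default: the span of
#'   the observations).
#' @return A list with `fits` (one record per segment: `K`, `r`, `t0`,
#'   `type`, segment bounds, `mre` mean relative error on observed points)
#'   and `series`, a complete tibble (`year`, `n_vessels`, `fitted`,
#'   `provenance`) where observed years keep their observed value and the
#'   flag `"observed"`.
#' @export
fit_logistic_series <- function(observations, disruption_years = NULL,
                                years = NULL) {
  obs <- dplyr::arrange(observations, .data$year)
  if (any(obs$n_vessels < 0)) stop("negative vessel counts in observations")
  if (is.null(years)) years <- seq(min(obs$year), max(obs$year))
  breaks <- sort(unique(disruption_years))
  breaks <- breaks[breaks > min(years) & breaks <= max(years)]
  seg_start <- c(min(years), breaks)
  seg_end <- c(breaks - 1L, max(years))

  fits <- list()
  series <- list()
  for (i in seq_along(seg_start)) {
    seg_years <- seq(seg_start[i], seg_end[i])
    seg_obs <- obs[obs$year %in% seg_years, ]
    if (nrow(seg_obs) < 3) {
      stop(errorCondition(
        sprintf("insufficient data: %d observed point(s) in segment %d-%d",
                nrow(seg_obs), seg_start[i], seg_end[i]),
        class = c("effortr_insufficient_data", "error", "condition")
      ))
    }
    fit <- fit_logistic_segment(seg_obs$year, seg_obs$n_vessels)
    pred <- pmax(0, predict_logistic_fit(fit, seg_years))
    fit$segment <- c(seg_start[i], seg_end[i])
    obs_pred <- pred[match(seg_obs$year, seg_years)]
    ok <- seg_obs$n_vessels > 0
    fit$mre <- if (any(ok)) {
      mean(abs(obs_pred[ok] - seg_obs$n_vessels[ok]) / seg_obs$n_vessels[ok])
    } else NA_real_
    fits[[i]] <- fit
    s <- tibble(year = seg_years, n_vessels = pred, fitted = pred,
                provenance = "reconstructed")
    io <- match(seg_obs$year, seg_years)
    s$n_vessels[io] <- seg_obs$n_vessels
    s$provenance[io] <- "observed"
    series[[i]] <- s
  }
  list(fits = fits, series = dplyr::bind_rows(series))
}

fit_logistic_segment <- function(year, nv) {
  if (sd(nv) < 1e-12 * max(1, mean(nv))) {
    return(list(K = max(nv[1], .Machine$double.eps), r = 0, t0 = NA_real_,
                type = "constant", value = nv[1]))
  }
  init <- list(K = 1.2 * max(nv), r = 0.1,
               t0 = year[which.min(abs(nv - max(nv) / 2))])
  # count observations carry multiplicative (lognormal) noise, so the
  # default error family is multiplicative: least squares on the log scale.
  # Series containing zero counts fall back to the additive-scale fit.
  fit <- NULL
  if (all(nv > 0)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        log(nv) ~ log(K) - log(1 + exp(-r * (year - t0))), start = init,
        lower = c(K = .Machine$double.eps, r = -Inf, t0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        nv ~ K / (1 + exp(-r * (year - t0))), start = init,
        lower = c(K = .Machine$double.eps, r = -Inf, t0 = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
  }
  if (!is.null(fit)) {
    cf <- coef(fit)
    return(list(K = unname(cf["K"]), r = unname(cf["r"]),
                t0 = unname(cf["t0"]), type = "nls"))
  }
  # fallback: straight line on the logit of NV / K-hat
  khat <- 1.05 * max(nv)
  z <- qlogis(pmin(pmax(nv / khat, 1e-6), 1 - 1e-6))
  lf <- lm(z ~ year)
  slope <- unname(coef(lf)[2])
  if (is.finite(slope) && abs(slope) > 1e-12) {
    return(list(K = khat, r = slope, t0 = -unname(coef(lf)[1]) / slope,
                type = "logit_linear"))
  }
  list(K = max(nv), r = NA_real_, t0 = NA_real_, type = "interpolation",
       year = year, nv = nv)
}

predict_logistic_fit <- function(fit, years) {
  switch(fit$type,
    constant = rep(fit$value, length(years)),
    interpolation = approx(fit$year, fit$nv, xout = years, rule = 2)$y,
    fit$K / (1 + exp(-fit$r * (years - fit$t0)))
  )
}

#' Reconstruct a fleet series from population growth
#'
#' For countries whose records are too sparse for curve fitting, the vessel
#' count is assumed to track population: each missing year is scaled from
#' the nearest observed anchor year (ties broken toward the earlier year) as
#' `NV_y = NV_anchor * population_y / population_anchor`.
#'
#' @param partial Tibble with `year`, `n_vessels` (observed anchors only).
#' @param covariates Tibble with `year`, `population` covering `years`.
#' @param years Full year range to reconstruct.
#' @return Complete tibble `year`, `n_vessels`, `provenance`.
#' @export
reconstruct_by_proxy <- function(partial, covariates, years = NULL) {
  if (nrow(partial) == 0) stop("no data for proxy scaling")
  if (is.null(years)) years <- seq(min(covariates$year), max(covariates$year))
  pop <- covariates$population[match(years, covariates$year)]
  if (anyNA(pop)) stop("covariates do not cover the requested year range")
  anchors <- dplyr::arrange(partial, .data$year)
  nearest <- vapply(years, function(y) {
    d <- abs(anchors$year - y)
    which(d == min(d))[1]  # ties resolved toward the earlier anchor
  }, integer(1))
  pop_anchor <- covariates$population[match(anchors$year[nearest],
                                            covariates$year)]
  nv <- anchors$n_vessels[nearest] * pop / pop_anchor
  prov <- ifelse(years %in% anchors$year, "observed", "reconstructed")
  nv[prov == "observed"] <-
    anchors$n_vessels[match(years[prov == "observed"], anchors$year)]
  tibble(year = years, n_vessels = pmax(0, nv), provenance = prov)
}

#' Fit the relation between unmotorized peak year and GDP per capita
#'
#' Across data-rich countries the year in which the unmotorized fleet peaks
#' (`Y_max`) relates weakly linearly to GDP per capita at that year; the
#' ordinary least-squares line is used to predict `Y_max` for countries
#' where no peak is observed.
#'
#' @param data_rich Tibble with columns `ymax` (year) and `gdp` (currency
#'   per person), one row per data-rich country.
#' @return An `unmotorized_model` list: `slope`, `intercept`, `residuals`,
#'   `sigma`, `n`.
#' @export
fit_ymax_gdp_relation <- function(data_rich) {
  if (nrow(data_rich) < 3) stop("need at least 3 (Y_max, GDP) points")
  if (sd(data_rich$gdp) < 1e-12) stop("degenerate design: constant GDP")
  f <- lm(ymax ~ gdp, data = data_rich)
  res <- unname(stats::residuals(f))
  structure(
    list(slope = unname(coef(f)[2]), intercept = unname(coef(f)[1]),
         residuals = res,
         sigma = sqrt(sum(res^2) / max(1, nrow(data_rich) - 2)),
         n = nrow(data_rich)),
    class = "unmotorized_model"
  )
}

#' Predict the unmotorized peak year from a GDP trajectory
#'
#' Solves `y = intercept + slope * gdp(y)` over the candidate years by
#' minimizing the residual, then rounds to the nearest year; values outside
#' the year range are clipped with a warning.
#'
#' @param model An [fit_ymax_gdp_relation()] model.
#' @param covariates Tibble with `year` and `gdp_per_capita`.
#' @return A single year.
#' @export
predict_ymax <- function(model, covariates) {
  resid <- abs(covariates$year -
                 (model$intercept + model$slope * covariates$gdp_per_capita))
  y <- covariates$year[which.min(resid)]
  rng <- range(covariates$year)
  if (y < rng[1] || y > rng[2]) {
    warning("predicted Y_max outside year range; clipped")
    y <- min(max(y, rng[1]), rng[2])
  }
  y
}

#' Reconstruct the unmotorized fleet around its peak year
#'
#' Before `Y_max` the unmotorized fleet is scaled by population growth from
#' the nearest observed anchor; after `Y_max` it changes at the motorized
#' artisanal fleet's relative growth rate times `coupling` (default -1:
#' when motorization grows 10\% the unmotorized fleet shrinks 10\%,
#' reflecting substitution - a positive coupling would contradict `Y_max`
#' being a maximum). The two pieces join continuously at `Y_max`.
#'
#' @param partial Observed unmotorized series (`year`, `n_vessels`).
#' @param motorized Complete motorized artisanal series (`year`,
#'   `n_vessels`) over the full range.
#' @param covariates Tibble with `year`, `population`, `gdp_per_capita`.
#' @param ymax Peak year; if `NULL`, predicted from `model`.
#' @param model Optional [fit_ymax_gdp_relation()] model used when `ymax`
#'   is not supplied.
#' @param coupling Post-peak coupling coefficient (default -1).
#' @param years Full year range.
#' @return Complete tibble `year`, `n_vessels`, `provenance`.
#' @export
reconstruct_unmotorized <- function(partial, motorized, covariates,
                                    ymax = NULL, model = NULL,
                                    coupling = -1, years = NULL) {
  if (is.null(motorized) || nrow(motorized) == 0) {
    stop("motorized series required")
  }
  if (nrow(partial) == 0) stop("no unmotorized observations to anchor on")
  if (is.null(years)) years <- seq(min(covariates$year), max(covariates$year))
  if (is.null(ymax)) {
    if (is.null(model)) stop("supply ymax or a fitted Y_max-GDP model")
    ymax <- predict_ymax(model, covariates[covariates$year %in% years, ])
  }
  if (ymax < min(years) || ymax > max(years)) {
    warning("Y_max outside year range; clipped")
    ymax <- min(max(ymax, min(years)), max(years))
  }
  mot <- motorized$n_vessels[match(years, motorized$year)]
  if (anyNA(mot)) stop("motorized series must cover the full year range")
  pop <- covariates$population[match(years, covariates$year)]
  if (anyNA(pop)) stop("covariates must cover the full year range")

  iy <- match(ymax, years)
  # multiplicative post-peak trajectory relative to Y_max
  traj <- rep(1, length(years))
  if (iy < length(years)) {
    rate <- diff(mot) / head(mot, -1)
    for (k in iy:(length(years) - 1)) {
      traj[k + 1] <- max(0, traj[k] * (1 + coupling * rate[k]))
    }
  }
  anchors <- dplyr::arrange(partial, .data$year)
  pre <- anchors[anchors$year <= ymax, ]
  post <- anchors[anchors$year > ymax, ]

  nv_ymax <- if (nrow(pre) > 0) {
    a <- pre[nrow(pre), ]  # nearest anchor at or before the peak
    a$n_vessels * pop[iy] / pop[match(a$year, years)]
  } else {
    a <- post[1, ]
    a$n_vessels / traj[match(a$year, years)]
  }

  nv <- numeric(length(years))
  for (j in seq_along(years)) {
    y <- years[j]
    if (y <= ymax) {
      if (nrow(pre) > 0) {
        d <- abs(pre$year - y)
        a <- pre[which(d == min(d))[1], ]
        nv[j] <- a$n_vessels * pop[j] / pop[match(a$year, years)]
      } else {
        nv[j] <- nv_ymax * pop[j] / pop[iy]
      }
    } else {
      if (nrow(post) > 0) {
        d <- abs(post$year - y)
        a <- post[which(d == min(d))[1], ]
        nv[j] <- a$n_vessels * traj[j] / traj[match(a$year, years)]
      } else {
        nv[j] <- nv_ymax * traj[j]
      }
    }
  }
  prov <- ifelse(years %in% anchors$year, "observed", "reconstructed")
  nv[prov == "observed"] <-
    anchors$n_vessels[match(years[prov == "observed"], anchors$year)]
  tibble(year = years, n_vessels = pmax(0, nv), provenance = prov)
}

#' Reconstruct every (country, sector) fleet series in a table
#'
#' Pipeline driver. Industrial and motorized-artisanal series get
#' [fit_logistic_series()], with a fall-back to population-proxy scaling
#' ([reconstruct_by_proxy()]) when a segment has fewer than three observed
#' points. The unmotorized sector follows its dedicated rules
#' ([reconstruct_unmotorized()]): its peak year is taken from the
#' observations when the observed maximum is interior, and otherwise
#' predicted from the Y_max-GDP relation fitted across the countries with
#' an observed peak (falling back to the observed maximum when fewer than
#' three countries can inform the relation).
#'
#' @param fleet_obs Long tibble: `saup`, `country`, `sector`, `year`,
#'   `n_vessels`.
#' @param covariates Tibble with `saup`, `year`, `population`,
#'   `gdp_per_capita`.
#' @param years Full year range.
#' @param disruption_years Optional named list: `saup` code (as character)
#'   to integer disruption years.
#' @param coupling Post-peak coupling for the unmotorized rules.
#' @return A list: `series` (complete long tibble with `provenance` and
#'   `method`), `fits` (per-group logistic fit summaries: `saup`, `sector`,
#'   `K`, `r`, `t0`, `type`, `mre`) and `ymax_model` (the fitted Y_max-GDP
#'   relation, or `NULL`).
#' @export
reconstruct_fleet_table <- function(fleet_obs, covariates, years,
                                    disruption_years = NULL, coupling = -1) {
  groups <- dplyr::distinct(fleet_obs, .data$saup, .data$country, .data$sector)
  out <- list()
  fit_rows <- list()
  for (i in which(groups$sector != "UP")) {
    g <- groups[i, ]
    obs <- fleet_obs[fleet_obs$saup == g$saup & fleet_obs$sector == g$sector, ]
    dis <- disruption_years[[as.character(g$saup)]]
    res <- tryCatch(
      fit_logistic_series(obs, disruption_years = dis, years = years),
      effortr_insufficient_data = function(e) NULL
    )
    if (!is.null(res)) {
      s <- res$series
      s$method <- "logistic"
      fit_rows[[length(fit_rows) + 1]] <-
        dplyr::bind_rows(lapply(res$fits, function(f) {
          tibble(saup = g$saup, sector = g$sector, K = f$K,
                 r = f$r %||% NA_real_, t0 = f$t0 %||% NA_real_,
                 type = f$type, mre = f$mre,
                 seg_start = f$segment[1], seg_end = f$segment[2])
        }))
    } else {
      cov <- covariates[covariates$saup == g$saup, ]
      s <- reconstruct_by_proxy(obs, cov, years)
      s$fitted <- NA_real_
      s$method <- "population_proxy"
    }
    s$saup <- g$saup; s$country <- g$country; s$sector <- g$sector
    out[[length(out) + 1]] <- s
  }
  done <- dplyr::bind_rows(out)

  # unmotorized sector: peak year from the observations where the observed
  # maximum is interior; otherwise predicted from the Y_max-GDP relation
  up_groups <- groups[groups$sector == "UP", ]
  ymax_obs <- numeric(0)
  gdp_at <- numeric(0)
  up_obs_list <- list()
  for (i in seq_len(nrow(up_groups))) {
    g <- up_groups[i, ]
    obs <- fleet_obs[fleet_obs$saup == g$saup & fleet_obs$sector == "UP", ]
    up_obs_list[[as.character(g$saup)]] <- obs
    peak <- obs$year[which.max(obs$n_vessels)]
    interior <- nrow(obs) >= 3 &&
      peak > min(obs$year) && peak < max(obs$year)
    if (interior) {
      cov <- covariates[covariates$saup == g$saup, ]
      ymax_obs[as.character(g$saup)] <- peak
      gdp_at[as.character(g$saup)] <-
        cov$gdp_per_capita[match(peak, cov$year)]
    }
  }
  ymax_model <- if (length(ymax_obs) >= 3 && sd(gdp_at) > 1e-12) {
    fit_ymax_gdp_relation(tibble(ymax = unname(ymax_obs),
                                 gdp = unname(gdp_at)))
  } else NULL

  for (i in seq_len(nrow(up_groups))) {
    g <- up_groups[i, ]
    obs <- up_obs_list[[as.character(g$saup)]]
    cov <- covariates[covariates$saup == g$saup, ]
    ym <- ymax_obs[as.character(g$saup)]
    if (is.na(ym) || length(ym) == 0) {
      ym <- if (!is.null(ymax_model)) {
        predict_ymax(ymax_model, cov[cov$year %in% years, ])
      } else {
        obs$year[which.max(obs$n_vessels)]
      }
    }
    apw <- done[done$saup == g$saup & done$sector == "APW",
                c("year", "n_vessels")]
    s <- if (nrow(apw) == length(years)) {
      reconstruct_unmotorized(obs, apw, cov, ymax = unname(ym),
                              coupling = coupling, years = years)
    } else {
      reconstruct_by_proxy(obs, cov, years)
    }
    s$fitted <- NA_real_
    s$method <- if (nrow(apw) == length(years)) "unmotorized_rules" else
      "population_proxy"
    s$saup <- g$saup; s$country <- g$country; s$sector <- g$sector
    out[[length(out) + 1]] <- s
  }

  list(
    series = dplyr::bind_rows(out) |>
      dplyr::select("saup", "country", "sector", "year", "n_vessels",
                    "provenance", "method", dplyr::any_of("fitted")),
    fits = dplyr::bind_rows(fit_rows),
    ymax_model = ymax_model
  )
}
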