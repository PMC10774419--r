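#' Configuration for the synthetic world generator
#'
#' Defines the study conditions under which every downstream stage is
#' exercised: the country registry size, the year range, the grid, and the
#' per-country ground-truth parameters (logistic fleet growth, unmotorized
#' peak year tied to GDP, engine-power equivalence, technological creep,
#' drifting length-class and gear compositions, observation gaps and noise).
#'
#' Each synthetic country occupies a two-row latitude band of the grid with a
#' stylized coastline along the western columns; catch intensity decays
#' exponentially with cell distance from the coast.
#'
#' @param n_countries Number of synthetic countries (>= 1).
#' @param years Integer vector of consecutive years (default 1950:2017).
#' @param lon_range,lat_range Grid bounding box in degrees. Defaults give
#'   each country a 2 x 10 cell band at 0.5 degrees.
#' @param cell_size Grid spacing in degrees (default 0.5).
#' @param coast_cols Westernmost columns flagged coastal.
#' @param catch_decay e-folding distance (in cells) of catch away from coast.
#' @param gap_fraction Fraction of years removed from each observed fleet
#'   series, in [0, 1); first and last year always retained.
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   observation noise on vessel counts (0 = noise free).
#' @param catch_noise_cv CV of multiplicative noise on annual catch totals.
#' @param share_obs_years Number of years at which compositions are observed.
#' @param coupling Post-peak coupling of the unmotorized fleet to the
#'   motorized growth rate (default -1: motorization substitutes for
#'   unmotorized craft).
#' @param creep_rates Named ground-truth creep rates per sector code.
#' @param ymax_slope,ymax_intercept,ymax_sd Linear relation generating the
#'   unmotorized peak year from GDP per capita at the peak
#'   (`Y_max = intercept + slope * gdp + noise`).
#' @param rng_seed Integer seed; identical configs give identical worlds.
#' @return A `world_config` list, validated.
#' @export
world_config <- function(n_countries = 10,
                         years = 1950:2017,
                         lon_range = c(0, 5),
                         lat_range = c(0, n_countries),
                         cell_size = 0.5,
                         coast_cols = 2,
                         catch_decay = 2,
                         gap_fraction = 0.3,
                         noise_cv = 0.05,
                         catch_noise_cv = 0.05,
                         share_obs_years = 6,
                         coupling = -1,
                         creep_rates = default_creep_rates(),
                         ymax_slope = -0.00125,
                         ymax_intercept = 2010,
                         ymax_sd = 3,
                         rng_seed = 1L) {
  cfg <- list(
    n_countries = as.integer(n_countries), years = as.integer(years),
    lon_range = lon_range, lat_range = lat_range, cell_size = cell_size,
    coast_cols = coast_cols, catch_decay = catch_decay,
    gap_fraction = gap_fraction, noise_cv = noise_cv,
    catch_noise_cv = catch_noise_cv, share_obs_years = share_obs_years,
    coupling = coupling, creep_rates = creep_rates,
    ymax_slope = ymax_slope, ymax_intercept = ymax_intercept,
    ymax_sd = ymax_sd, rng_seed = as.integer(rng_seed)
  )
  validate_world_config(cfg)
  class(cfg) <- "world_config"
  cfg
}

validate_world_config <- function(cfg) {
  if (cfg$n_countries < 1) stop("n_countries must be >= 1")
  if (length(cfg$years) < 3) stop("year range shorter than 3 years")
  if (any(diff(cfg$years) != 1)) stop("years must be consecutive")
  if (cfg$gap_fraction < 0 || cfg$gap_fraction >= 1) {
    stop("gap_fraction must be in [0, 1)")
  }
  if (cfg$noise_cv < 0 || cfg$catch_noise_cv < 0) stop("noise CVs must be >= 0")
  n_lat <- diff(cfg$lat_range) / cfg$cell_size
  n_lon <- diff(cfg$lon_range) / cfg$cell_size
  if (abs(n_lat - round(n_lat)) > 1e-9 || abs(n_lon - round(n_lon)) > 1e-9) {
    stop("cell_size must divide the bounding box evenly")
  }
  if (round(n_lat) * round(n_lon) < 2) stop("degenerate grid: a single cell")
  if (round(n_lat) < 2 * cfg$n_countries) {
    stop("lat_range too small: each country needs a 2-row band")
  }
  invisible(cfg)
}

logistic_curve <- function(years, K, r, t0) K / (1 + exp(-r * (years - t0)))

# lognormal multiplier with mean 1 and coefficient of variation cv
lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# per-class mean engine power (kW/vessel) and gross tonnage (GT/vessel)
class_power_base <- function() {
  setNames(c(10, 30, 120, 500, 1800), length_classes())
}
class_tonnage_base <- function() {
  setNames(c(2, 8, 50, 250, 1200), length_classes())
}

# length classes plausibly present in each sector
sector_classes <- function(sector) {
  switch(sector,
    UP  = length_classes()[1:2],
    APW = length_classes()[1:2],
    I   = length_classes()[2:5],
    stop("unknown sector: ", sector)
  )
}

# effort-side and catch-side gear vocabularies per sector; chosen so the
# gear-matching cascade is exercised at all three levels (exact, family,
# country) on synthetic data
sector_gears <- function(sector) {
  switch(sector,
    I   = c("bottom trawls", "longlines"),
    APW = c("gillnets", "lines"),
    UP  = c("gillnets", "pole and line")
  )
}
sector_catch_gears <- function(sector) {
  switch(sector,
    I   = c("bottom trawls", "longlines"),  # exact matches
    APW = c("gillnets", "longlines"),       # "lines" matches via family
    UP  = c("gillnets")                     # "pole and line" -> country level
  )
}

functional_groups <- function() c("pelagics", "demersals", "crustaceans")

# linear drift between a start and an end composition on the additive
# log-ratio scale (reference = last component); structural zeros stay zero
drift_composition <- function(start, end, years) {
  stopifnot(length(start) == length(end))
  f <- (years - years[1]) / (years[length(years)] - years[1])
  ref <- length(start)
  alr0 <- log(start[-ref] / start[ref])
  alr1 <- log(end[-ref] / end[ref])
  out <- sapply(f, function(fi) {
    a <- (1 - fi) * alr0 + fi * alr1
    v <- c(exp(a), 1)
    v[!is.finite(v)] <- 0
    v / sum(v)
  })
  t(out)  # years x classes
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic world with known ground truth
#'
#' Builds the full input bundle for the pipeline: gappy, noisy national fleet
#' observations following logistic growth; country covariates (population,
#' GDP per capita); gridded catch by country, gear, functional group and
#' cell, concentrated near a stylized coast; observed length-class and gear
#' compositions; engine power, tonnage and days-at-sea tables; and the
#' ground-truth record used by recovery tests.
#'
#' The unmotorized fleet rises in proportion to population up to its peak
#' year `Y_max` (tied to GDP per capita through a linear relation) and then
#' declines at the motorized fleet's growth rate times the configured
#' coupling. Artisanal catch is generated so that total artisanal catch is
#' proportional to `NV_unmotorized * PPV_eq + P_motorized`, which makes the
#' engine-power equivalence identifiable.
#'
#' @param config A [world_config()].
#' @return A list of class `synthetic_world` with elements `config`, `grid`,
#'   `registry`, `fleet_obs`, `covariates`, `catch`, `length_share_obs`,
#'   `gear_share_obs`, `power_obs`, `tonnage_obs`, `das_table`,
#'   `artisanal_catch` and `truth`.
#' @export
generate_world <- function(config) {
  validate_world_config(config)
  set.seed(config$rng_seed)
  years <- config$years
  ny <- length(years)
  n <- config$n_countries

  grid <- make_grid(config$lat_range, config$lon_range, config$cell_size)
  grid <- set_coastal_columns(grid, config$coast_cols)

  registry <- tibble(
    saup = 100L + seq_len(n),
    country = sprintf("C%03d", seq_len(n)),
    band = seq_len(n)
  )

  # --- per-country ground-truth parameters ------------------------------
  params <- lapply(seq_len(n), function(i) {
    gdp_at_ymax <- runif(1, 5000, 45000)
    ymax <- round(config$ymax_intercept + config$ymax_slope * gdp_at_ymax +
                    rnorm(1, 0, config$ymax_sd))
    ymax <- min(max(ymax, years[5]), years[ny - 5])
    list(
      saup = registry$saup[i],
      K = c(I = exp(rnorm(1, log(2000), 0.4)),
            APW = exp(rnorm(1, log(5000), 0.4)),
            UP = exp(rnorm(1, log(8000), 0.4))),
      r = c(I = runif(1, 0.06, 0.18), APW = runif(1, 0.04, 0.12)),
      # motorization drives the unmotorized decline: the motorized logistic
      # midpoint falls shortly after the unmotorized peak year
      t0 = c(I = runif(1, 1960, 1995), APW = ymax + runif(1, 0, 8)),
      ymax = ymax, gdp_at_ymax = gdp_at_ymax,
      gdp_growth = runif(1, 0.01, 0.03),
      pop0 = runif(1, 1e5, 5e6), pop_growth = runif(1, 0.005, 0.025),
      ppv_eq = runif(1, 3, 8),
      q_art = runif(1, 0.02, 0.08), q_ind = runif(1, 0.02, 0.08),
      power_factor = runif(1, 0.8, 1.2),
      tonnage_factor = runif(1, 0.8, 1.2),
      fg_weights = setNames(rdirichlet1(rep(2, 3)), functional_groups()),
      catch_gear_split = lapply(
        setNames(nm = sector_codes()),
        function(s) setNames(rdirichlet1(rep(2, length(sector_catch_gears(s)))),
                             sector_catch_gears(s))
      )
    )
  })
  names(params) <- registry$country

  # --- covariates -------------------------------------------------------
  covariates <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    tibble(
      saup = p$saup, country = registry$country[i], year = years,
      population = p$pop0 * (1 + p$pop_growth)^(years - years[1]),
      gdp_per_capita = p$gdp_at_ymax * (1 + p$gdp_growth)^(years - p$ymax)
    )
  }))

  # --- fleet ground truth -----------------------------------------------
  fleet_truth <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    pop <- covariates$population[covariates$saup == p$saup]
    nv_i <- logistic_curve(years, p$K["I"], p$r["I"], p$t0["I"])
    nv_apw <- logistic_curve(years, p$K["APW"], p$r["APW"], p$t0["APW"])
    iy <- match(p$ymax, years)
    nv_up <- numeric(ny)
    nv_up[1:iy] <- p$K["UP"] * pop[1:iy] / pop[iy]
    if (iy < ny) {
      apw_rate <- diff(nv_apw) / head(nv_apw, -1)
      for (k in iy:(ny - 1)) {
        nv_up[k + 1] <- max(0, nv_up[k] * (1 + config$coupling * apw_rate[k]))
      }
    }
    tibble(
      saup = p$saup, country = registry$country[i],
      sector = rep(sector_codes(), each = ny), year = rep(years, 3),
      n_vessels = c(nv_i, nv_apw, nv_up)
    )
  }))

  # --- observations: gaps + multiplicative noise ------------------------
  n_drop <- round(config$gap_fraction * ny)
  n_drop <- min(n_drop, ny - 2)  # first and last year always retained
  fleet_obs <- fleet_truth |>
    dplyr::group_by(.data$saup, .data$sector) |>
    dplyr::group_modify(function(d, key) {
      keep <- rep(TRUE, ny)
      if (n_drop > 0) {
        droppable <- 2:(ny - 1)
        keep[sample(droppable, n_drop)] <- FALSE
      }
      d <- d[keep, , drop = FALSE]
      if (config$noise_cv > 0) {
        d$n_vessels <- round(d$n_vessels * lnorm_noise(nrow(d), config$noise_cv))
      }
      d
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(provenance = "observed") |>
    dplyr::select("saup", "country", "sector", "year", "n_vessels", "provenance")

  # --- compositions: length-class and gear shares -----------------------
  obs_years <- sort(unique(c(
    years[1], years[ny],
    years[round(seq(1, ny, length.out = config$share_obs_years))]
  )))
  comp_tables <- lapply(seq_len(n), function(i) {
    p <- params[[i]]
    len_list <- list(); gear_list <- list(); truth_len <- list()
    for (s in sector_codes()) {
      cls <- sector_classes(s)
      start <- rdirichlet1(rep(2, length(cls)))
      end <- rdirichlet1(rep(2, length(cls)))
      sh <- drift_composition(start, end, years)
      truth_len[[s]] <- tibble(
        saup = p$saup, sector = s,
        year = rep(years, length(cls)),
        length_class = rep(cls, each = ny),
        share = as.vector(sh)
      )
      obs <- sh[match(obs_years, years), , drop = FALSE]
      len_list[[s]] <- tibble(
        saup = p$saup, sector = s,
        year = rep(obs_years, length(cls)),
        length_class = rep(cls, each = length(obs_years)),
        share = as.vector(obs)
      )
      gears <- sector_gears(s)
      gstart <- rdirichlet1(rep(2, length(gears)))
      gend <- rdirichlet1(rep(2, length(gears)))
      gsh <- drift_composition(gstart, gend, years)
      gobs <- gsh[match(obs_years, years), , drop = FALSE]
      gear_list[[s]] <- tibble(
        saup = p$saup, sector = s,
        year = rep(obs_years, length(gears)),
        gear = rep(gears, each = length(obs_years)),
        share = as.vector(gobs)
      )
    }
    list(len = dplyr::bind_rows(len_list), gear = dplyr::bind_rows(gear_list),
         truth_len = dplyr::bind_rows(truth_len))
  })
  length_share_obs <- dplyr::bind_rows(lapply(comp_tables, `[[`, "len"))
  gear_share_obs <- dplyr::bind_rows(lapply(comp_tables, `[[`, "gear"))
  length_share_truth <- dplyr::bind_rows(lapply(comp_tables, `[[`, "truth_len"))

  # --- power / tonnage observations -------------------------------------
  pw_years <- years[round(seq(1, ny, length.out = 3))]
  power_obs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    dplyr::bind_rows(lapply(c("I", "APW"), function(s) {
      cls <- sector_classes(s)
      tidyr::crossing(year = pw_years, length_class = cls) |>
        dplyr::mutate(
          saup = p$saup, sector = s,
          mean_kw = unname(class_power_base()[.data$length_class]) *
            p$power_factor * (1 + 0.004)^(.data$year - years[1])
        )
    }))
  }))
  tonnage_obs <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    dplyr::bind_rows(lapply(c("I", "APW", "UP"), function(s) {
      cls <- sector_classes(s)
      tibble(
        saup = p$saup, sector = s, length_class = cls,
        year = years[1],
        mean_gt = unname(class_tonnage_base()[cls]) * p$tonnage_factor
      )
    }))
  }))

  # --- days at sea / activity -------------------------------------------
  das_years <- seq(years[1], years[ny], by = 5)
  has_activity <- runif(n) < 0.25
  das_table <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    dplyr::bind_rows(lapply(sector_codes(), function(s) {
      tidyr::crossing(year = das_years, gear = sector_gears(s)) |>
        dplyr::mutate(
          saup = p$saup, sector = s,
          das = round(runif(1, 120, 280)),
          r_act = if (has_activity[i]) runif(1, 0.6, 0.85) else NA_real_
        )
    }))
  })) |>
    dplyr::select("saup", "sector", "gear", "year", "das", "r_act")

  # --- artisanal catch (Eq.-1 structure) and gridded catch --------------
  # true total motorized artisanal engine power, consistent with power_obs
  # (same per-class base, country factor, and 0.4%/yr drift)
  power_factors <- vapply(params, function(p) p$power_factor, numeric(1))
  apw_power <- fleet_truth |>
    dplyr::filter(.data$sector == "APW") |>
    dplyr::inner_join(length_share_truth |> dplyr::filter(.data$sector == "APW"),
                      by = c("saup", "sector", "year")) |>
    dplyr::left_join(
      tibble(length_class = length_classes(),
             base_kw = unname(class_power_base())),
      by = "length_class"
    ) |>
    dplyr::group_by(.data$saup, .data$year) |>
    dplyr::summarise(
      p_total = sum(.data$n_vessels * .data$share * .data$base_kw) *
        (1 + 0.004)^(.data$year[1] - years[1]),
      .groups = "drop"
    ) |>
    dplyr::mutate(p_total = .data$p_total *
                    power_factors[match(.data$saup, registry$saup)])

  artisanal_catch <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    nv_up <- fleet_truth$n_vessels[fleet_truth$saup == p$saup &
                                     fleet_truth$sector == "UP"]
    p_apw <- apw_power$p_total[apw_power$saup == p$saup]
    tibble(
      saup = p$saup, country = registry$country[i], year = years,
      catch = p$q_art * (nv_up * p$ppv_eq + p_apw) *
        lnorm_noise(ny, config$catch_noise_cv)
    )
  }))

  # stable per-cell spatial pattern: exponential decay from coast times a
  # fixed lognormal texture per (country, cell, functional group)
  lat_rows <- sort(unique(grid$lat))
  catch <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    p <- params[[i]]
    band_lats <- lat_rows[(2 * i - 1):(2 * i)]
    cells <- grid[grid$lat %in% band_lats, ]
    base_w <- exp(-cells$dist_coast / config$catch_decay)
    texture <- lapply(functional_groups(), function(fg) {
      w <- base_w * lnorm_noise(nrow(cells), 0.3)
      w / sum(w)
    })
    names(texture) <- functional_groups()
    sector_tot <- lapply(setNames(nm = sector_codes()), function(s) {
      nv <- fleet_truth$n_vessels[fleet_truth$saup == p$saup &
                                    fleet_truth$sector == s]
      if (s == "I") p$q_ind * nv * class_power_base()[[length_classes()[3]]]
      else artisanal_catch$catch[artisanal_catch$saup == p$saup] / 2
    })
    dplyr::bind_rows(lapply(sector_codes(), function(s) {
      gs <- p$catch_gear_split[[s]]
      dplyr::bind_rows(lapply(names(gs), function(g) {
        dplyr::bind_rows(lapply(functional_groups(), function(fg) {
          tibble(
            year = rep(years, each = nrow(cells)),
            saup = p$saup, sector = s, gear = g, fgroup = fg,
            lat = rep(cells$lat, ny), lon = rep(cells$lon, ny),
            catch = rep(sector_tot[[s]], each = nrow(cells)) *
              gs[[g]] * p$fg_weights[[fg]] * rep(texture[[fg]], ny)
          )
        }))
      }))
    }))
  }))
  catch <- dplyr::filter(catch, .data$catch > 0)

  truth <- list(
    params = params,
    fleet = fleet_truth,
    length_shares = length_share_truth,
    apw_power = apw_power,
    ymax = tibble(
      saup = registry$saup,
      country = registry$country,
      ymax = vapply(params, function(p) p$ymax, numeric(1)),
      gdp_at_ymax = vapply(params, function(p) p$gdp_at_ymax, numeric(1)),
      ppv_eq = vapply(params, function(p) p$ppv_eq, numeric(1))
    ),
    creep_rates = config$creep_rates
  )

  structure(
    list(config = config, grid = grid, registry = registry,
         fleet_obs = fleet_obs, covariates = covariates, catch = catch,
         length_share_obs = length_share_obs, gear_share_obs = gear_share_obs,
         power_obs = power_obs, tonnage_obs = tonnage_obs,
         das_table = das_table, artisanal_catch = artisanal_catch,
         truth = truth),
    class = "synthetic_world"
  )
}

#' Distort a mapped effort grid into an AIS-like comparison grid
#'
#' Emulates the main pathologies of satellite AIS coverage: multiplicative
#' cell-level noise, and preferential loss of small vessels (receiver and
#' transponder coverage is biased towards large industrial vessels). With no
#' distortion the input is returned unchanged.
#'
#' @param effort_grid An effort grid (Table-1 style tibble with `NomActive`,
#'   `EffActive`, `Length_Category` columns).
#' @param noise_cv CV of multiplicative lognormal noise applied per row.
#' @param coverage Retention probability for rows of small-vessel classes
#'   (1 = keep all, 0 = drop all).
#' @param small_classes Length classes subject to coverage thinning
#'   (default: vessels under 12 m).
#' @param seed Optional integer seed for the distortion draws.
#' @return A distorted copy of `effort_grid`.
#' @export
generate_ais_like_grid <- function(effort_grid, noise_cv = 0, coverage = 1,
                                   small_classes = length_classes()[1:2],
                                   seed = NULL) {
  stopifnot(is.data.frame(effort_grid))
  if (coverage < 0 || coverage > 1) stop("coverage must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  out <- effort_grid
  if (coverage < 1) {
    small <- out$Length_Category %in% small_classes
    dropped <- small & (runif(nrow(out)) >= coverage)
    out$NomActive[dropped] <- 0
    if ("EffActive" %in% names(out)) out$EffActive[dropped] <- 0
  }
  if (noise_cv > 0) {
    f <- lnorm_noise(nrow(out), noise_cv)
    out$NomActive <- out$NomActive * f
    if ("EffActive" %in% names(out)) out$EffActive <- out$EffActive * f
  }
  out
}
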