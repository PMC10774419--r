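#' Vectorized days-at-sea lookup for a table of segment keys
#'
#' The same key-relaxation cascade as [fill_days_at_sea()] (exact, drop
#' year, drop gear, drop country), applied by joins so a whole segment
#' table is resolved at once.
#'
#' @param keys Tibble `saup`, `sector`, `gear`, `year`.
#' @param das_table Tibble `saup`, `sector`, `gear`, `year`, `das`, `r_act`.
#' @return `keys` with `das`, `r_act` (NA where absent everywhere) and
#'   `das_provenance`.
#' @export
fill_das_table <- function(keys, das_table) {
  agg <- function(d, by) {
    d |>
      dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
      dplyr::summarise(das = mean(.data$das),
                       r_act = if (any(!is.na(.data$r_act))) {
                         mean(.data$r_act, na.rm = TRUE)
                       } else NA_real_,
                       .groups = "drop")
  }
  lvl <- list(
    exact = agg(das_table, c("saup", "sector", "gear", "year")),
    segment = agg(das_table, c("saup", "sector", "gear")),
    country = agg(das_table, c("saup", "sector")),
    region = agg(das_table, "sector")
  )
  out <- keys
  out$das <- NA_real_; out$r_act <- NA_real_
  out$das_provenance <- NA_character_
  for (nm in names(lvl)) {
    by <- switch(nm, exact = c("saup", "sector", "gear", "year"),
                 segment = c("saup", "sector", "gear"),
                 country = c("saup", "sector"), region = "sector")
    todo <- is.na(out$das)
    if (!any(todo)) break
    m <- dplyr::left_join(out[todo, names(keys)], lvl[[nm]], by = by)
    hit <- !is.na(m$das)
    idx <- which(todo)[hit]
    out$das[idx] <- m$das[hit]
    out$r_act[idx] <- m$r_act[hit]
    out$das_provenance[idx] <- nm
  }
  out
}

#' Run the full reconstruction-to-mapping pipeline on a synthetic world
#'
#' Executes every stage in order: fleet reconstruction (logistic fits with
#' population-proxy fallback), compositional smoothing of length-class and
#' gear shares, integer disaggregation into fleet segments, engine power
#' and tonnage attachment, engine-power equivalence for the unmotorized
#' fleet, days-at-sea lookup with the activity-ratio default, nominal and
#' effective effort (creep compounded from the 1949 baseline), and spatial
#' allocation onto the grid.
#'
#' If a country's motor equivalence cannot be solved inside the 20-80\%
#' window, the window is widened to 10-90\%; failing that, the median
#' equivalence of the solved countries is borrowed.
#'
#' @param world A [generate_world()] bundle.
#' @param sigma Spatial smoothing width in cells (default 1).
#' @param creep_rates Named per-sector creep rates (default
#'   [default_creep_rates()]).
#' @param map If `FALSE`, stop after the national effort table (no spatial
#'   allocation).
#' @return A list: `reconstruction` (series + fits), `length_shares`,
#'   `gear_shares`, `segments` (national effort table), `motor_equivalence`
#'   (per-country), `effort` (mapped grid, when `map = TRUE`).
#' @export
run_pipeline <- function(world, sigma = 1,
                         creep_rates = default_creep_rates(), map = TRUE) {
  cfg <- world$config
  years <- cfg$years

  # 1. fleet reconstruction ---------------------------------------------
  rec <- reconstruct_fleet_table(world$fleet_obs, world$covariates, years)

  # 2. compositional smoothing ------------------------------------------
  smooth_all <- function(obs, key) {
    obs |>
      dplyr::group_by(.data$saup, .data$sector) |>
      dplyr::group_modify(function(d, k) {
        smooth_share_series(d, years, key = key)
      }) |>
      dplyr::ungroup()
  }
  length_shares <- smooth_all(world$length_share_obs, "length_class")
  gear_shares <- smooth_all(world$gear_share_obs, "gear")

  # 3. integer disaggregation -------------------------------------------
  skeleton <- disaggregate_fleet(rec$series, length_shares, gear_shares)

  # 4. motor equivalence, then power/tonnage ----------------------------
  recs <- rec$series
  # the equivalence solve needs an APW national power series, so power is
  # attached to the motorized artisanal segments first
  apw_power_series <- attach_power_tonnage(
    skeleton |> dplyr::filter(.data$sector == "APW"),
    world$power_obs, world$tonnage_obs, years
  ) |>
    dplyr::group_by(.data$saup, .data$year) |>
    dplyr::summarise(p_total = sum(.data$p_total), .groups = "drop")

  solved <- list()
  for (code in unique(world$registry$saup)) {
    ca <- world$artisanal_catch |> dplyr::filter(.data$saup == code) |>
      dplyr::select("year", "catch")
    up <- recs |> dplyr::filter(.data$saup == code, .data$sector == "UP") |>
      dplyr::select("year", "n_vessels")
    ap <- recs |> dplyr::filter(.data$saup == code, .data$sector == "APW") |>
      dplyr::select("year", "n_vessels")
    pw <- apw_power_series |> dplyr::filter(.data$saup == code)
    me <- tryCatch(
      solve_motor_equivalence(ca, up, ap, pw),
      error = function(e) tryCatch(
        solve_motor_equivalence(ca, up, ap, pw, window = c(0.1, 0.9)),
        error = function(e2) NULL
      )
    )
    solved[[as.character(code)]] <- me
  }
  ppv <- vapply(solved, function(m) if (is.null(m)) NA_real_ else m$ppv_eq,
                numeric(1))
  if (all(is.na(ppv))) stop("motor equivalence unsolvable for every country")
  ppv[is.na(ppv)] <- median(ppv, na.rm = TRUE)
  motor_equivalence <- tibble(saup = as.integer(names(ppv)),
                              ppv_eq = unname(ppv))

  up_power_obs <- skeleton |>
    dplyr::filter(.data$sector == "UP") |>
    dplyr::distinct(.data$saup, .data$sector, .data$length_class) |>
    dplyr::mutate(year = years[1],
                  mean_kw = motor_equivalence$ppv_eq[
                    match(.data$saup, motor_equivalence$saup)])
  capacity <- attach_power_tonnage(
    skeleton, dplyr::bind_rows(world$power_obs, up_power_obs),
    world$tonnage_obs, years
  )

  # 5. days at sea, activity, nominal and effective effort --------------
  capacity <- fill_das_table(capacity, world$das_table)
  capacity$r_act[is.na(capacity$r_act)] <- default_activity_ratio()
  capacity$nom_active <- nominal_effort(capacity$p_total, capacity$das,
                                        capacity$r_act)
  segments <- capacity |>
    dplyr::group_by(.data$sector) |>
    dplyr::group_modify(function(d, key) {
      cm <- creep_model(creep_rates[[key$sector]])
      d$eff_active <- effective_effort(d$year, d$nom_active, cm)
      d
    }) |>
    dplyr::ungroup()

  out <- list(reconstruction = rec, length_shares = length_shares,
              gear_shares = gear_shares, segments = segments,
              motor_equivalence = motor_equivalence)
  if (map) {
    out$effort <- map_effort(segments, world$catch, world$grid, sigma = sigma)
  }
  out
}
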