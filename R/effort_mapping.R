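EFFORT_SEG_COLS <- c("Year", "SAUP", "Sector", "Length_Category", "Gear")
EFFORT_VALUE_COLS <- c("NV", "P", "GT", "NomActive", "EffActive")

seg_cols_of <- function(df) intersect(EFFORT_SEG_COLS, names(df))
value_cols_of <- function(df) intersect(EFFORT_VALUE_COLS, names(df))

gear_family_of <- function(gear, family_table) {
  fam <- family_table$family[match(gear, family_table$gear)]
  if (anyNA(fam)) {
    stop("unmapped gear code: ",
         paste(unique(gear[is.na(fam)]), collapse = ", "))
  }
  fam
}

# packed integer key for (lat, lon) cell lookups; avoids string pastes on
# multi-million-row tables
cell_key <- function(lat, lon, cs) {
  OFF <- 2048; BASE <- 2 * OFF
  (round((lat - cs / 2) / cs) + OFF) * BASE + (round((lon - cs / 2) / cs) + OFF)
}

grid_cell_size <- function(grid) {
  u <- sort(unique(grid$lat))
  if (length(u) > 1) min(diff(u)) else {
    v <- sort(unique(grid$lon)); min(diff(v))
  }
}

#' Match an effort gear to the catch database's gear vocabulary
#'
#' The catch maps carry their own gear labels, so effort is associated to
#' catch through a cascade: the identical gear when present (`"exact"`);
#' otherwise every catch gear in the same family - nets, trawls, lines, ...
#' (`"family"`); otherwise all catch gears of the country and year
#' (`"country"`). The cascade is total: an effort gear is never dropped.
#'
#' @param effort_gear Single gear label on the effort side.
#' @param catch_gears Gear labels present in the catch data for the
#'   (country, year) under consideration.
#' @param family_table Gear-to-family map, see [default_gear_families()].
#' @return List with `level` (`"exact"`, `"family"` or `"country"`) and
#'   `gears`, the matched catch gears.
#' @export
match_gear <- function(effort_gear, catch_gears,
                       family_table = default_gear_families()) {
  fam <- gear_family_of(effort_gear, family_table)
  if (effort_gear %in% catch_gears) {
    return(list(level = "exact", gears = effort_gear))
  }
  cfam <- family_table$family[match(catch_gears, family_table$gear)]
  in_family <- catch_gears[!is.na(cfam) & cfam == fam]
  if (length(in_family) > 0) {
    return(list(level = "family", gears = in_family))
  }
  list(level = "country", gears = catch_gears)
}

#' Prorate a segment's effort to functional groups and vessel categories
#'
#' The catch maps resolve functional groups but not vessel characteristics,
#' so effort is split across (functional group, vessel category) pairs as
#' the outer product of the catch composition across functional groups and
#' the gross-tonnage shares across categories (vessels are assumed to fish
#' in proportion to their capacity), renormalized to conserve the segment
#' total. If the matched catch is all zero, effort is spread uniformly over
#' the functional groups with a warning.
#'
#' @param effort_total Segment effort to distribute.
#' @param fg_catch Tibble `fgroup`, `catch` (tonnes, >= 0).
#' @param tonnage_shares Named numeric: gross-tonnage share per vessel
#'   category, summing to 1.
#' @return Tibble `fgroup`, `category`, `effort` summing to `effort_total`.
#' @export
allocate_to_functional_groups <- function(effort_total, fg_catch,
                                          tonnage_shares = c(all = 1)) {
  stopifnot(all(fg_catch$catch >= 0))
  if (abs(sum(tonnage_shares) - 1) > 1e-6) {
    stop("tonnage shares must sum to 1")
  }
  w <- fg_catch$catch
  if (sum(w) == 0) {
    warning("all-zero catch: effort spread uniformly over functional groups")
    w <- rep(1, length(w))
  }
  w <- w / sum(w)
  out <- tidyr::crossing(fgroup = fg_catch$fgroup,
                         category = names(tonnage_shares))
  out$effort <- effort_total * w[match(out$fgroup, fg_catch$fgroup)] *
    unname(tonnage_shares[out$category])
  out$effort <- out$effort * effort_total / max(sum(out$effort),
                                                .Machine$double.xmin)
  if (effort_total == 0) out$effort <- 0
  out
}

#' Prorate effort across grid cells from the catch distribution
#'
#' Within each functional group, the relative catch across grid cells is
#' the spatial weight: `effort_cell = effort_fg * catch_cell / sum(catch)`.
#'
#' @param effort_by_fg Tibble `fgroup`, `effort`.
#' @param catch_cells Tibble `fgroup`, `lat`, `lon`, `catch`.
#' @return Tibble `fgroup`, `lat`, `lon`, `effort`; per functional group the
#'   cell efforts sum to the group's effort.
#' @export
allocate_to_cells <- function(effort_by_fg, catch_cells) {
  stopifnot(all(catch_cells$catch >= 0))
  out <- catch_cells |>
    dplyr::inner_join(effort_by_fg, by = "fgroup") |>
    dplyr::group_by(.data$fgroup) |>
    dplyr::mutate(effort = .data$effort * .data$catch / sum(.data$catch)) |>
    dplyr::ungroup() |>
    dplyr::select("fgroup", "lat", "lon", "effort")
  if (any(!is.finite(out$effort))) {
    stop("functional group with zero total catch: no spatial weights")
  }
  out
}

# allowed-cell rule shared by masking and smoothing: the unpowered sector is
# confined to coastal cells; trawl-family gears are excluded from cells
# under a trawl ban
cell_allowed <- function(sector, gear, grid_attrs,
                         family_table = default_gear_families()) {
  fam <- gear_family_of(gear, family_table)
  ok <- rep(TRUE, nrow(grid_attrs))
  ok[sector == "UP" & !grid_attrs$coastal] <- FALSE
  ok[fam == "trawls" & grid_attrs$trawl_ban] <- FALSE
  ok
}

#' Zero out disallowed cells and redistribute the effort
#'
#' Gear and sector specificities constrain where effort can occur: bottom
#' trawling is banned in flagged cells, and the unpowered fleet is limited
#' to coastal waters. Effort in disallowed cells is set to zero and
#' redistributed proportionally over the segment's allowed cells, so each
#' segment's total is conserved.
#'
#' @param effort Effort grid tibble with `Lat`, `Lon`, the segment key
#'   columns (`Year`, `SAUP`, `Sector`, `Length_Category`, `Gear` - those
#'   present are used) and any of the value columns `NV`, `P`, `GT`,
#'   `NomActive`, `EffActive`.
#' @param grid A grid from [make_grid()] with `coastal` and `trawl_ban` set.
#' @param family_table Gear-to-family map.
#' @return The effort tibble with disallowed rows removed and allowed rows
#'   rescaled; errors if a segment has no allowed cell.
#' @export
apply_constraints <- function(effort, grid,
                              family_table = default_gear_families()) {
  sc <- seg_cols_of(effort); vc <- value_cols_of(effort)
  cs <- grid_cell_size(grid)
  ga <- grid[match(cell_key(effort$Lat, effort$Lon, cs),
                   cell_key(grid$lat, grid$lon, cs)),
             c("coastal", "trawl_ban")]
  if (anyNA(ga$coastal)) stop("effort contains cells outside the grid")
  allowed <- cell_allowed(effort$Sector, effort$Gear, ga, family_table)
  grp <- do.call(paste, c(effort[sc], sep = "\r"))
  n_allowed <- ave(as.numeric(allowed), grp, FUN = sum)
  if (any(n_allowed == 0)) {
    bad <- unique(grp[n_allowed == 0])
    stop("all cells disallowed for segment(s): ",
         paste(gsub("\r", " / ", utils::head(bad, 5)), collapse = "; "))
  }
  for (v in vc) {
    tot <- ave(effort[[v]], grp, FUN = sum)
    kept <- ave(ifelse(allowed, effort[[v]], 0), grp, FUN = sum)
    # proportional redistribution over allowed cells; if all mass sat on
    # disallowed cells, spread the total evenly over the allowed ones
    effort[[v]] <- ifelse(allowed,
                          ifelse(kept > 0, effort[[v]] * tot / kept,
                                 tot / n_allowed),
                          0)
  }
  effort[allowed, , drop = FALSE]
}

gaussian_kernel_1d <- function(sigma, truncate = 3) {
  half <- ceiling(truncate * sigma)
  offs <- -half:half
  k <- exp(-offs^2 / (2 * sigma^2))
  list(offsets = offs, weights = k / sum(k))
}

#' Spread mapped effort normally into surrounding cells
#'
#' To avoid artificially sharp hotspots, each segment's cell values are
#' convolved with a 2-D Gaussian kernel (default sigma of one cell,
#' truncated at three sigma). Mass that would land outside the grid or in a
#' cell disallowed for the segment (coastal rule for the unpowered sector,
#' trawl bans) is folded back by renormalizing the segment to its original
#' total, so smoothing conserves effort and never re-enters banned cells.
#' `sigma = 0` is the identity.
#'
#' @param effort Effort grid tibble (see [apply_constraints()]).
#' @param grid Grid with mask attributes.
#' @param sigma Kernel width in cells.
#' @param truncate Kernel truncation in multiples of sigma.
#' @param family_table Gear-to-family map (for the allowed-cell rule).
#' @return Smoothed effort tibble; per-segment totals unchanged within
#'   floating-point tolerance.
#' @export
smooth_spread <- function(effort, grid, sigma = 1, truncate = 3,
                          family_table = default_gear_families()) {
  if (sigma < 0) stop("kernel width must be >= 0")
  if (sigma == 0 || nrow(effort) == 0) return(effort)
  sc <- seg_cols_of(effort); vc <- value_cols_of(effort)
  cs <- grid_cell_size(grid)
  ker <- gaussian_kernel_1d(sigma, truncate)

  # collapse all non-spatial, non-value columns into one integer key; the
  # two separable convolution passes then aggregate with rowsum() on a
  # packed (group, lat index, lon index) integer key
  other <- setdiff(names(effort), c("Lat", "Lon", vc))
  key <- do.call(paste, c(effort[other], sep = "\r"))
  ukey <- unique(key)
  lut <- effort[match(ukey, key), other, drop = FALSE]
  lut$.gid <- seq_along(ukey)
  gid <- match(key, ukey)
  to_idx <- function(x) round((x - cs / 2) / cs)
  dt <- data.table::data.table(.gid = gid,
                               il = to_idx(effort$Lat),
                               ilon = to_idx(effort$Lon))
  for (v in vc) data.table::set(dt, j = v, value = effort[[v]])

  pass <- function(dt, along) {
    n <- nrow(dt)
    idx <- rep(seq_len(n), times = length(ker$offsets))
    offj <- rep(ker$offsets, each = n)
    wj <- rep(ker$weights, each = n)
    e <- dt[idx]
    coord <- if (along == "lat") "il" else "ilon"
    data.table::set(e, j = coord, value = e[[coord]] + offj)
    for (v in vc) data.table::set(e, j = v, value = e[[v]] * wj)
    e[, lapply(.SD, sum), by = c(".gid", "il", "ilon"), .SDcols = vc]
  }
  p2 <- pass(pass(dt, "lat"), "lon")
  sm <- as_tibble(p2)
  sm$Lat <- sm$il * cs + cs / 2
  sm$Lon <- sm$ilon * cs + cs / 2
  sm$il <- NULL; sm$ilon <- NULL
  sm <- dplyr::left_join(sm, lut, by = ".gid")

  ga <- grid[match(cell_key(sm$Lat, sm$Lon, cs),
                   cell_key(grid$lat, grid$lon, cs)),
             c("coastal", "trawl_ban")]
  on_grid <- !is.na(ga$coastal)
  keep <- on_grid
  keep[on_grid] <- cell_allowed(sm$Sector[on_grid], sm$Gear[on_grid],
                                ga[on_grid, , drop = FALSE], family_table)
  sm <- sm[keep, , drop = FALSE]

  before <- effort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(sc))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vc), sum), .groups = "drop")
  after <- sm |>
    dplyr::group_by(dplyr::across(dplyr::all_of(sc))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vc), sum), .groups = "drop")
  scale <- dplyr::left_join(before, after, by = sc,
                            suffix = c("_before", "_after"))
  sm <- dplyr::left_join(sm, scale, by = sc)
  for (v in vc) {
    f <- sm[[paste0(v, "_before")]] / sm[[paste0(v, "_after")]]
    f[!is.finite(f)] <- 0
    sm[[v]] <- sm[[v]] * f
  }
  sm |>
    dplyr::select(dplyr::all_of(names(effort))) |>
    dplyr::filter(dplyr::if_any(dplyr::all_of(vc), ~ .x > 0))
}

#' Aggregate a mapped effort grid by region
#'
#' Sums effort per region label (for instance Large Marine Ecosystems) and
#' year; cells without a label fall into `"none"`, so regional sums plus the
#' unlabelled remainder equal the global total.
#'
#' @param effort Effort grid tibble with `Lat`, `Lon` and value columns.
#' @param region_map Tibble `lat`, `lon`, `region`.
#' @return Tibble of `region` (and `Year` when present) with summed value
#'   columns.
#' @export
aggregate_by_region <- function(effort, region_map) {
  vc <- value_cols_of(effort)
  effort$region <- region_map$region[match(paste(effort$Lat, effort$Lon),
                                           paste(region_map$lat,
                                                 region_map$lon))]
  effort$region[is.na(effort$region)] <- "none"
  by <- c(intersect("Year", names(effort)), "region")
  effort |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(vc), sum), .groups = "drop")
}

#' Map national effort segments onto the grid
#'
#' The full spatial allocation: each (year, country, sector, length class,
#' gear) segment's national totals are matched to the catch maps through the
#' gear cascade ([match_gear()]), prorated to functional groups and cells by
#' relative catch, constrained (coastal rule for the unpowered sector, trawl
#' bans), and Gaussian-spread. Segments matching no catch anywhere fall back
#' to a uniform spread over the country's cells (or the grid's coastal cells
#' if the country has no catch at all), with functional group `"Unknown"` -
#' dropping effort would break conservation.
#'
#' @param segments Tibble of national segment totals: `saup`, `sector`,
#'   `year`, `length_class`, `gear`, `nv`, `p_total`, `gt_total`,
#'   `nom_active`, `eff_active`.
#' @param catch Catch cell table: `year`, `saup`, `sector`, `gear`,
#'   `fgroup`, `lat`, `lon`, `catch`.
#' @param grid Grid with mask attributes.
#' @param family_table Gear-to-family map covering the effort vocabulary.
#' @param sigma Smoothing kernel width in cells (0 disables smoothing).
#' @param truncate Kernel truncation in sigmas.
#' @param chunk_years Years are mapped independently, so long runs are
#'   processed in blocks of this many years to bound peak memory.
#' @return Effort grid tibble with the 13 schema fields `Year`, `SAUP`,
#'   `NV`, `P`, `GT`, `NomActive`, `EffActive`, `Length_Category`, `Gear`,
#'   `Lat`, `Lon`, `FGroup`, `Sector`.
#' @export
map_effort <- function(segments, catch, grid,
                       family_table = default_gear_families(),
                       sigma = 1, truncate = 3, chunk_years = 8) {
  years <- sort(unique(segments$year))
  if (length(years) > chunk_years) {
    # allocation, constraints and smoothing are all within-segment (hence
    # within-year); the fallback cell sets are precomputed over all years
    country_cells <- dplyr::distinct(catch, .data$saup, .data$lat, .data$lon)
    blocks <- split(years, ceiling(seq_along(years) / chunk_years))
    out <- lapply(blocks, function(ys) {
      map_effort_block(segments[segments$year %in% ys, ],
                       catch[catch$year %in% ys, ], grid, family_table,
                       sigma, truncate, country_cells)
    })
    return(dplyr::bind_rows(out))
  }
  map_effort_block(segments, catch, grid, family_table, sigma, truncate,
                   dplyr::distinct(catch, .data$saup, .data$lat, .data$lon))
}

map_effort_block <- function(segments, catch, grid, family_table,
                             sigma, truncate, country_cells) {
  seg <- dplyr::mutate(segments, seg_id = dplyr::row_number())
  gear_family_of(unique(seg$gear), family_table)  # errors on unmapped gears

  catch_gears <- dplyr::distinct(catch, .data$year, .data$saup, .data$sector,
                                 .data$gear) |>
    dplyr::mutate(cfamily = family_table$family[match(.data$gear,
                                                      family_table$gear)])
  seg_keys <- seg |>
    dplyr::select("seg_id", "year", "saup", "sector", "gear") |>
    dplyr::mutate(efamily = family_table$family[match(.data$gear,
                                                      family_table$gear)])
  # exact level
  exact <- seg_keys |>
    dplyr::inner_join(catch_gears |> dplyr::mutate(exact = TRUE),
                      by = c("year", "saup", "sector", "gear")) |>
    dplyr::transmute(.data$seg_id, cgear = .data$gear, level = "exact")
  # family level
  fam <- seg_keys |>
    dplyr::anti_join(exact, by = "seg_id") |>
    dplyr::inner_join(catch_gears,
                      by = c("year", "saup", "sector", "efamily" = "cfamily"),
                      relationship = "many-to-many") |>
    dplyr::transmute(.data$seg_id, cgear = .data$gear.y, level = "family")
  # country level: all catch gears of the country-year, any sector
  country_gears <- dplyr::distinct(catch, .data$year, .data$saup, .data$gear)
  ctry <- seg_keys |>
    dplyr::anti_join(exact, by = "seg_id") |>
    dplyr::anti_join(fam, by = "seg_id") |>
    dplyr::inner_join(country_gears, by = c("year", "saup"),
                      relationship = "many-to-many") |>
    dplyr::transmute(.data$seg_id, cgear = .data$gear.y, level = "country")
  match_map <- dplyr::bind_rows(exact, fam, ctry)

  # attach catch cells; exact/family matches respect the catch sector,
  # country-level matches pool across sectors
  seg_small <- dplyr::select(seg, "seg_id", "year", "saup", "sector")
  catch_small <- dplyr::select(catch, "year", "saup", "sector", "gear",
                               "fgroup", "lat", "lon", "catch")
  alloc_sec <- match_map |>
    dplyr::filter(.data$level != "country") |>
    dplyr::inner_join(seg_small, by = "seg_id") |>
    dplyr::inner_join(catch_small,
                      by = c("year", "saup", "sector", "cgear" = "gear"),
                      relationship = "many-to-many")
  alloc_ctry <- match_map |>
    dplyr::filter(.data$level == "country") |>
    dplyr::inner_join(seg_small, by = "seg_id") |>
    dplyr::inner_join(dplyr::select(catch_small, -"sector"),
                      by = c("year", "saup", "cgear" = "gear"),
                      relationship = "many-to-many")
  weights <- dplyr::bind_rows(alloc_sec, alloc_ctry) |>
    dplyr::group_by(.data$seg_id, .data$fgroup, .data$lat, .data$lon) |>
    dplyr::summarise(w = sum(.data$catch), .groups = "drop_last") |>
    dplyr::group_by(.data$seg_id) |>
    dplyr::mutate(w = .data$w / sum(.data$w)) |>
    dplyr::ungroup()

  # fallback: uniform over the country's cells (Unknown functional group)
  unmatched <- setdiff(seg$seg_id, unique(weights$seg_id))
  if (length(unmatched) > 0) {
    fb <- seg_small |>
      dplyr::filter(.data$seg_id %in% unmatched) |>
      dplyr::left_join(country_cells, by = "saup",
                       relationship = "many-to-many")
    no_cells <- is.na(fb$lat)
    if (any(no_cells)) {
      coastal <- grid[grid$coastal, c("lat", "lon")]
      fb <- dplyr::bind_rows(
        fb[!no_cells, ],
        fb[no_cells, c("seg_id", "year", "saup", "sector")] |>
          dplyr::distinct() |>
          dplyr::cross_join(coastal)
      )
    }
    fb <- fb |>
      dplyr::group_by(.data$seg_id) |>
      dplyr::mutate(w = 1 / dplyr::n(), fgroup = "Unknown") |>
      dplyr::ungroup() |>
      dplyr::select("seg_id", "fgroup", "lat", "lon", "w")
    weights <- dplyr::bind_rows(weights, fb)
  }

  out <- weights |>
    dplyr::inner_join(seg, by = "seg_id") |>
    dplyr::transmute(
      Year = .data$year, SAUP = .data$saup,
      NV = .data$nv * .data$w, P = .data$p_total * .data$w,
      GT = .data$gt_total * .data$w,
      NomActive = .data$nom_active * .data$w,
      EffActive = .data$eff_active * .data$w,
      Length_Category = .data$length_class, Gear = .data$gear,
      Lat = .data$lat, Lon = .data$lon, FGroup = .data$fgroup,
      Sector = .data$sector
    )
  out <- apply_constraints(out, grid, family_table)
  out <- smooth_spread(out, grid, sigma = sigma, truncate = truncate,
                       family_table = family_table)
  dplyr::arrange(out, .data$Year, .data$SAUP, .data$Sector,
                 .data$Length_Category, .data$Gear, .data$FGroup,
                 .data$Lat, .data$Lon)
}
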