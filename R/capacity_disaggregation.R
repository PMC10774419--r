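#' Smooth a gappy compositional share series over years
#'
#' Length-class and gear compositions are observed in a few years only and
#' must be carried to every year while staying on the simplex. Each
#' composition is transformed to additive log-ratios (ALR) against the class
#' with the largest mean share, the ALR coordinates are interpolated
#' linearly over years (flat beyond the first/last observation), and the
#' inverse transform is renormalized so shares sum to one each year.
#' Structural zeros (a class that is zero in every observed year) are
#' preserved as exact zeros throughout.
#'
#' @param shares Tibble with columns `year`, a grouping column named by
#'   `key`, and `share`; at least two observed years (one is carried flat
#'   with a warning).
#' @param years Full year range to cover.
#' @param key Name of the class column (default `"length_class"`).
#' @return Complete tibble `year`, `key`, `share` with per-year sums of 1.
#' @export
smooth_share_series <- function(shares, years, key = "length_class") {
  stopifnot(all(c("year", key, "share") %in% names(shares)))
  classes <- unique(shares[[key]])
  obs_years <- sort(unique(shares$year))
  if (length(obs_years) < 1) stop("no observed compositions")
  wide <- matrix(0, nrow = length(obs_years), ncol = length(classes),
                 dimnames = list(NULL, classes))
  for (r in seq_len(nrow(shares))) {
    wide[match(shares$year[r], obs_years), shares[[key]][r]] <- shares$share[r]
  }
  wide <- wide / rowSums(wide)
  if (length(obs_years) == 1) {
    warning("single observed composition: carried flat across all years")
    out <- tidyr::crossing(year = years, cls = classes)
    out$share <- wide[1, out$cls]
    names(out)[names(out) == "cls"] <- key
    return(dplyr::arrange(out, .data$year))
  }
  structural_zero <- colSums(wide > 0) == 0
  active <- classes[!structural_zero]
  ref <- active[which.max(colMeans(wide[, active, drop = FALSE]))]
  eps <- 1e-8
  full <- matrix(0, nrow = length(years), ncol = length(classes),
                 dimnames = list(NULL, classes))
  for (cl in setdiff(active, ref)) {
    alr <- log(pmax(wide[, cl], eps) / pmax(wide[, ref], eps))
    full[, cl] <- exp(approx(obs_years, alr, xout = years, rule = 2)$y)
  }
  full[, ref] <- 1
  full <- full / rowSums(full)
  tibble(
    year = rep(years, length(classes)),
    !!key := rep(classes, each = length(years)),
    share = as.vector(full)
  ) |> dplyr::arrange(.data$year)
}

#' Impute an attribute series from similar (donor) countries
#'
#' Data-poor countries borrow the unweighted mean of a configured set of
#' donor countries, per year (and per class for compositional attributes,
#' which are renormalized to the simplex after averaging). The number of
#' donors contributing to each key is recorded.
#'
#' @param donors Tibble with a `donor` column, the key columns, and the
#'   value column; donors missing a year simply have no row there.
#' @param value Name of the value column (default `"share"`).
#' @param keys Key columns to average within (default `year` +
#'   `length_class`).
#' @param compositional If `TRUE`, renormalize per year so shares sum to 1.
#' @return Tibble of keys, the averaged value, and `n_donors`.
#' @export
impute_from_similar <- function(donors, value = "share",
                                keys = c("year", "length_class"),
                                compositional = TRUE) {
  if (is.null(donors) || nrow(donors) == 0) {
    stop("no similar countries configured")
  }
  out <- donors |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(
      !!value := mean(.data[[value]]),
      n_donors = dplyr::n(),
      .groups = "drop"
    )
  if (compositional && "year" %in% keys) {
    out <- out |>
      dplyr::group_by(.data$year) |>
      dplyr::mutate(!!value := .data[[value]] / sum(.data[[value]])) |>
      dplyr::ungroup()
  }
  out
}

#' Largest-remainder integer apportionment
#'
#' Splits an integer total across classes in proportion to `shares` so the
#' integer parts sum exactly to the total: floors of the quotas are assigned
#' first, then one unit to each of the largest remainders (ties to the
#' earlier class).
#'
#' @param total Non-negative integer total.
#' @param shares Non-negative weights (normalized internally).
#' @return Integer vector of the same length as `shares`, summing to `total`.
#' @export
apportion_largest_remainder <- function(total, shares) {
  stopifnot(total >= 0, all(shares >= 0))
  if (sum(shares) == 0) shares <- rep(1, length(shares))
  quota <- total * shares / sum(shares)
  base <- floor(quota)
  left <- round(total - sum(base))
  if (left > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Disaggregate reconstructed fleets into length classes and gears
#'
#' Apportions each (country, sector, year) vessel count across the five
#' length classes and then across gear types, using largest-remainder
#' rounding at both levels so the integer segment counts sum exactly to the
#' (rounded) national total.
#'
#' @param fleet Complete reconstructed series: `saup`, `country`, `sector`,
#'   `year`, `n_vessels`.
#' @param length_shares Complete tibble `saup`, `sector`, `year`,
#'   `length_class`, `share`.
#' @param gear_shares Complete tibble `saup`, `sector`, `year`, `gear`,
#'   `share` (applied uniformly across the sector's length classes).
#' @return Segment skeleton: `saup`, `country`, `sector`, `year`,
#'   `length_class`, `gear`, `nv`.
#' @export
disaggregate_fleet <- function(fleet, length_shares, gear_shares) {
  ls_split <- split(length_shares,
                    list(length_shares$saup, length_shares$sector,
                         length_shares$year), drop = TRUE)
  gs_split <- split(gear_shares,
                    list(gear_shares$saup, gear_shares$sector,
                         gear_shares$year), drop = TRUE)
  rows <- vector("list", nrow(fleet))
  for (i in seq_len(nrow(fleet))) {
    f <- fleet[i, ]
    keyname <- paste(f$saup, f$sector, f$year, sep = ".")
    ls <- ls_split[[keyname]]
    gs <- gs_split[[keyname]]
    if (is.null(ls) || is.null(gs)) {
      stop("missing shares for segment ", keyname)
    }
    total <- as.integer(round(f$n_vessels))
    nv_class <- apportion_largest_remainder(total, ls$share)
    seg <- lapply(seq_len(nrow(ls)), function(k) {
      if (nv_class[k] == 0) return(NULL)
      nv_gear <- apportion_largest_remainder(nv_class[k], gs$share)
      tibble(saup = f$saup, country = f$country, sector = f$sector,
             year = f$year, length_class = ls$length_class[k],
             gear = gs$gear, nv = nv_gear)
    })
    rows[[i]] <- dplyr::bind_rows(seg)
  }
  dplyr::bind_rows(rows) |> dplyr::filter(.data$nv > 0)
}

#' Attach engine power and gross tonnage to fleet segments
#'
#' Mean engine power per vessel varies in time: the observed (year, kW)
#' points per (country, sector, length class) are interpolated linearly and
#' held flat outside the observed span. Gross tonnage depends only on hull
#' geometry and is treated as constant within configured periods (mean of
#' the period's observations; a period without observations borrows the
#' nearest observed period). Totals are `mean * NV`. Segments with no
#' observation fall back to the donor countries in `donor_map`, and error
#' out if none is configured.
#'
#' @param skeleton Output of [disaggregate_fleet()].
#' @param power_obs Tibble `saup`, `sector`, `length_class`, `year`,
#'   `mean_kw`.
#' @param tonnage_obs Tibble `saup`, `sector`, `length_class`, `year`,
#'   `mean_gt`.
#' @param years Full year range.
#' @param period_breaks Years starting new tonnage periods (default: one
#'   period spanning all years).
#' @param donor_map Optional named list: `saup` (as character) -> vector of
#'   donor `saup` codes.
#' @return The skeleton with `mean_kw`, `p_total`, `mean_gt`, `gt_total`.
#' @export
attach_power_tonnage <- function(skeleton, power_obs, tonnage_obs, years,
                                 period_breaks = NULL, donor_map = NULL) {
  keys <- dplyr::distinct(skeleton, .data$saup, .data$sector,
                          .data$length_class)
  get_obs <- function(tab, s, sec, lc) {
    tab[tab$saup == s & tab$sector == sec & tab$length_class == lc, ]
  }
  smooth_attr <- function(obs_y, obs_v) {
    obs_v <- unname(obs_v)
    if (length(obs_y) == 1) return(rep(obs_v, length(years)))
    approx(obs_y, obs_v, xout = years, rule = 2)$y
  }
  period_of <- function(y) findInterval(y, c(min(years), period_breaks))

  pw <- vector("list", nrow(keys)); gt <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    k <- keys[i, ]
    po <- get_obs(power_obs, k$saup, k$sector, k$length_class)
    if (nrow(po) == 0 && !is.null(donor_map)) {
      dn <- donor_map[[as.character(k$saup)]]
      po <- power_obs[power_obs$saup %in% dn & power_obs$sector == k$sector &
                        power_obs$length_class == k$length_class, ] |>
        dplyr::group_by(.data$year) |>
        dplyr::summarise(mean_kw = mean(.data$mean_kw), .groups = "drop")
    }
    if (nrow(po) == 0) {
      stop(sprintf("no engine power data or donor for segment (%s, %s, %s)",
                   k$saup, k$sector, k$length_class))
    }
    pw[[i]] <- tibble(saup = k$saup, sector = k$sector,
                      length_class = k$length_class, year = years,
                      mean_kw = smooth_attr(po$year, po$mean_kw))
    to <- get_obs(tonnage_obs, k$saup, k$sector, k$length_class)
    if (nrow(to) == 0 && !is.null(donor_map)) {
      dn <- donor_map[[as.character(k$saup)]]
      to <- tonnage_obs[tonnage_obs$saup %in% dn &
                          tonnage_obs$sector == k$sector &
                          tonnage_obs$length_class == k$length_class, ]
    }
    if (nrow(to) == 0) {
      stop(sprintf("no tonnage data or donor for segment (%s, %s, %s)",
                   k$saup, k$sector, k$length_class))
    }
    per_obs <- tapply(to$mean_gt, period_of(to$year), mean)
    all_periods <- sort(unique(period_of(years)))
    have <- as.integer(names(per_obs))
    val <- vapply(all_periods, function(p) {
      per_obs[[as.character(have[which.min(abs(have - p))])]]
    }, numeric(1))
    gt[[i]] <- tibble(saup = k$saup, sector = k$sector,
                      length_class = k$length_class, year = years,
                      mean_gt = val[match(period_of(years), all_periods)])
  }
  skeleton |>
    dplyr::left_join(dplyr::bind_rows(pw),
                     by = c("saup", "sector", "length_class", "year")) |>
    dplyr::left_join(dplyr::bind_rows(gt),
                     by = c("saup", "sector", "length_class", "year")) |>
    dplyr::mutate(p_total = .data$mean_kw * .data$nv,
                  gt_total = .data$mean_gt * .data$nv)
}
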