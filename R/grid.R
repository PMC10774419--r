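#' Build a half-degree (or finer/coarser) grid of cell centres
#'
#' Cells are identified by their centre coordinates. With the default 0.5
#' degree spacing, centres fall at odd multiples of 0.25 (..., -0.25, 0.25,
#' 0.75, ...), matching the output schema which records the centre of each
#' cell. The bounding box must be an exact multiple of the cell size.
#'
#' @param lat_range Length-2 numeric, inclusive latitude bounds in degrees.
#' @param lon_range Length-2 numeric, inclusive longitude bounds in degrees.
#' @param cell_size Cell spacing in degrees (default 0.5).
#' @return A tibble with one row per cell: `cell_id`, `lon`, `lat`, and the
#'   mask columns `coastal`, `trawl_ban` (both `FALSE` by default) and
#'   `dist_coast` (cells from the coast, `NA` until masks are set).
#' @export
make_grid <- function(lat_range = c(-90, 90), lon_range = c(-180, 180),
                      cell_size = 0.5) {
  stopifnot(length(lat_range) == 2, length(lon_range) == 2, cell_size > 0)
  n_lat <- (lat_range[2] - lat_range[1]) / cell_size
  n_lon <- (lon_range[2] - lon_range[1]) / cell_size
  if (abs(n_lat - round(n_lat)) > 1e-9 || abs(n_lon - round(n_lon)) > 1e-9) {
    stop("cell_size must divide the bounding box evenly")
  }
  n_lat <- round(n_lat); n_lon <- round(n_lon)
  if (n_lat * n_lon < 2) stop("degenerate grid: fewer than 2 cells")
  lat_centres <- lat_range[1] + cell_size * (seq_len(n_lat) - 0.5)
  lon_centres <- lon_range[1] + cell_size * (seq_len(n_lon) - 0.5)
  g <- tidyr::crossing(lat = lat_centres, lon = lon_centres)
  g <- dplyr::mutate(g,
    cell_id = seq_len(nrow(g)),
    coastal = FALSE, trawl_ban = FALSE, dist_coast = NA_real_
  )
  dplyr::select(g, "cell_id", "lon", "lat", "coastal", "trawl_ban", "dist_coast")
}

#' Flag coastal cells by longitude column
#'
#' A stylized coastline: the westernmost `coast_cols` columns of the grid are
#' coastal, and `dist_coast` counts whole cells east of the coastal strip.
#' Real bathymetry is out of scope; this reproduces the assumption that
#' catch (and hence effort) concentrates near the coast.
#'
#' @param grid A grid from [make_grid()].
#' @param coast_cols Number of westernmost longitude columns flagged coastal.
#' @return The grid with `coastal` and `dist_coast` filled in.
#' @export
set_coastal_columns <- function(grid, coast_cols = 2) {
  lon_sorted <- sort(unique(grid$lon))
  stopifnot(coast_cols >= 1, coast_cols <= length(lon_sorted))
  col_idx <- match(grid$lon, lon_sorted)
  grid$coastal <- col_idx <= coast_cols
  grid$dist_coast <- pmax(0, col_idx - coast_cols)
  grid
}

#' Check that coordinates sit on the cell-centre lattice
#'
#' @param x Numeric coordinates.
#' @param cell_size Cell spacing in degrees.
#' @return Logical vector: `TRUE` where `x` is a valid cell centre.
#' @export
on_centre_lattice <- function(x, cell_size = 0.5) {
  abs((x - cell_size / 2) / cell_size -
        round((x - cell_size / 2) / cell_size)) < 1e-9
}
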