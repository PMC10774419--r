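EFFORT_SCHEMA <- c("Year", "SAUP", "NV", "P", "GT", "NomActive", "EffActive",
                   "Length_Category", "Gear", "Lat", "Lon", "FGroup",
                   "Sector")

effort_key_cols <- function() {
  c("Year", "SAUP", "Sector", "Length_Category", "Gear", "FGroup",
    "Lat", "Lon")
}

#' Write the mapped-effort output layout
#'
#' Mirrors the published layout: `effort_mapped/` holds one file per
#' (year, sector) with the `Year` column omitted to reduce size (a full
#' 1950-2017 run over the three sectors gives 204 files), and
#' `effort_mapped_country/` holds one file per registry country with all 13
#' fields. A registry country with no mapped rows still gets its
#' (header-only) file, so the country folder always has one file per
#' registry entry. Files are UTF-8, comma-separated CSV with a header row
#' and no quoting unless needed.
#'
#' @param effort Mapped effort tibble with the 13 schema fields.
#' @param dir Output directory (created if absent).
#' @param registry Tibble with `saup` (and optionally `country`); defaults
#'   to the countries present in `effort`.
#' @return A manifest tibble: `folder`, `file`, `n_rows`, invisibly
#'   attributed with per-folder counts.
#' @export
write_effort_outputs <- function(effort, dir, registry = NULL) {
  stopifnot(all(EFFORT_SCHEMA %in% names(effort)))
  effort <- effort[, EFFORT_SCHEMA]
  if (anyDuplicated(effort[, effort_key_cols()])) {
    stop("duplicate (year, country, sector, class, gear, fgroup, cell) keys")
  }
  if (is.null(registry)) {
    registry <- tibble(saup = sort(unique(effort$SAUP)))
  }
  dir_y <- file.path(dir, "effort_mapped")
  dir_c <- file.path(dir, "effort_mapped_country")
  dir.create(dir_y, recursive = TRUE, showWarnings = FALSE)
  dir.create(dir_c, recursive = TRUE, showWarnings = FALSE)

  manifest <- list()
  for (y in sort(unique(effort$Year))) {
    for (s in sort(unique(effort$Sector[effort$Year == y]))) {
      d <- effort[effort$Year == y & effort$Sector == s, ]
      d <- d[, setdiff(EFFORT_SCHEMA, "Year")]
      f <- file.path(dir_y, sprintf("mapped_effort_%d_%s.csv", y, s))
      write.csv(d, f, row.names = FALSE)
      manifest[[length(manifest) + 1]] <-
        tibble(folder = "effort_mapped", file = basename(f), n_rows = nrow(d))
    }
  }
  for (i in seq_len(nrow(registry))) {
    code <- registry$saup[i]
    d <- effort[effort$SAUP == code, ]
    f <- file.path(dir_c, sprintf("mapped_effort_%s.csv", code))
    write.csv(d, f, row.names = FALSE)
    manifest[[length(manifest) + 1]] <-
      tibble(folder = "effort_mapped_country", file = basename(f),
             n_rows = nrow(d))
  }
  dplyr::bind_rows(manifest)
}

#' Read a mapped-effort CSV
#'
#' @param path File path; a per-year file (no `Year` column) needs `year`
#'   supplied to restore the column.
#' @param year Optional year for per-year files.
#' @return Tibble in schema order.
#' @export
read_effort_csv <- function(path, year = NULL) {
  d <- as_tibble(read.csv(path, check.names = FALSE))
  if (!"Year" %in% names(d)) {
    if (is.null(year)) stop("file has no Year column; supply `year`")
    d$Year <- as.integer(year)
  }
  d[, EFFORT_SCHEMA[EFFORT_SCHEMA %in% names(d)]]
}

#' Validate a mapped-effort file or table against the output schema
#'
#' Checks the 13 fields by name and order, numeric types, sector codes in
#' {APW, UP, I}, length categories among the five class labels, and that
#' latitude/longitude sit on the half-degree cell-centre lattice.
#'
#' @param x A file path or a data frame.
#' @param expect_year `FALSE` for per-year files, which omit `Year`.
#' @param cell_size Grid spacing the coordinates must respect.
#' @return List `valid` (logical) and `issues` (character vector, itemized).
#' @export
validate_schema <- function(x, expect_year = TRUE, cell_size = 0.5) {
  d <- if (is.character(x)) read.csv(x, check.names = FALSE) else x
  want <- if (expect_year) EFFORT_SCHEMA else setdiff(EFFORT_SCHEMA, "Year")
  issues <- character()
  if (!identical(names(d), want)) {
    issues <- c(issues, paste0(
      "field names/order mismatch: got [", paste(names(d), collapse = ", "),
      "], want [", paste(want, collapse = ", "), "]"))
  }
  if (nrow(d) > 0 && length(issues) == 0) {
    num_cols <- intersect(c("Year", "NV", "P", "GT", "NomActive",
                            "EffActive", "Lat", "Lon"), names(d))
    for (cl in num_cols) {
      if (!is.numeric(d[[cl]])) {
        issues <- c(issues, paste0("field ", cl, " is not numeric"))
      }
    }
    bad_sec <- setdiff(unique(d$Sector), sector_codes())
    if (length(bad_sec) > 0) {
      issues <- c(issues, paste0("Sector: invalid code(s) ",
                                 paste(bad_sec, collapse = ", ")))
    }
    bad_len <- setdiff(unique(d$Length_Category), length_classes())
    if (length(bad_len) > 0) {
      issues <- c(issues, paste0("Length_Category: invalid label(s) ",
                                 paste(bad_len, collapse = ", ")))
    }
    if (is.numeric(d$Lat) && !all(on_centre_lattice(d$Lat, cell_size))) {
      issues <- c(issues, "Lat: values off the cell-centre lattice")
    }
    if (is.numeric(d$Lon) && !all(on_centre_lattice(d$Lon, cell_size))) {
      issues <- c(issues, "Lon: values off the cell-centre lattice")
    }
  }
  list(valid = length(issues) == 0, issues = issues)
}

#' Construct a days-at-sea to fishing-hours conversion table
#'
#' @param df Tibble `gear`, `length_class`, `hours_per_das` with factors in
#'   (0, 24].
#' @return The validated table, classed `conversion_table`.
#' @export
conversion_table <- function(df) {
  stopifnot(all(c("gear", "length_class", "hours_per_das") %in% names(df)))
  if (any(df$hours_per_das <= 0 | df$hours_per_das > 24)) {
    stop("hours_per_das must be in (0, 24]")
  }
  structure(as_tibble(df), class = c("conversion_table", class(tibble())))
}

#' Convert effort from kW x days at sea to kW x fishing hours
#'
#' Applies externally derived (gear, length class) conversion factors to the
#' `NomActive` and `EffActive` columns; the factor source is recorded per
#' row. Rows with no factor use `default_factor`, or raise an error listing
#' the gaps if none is configured.
#'
#' @param records Mapped effort tibble.
#' @param conversion A [conversion_table()].
#' @param default_factor Optional fallback hours-per-day factor.
#' @return The records with effort in kW x hours and a `factor_source`
#'   column (`"table"` or `"default"`).
#' @export
convert_das_to_hours <- function(records, conversion, default_factor = NULL) {
  f <- conversion$hours_per_das[match(
    paste(records$Gear, records$Length_Category),
    paste(conversion$gear, conversion$length_class)
  )]
  src <- ifelse(is.na(f), "default", "table")
  if (anyNA(f)) {
    if (is.null(default_factor)) {
      gaps <- unique(paste(records$Gear, records$Length_Category,
                           sep = " / ")[is.na(f)])
      stop("no conversion factor for: ", paste(gaps, collapse = "; "))
    }
    f[is.na(f)] <- default_factor
  }
  records$NomActive <- records$NomActive * f
  if ("EffActive" %in% names(records)) {
    records$EffActive <- records$EffActive * f
  }
  records$factor_source <- src
  records
}

#' Country code map between SAUP numeric codes and country names
#'
#' @param registry Tibble `saup`, `country`; must be one-to-one.
#' @return The validated map.
#' @export
country_code_map <- function(registry) {
  stopifnot(all(c("saup", "country") %in% names(registry)))
  if (anyDuplicated(registry$saup) || anyDuplicated(registry$country)) {
    stop("SAUP-to-country map must be bijective")
  }
  as_tibble(registry[, c("saup", "country")])
}

#' Write the synthetic world bundle as CSV tables
#'
#' Writes every table of a [generate_world()] bundle plus a JSON metadata
#' file recording the configuration (including the seed).
#'
#' @param world A `synthetic_world` bundle.
#' @param dir Output directory.
#' @return Invisibly, the vector of files written.
#' @export
write_world_tables <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tabs <- c("registry", "fleet_obs", "covariates", "catch",
            "length_share_obs", "gear_share_obs", "power_obs", "tonnage_obs",
            "das_table", "artisanal_catch", "grid")
  files <- character()
  for (tb in tabs) {
    f <- file.path(dir, paste0(tb, ".csv"))
    write.csv(world[[tb]], f, row.names = FALSE)
    files <- c(files, f)
  }
  meta <- world$config
  class(meta) <- NULL
  jsonlite::write_json(meta, file.path(dir, "world_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, file.path(dir, "world_config.json")))
}

#' Build a world configuration from a JSON (or YAML) config file
#'
#' @param path Path to a config file whose top-level keys are
#'   [world_config()] arguments.
#' @return A validated `world_config`.
#' @export
world_config_from_file <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML configs need the yaml package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(cfg$creep_rates)) cfg$creep_rates <- unlist(cfg$creep_rates)
  do.call(world_config, cfg)
}
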