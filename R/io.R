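HEADER_PREFIX <- "# thermofill-grid "

write_gridded_csv <- function(df, spec, path, extra = NULL) {
  meta <- unclass(spec)
  if (!is.null(extra)) meta <- c(meta, extra)
  writeLines(paste0(HEADER_PREFIX,
                    jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
             path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(path)
}

read_gridded_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, HEADER_PREFIX)) {
    stop("not a thermofill gridded CSV (missing grid header): ", path,
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sub(HEADER_PREFIX, "", first, fixed = TRUE))
  spec <- grid_spec(meta$n_lat, meta$n_lon, meta$cell_size_deg,
                    meta$lat_origin, meta$lon_origin, meta$periodic_lon)
  df <- readr::read_csv(path, skip = 1, show_col_types = FALSE,
                        progress = FALSE)
  df <- tibble::as_tibble(as.data.frame(df))
  list(spec = spec, meta = meta, df = df)
}

check_columns <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    rlang::abort(
      message = sprintf("%s is missing required column(s): %s", what,
                        paste(missing_cols, collapse = ", ")),
      class = "thermofill_schema_error")
  }
  invisible(df)
}

#' Read and write world grids
#'
#' Worlds, ranges and climatologies are stored as plain CSV tables with a
#' one-line JSON grid-spec header, one row per cell. Round-tripping
#' reproduces integer and logical rasters bit-exactly and floats to well
#' within 1e-6.
#'
#' @param world A `thermofill_world`.
#' @param path File path.
#' @return `read_world()` returns a `thermofill_world`.
#' @export
write_world <- function(world, path) {
  write_gridded_csv(tibble::as_tibble(world), spec_of(world), path)
}

#' @rdname write_world
#' @export
read_world <- function(path) {
  g <- read_gridded_csv(path)
  check_columns(g$df, c("cell_id", "row", "col", "lat", "lon", "is_land",
                        "is_ocean", "is_coastal_land", "is_coastal_ocean",
                        "realm_id", "elevation_m", "depth_m"), "world file")
  out <- g$df
  out$realm_id <- as.integer(out$realm_id)
  for (cl in c("cell_id", "row", "col")) out[[cl]] <- as.integer(out[[cl]])
  attr(out, "spec") <- g$spec
  class(out) <- c("thermofill_world", class(tibble::tibble()))
  out
}

#' Read and write presence/absence range grids
#'
#' @param range A `thermofill_range`.
#' @param path File path.
#' @return `read_range()` returns a `thermofill_range`.
#' @export
write_range <- function(range, path) {
  write_gridded_csv(tibble::as_tibble(range), spec_of(range), path,
                    extra = list(species_id = attr(range, "species_id")))
}

#' @rdname write_range
#' @export
read_range <- function(path) {
  g <- read_gridded_csv(path)
  df <- g$df
  if (nrow(df) == 0) {
    df <- grid_cells(g$spec)[0, ]
  }
  check_columns(df, c("cell_id", "row", "col", "lat", "lon"), "range file")
  for (cl in c("cell_id", "row", "col")) df[[cl]] <- as.integer(df[[cl]])
  new_range(df, g$spec, g$meta$species_id %||% NA_character_)
}

#' Read and write body-temperature fields
#'
#' @param fields A `thermofill_bodytemp`.
#' @param path File path.
#' @return `read_bodytemp()` returns a `thermofill_bodytemp`.
#' @export
write_bodytemp <- function(fields, path) {
  write_gridded_csv(tibble::as_tibble(fields), spec_of(fields), path,
                    extra = list(species_id = attr(fields, "species_id")))
}

#' @rdname write_bodytemp
#' @export
read_bodytemp <- function(path) {
  g <- read_gridded_csv(path)
  check_columns(g$df, c("cell_id", "tbody_warm", "tbody_cool"),
                "body-temperature file")
  df <- g$df
  for (cl in c("cell_id", "row", "col")) df[[cl]] <- as.integer(df[[cl]])
  new_bodytemp(df, g$spec, g$meta$species_id %||% NA_character_)
}

#' Read and write climatologies
#'
#' A climatology is stored as a directory holding `cells.csv` and
#' `monthly.csv` (both with the grid header) plus the generator
#' configuration as JSON.
#'
#' @param climate A `thermofill_climate`.
#' @param dir Directory path (created if needed).
#' @return `read_climate()` returns a `thermofill_climate`.
#' @export
write_climate <- function(climate, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gridded_csv(climate$cells, climate$spec, file.path(dir, "cells.csv"))
  write_gridded_csv(climate$monthly, climate$spec,
                    file.path(dir, "monthly.csv"))
  jsonlite::write_json(unclass(climate$config),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_climate
#' @export
read_climate <- function(dir) {
  cells <- read_gridded_csv(file.path(dir, "cells.csv"))
  monthly <- read_gridded_csv(file.path(dir, "monthly.csv"))
  check_columns(cells$df, c("cell_id", "air_warm", "air_cool", "sst_warm",
                            "sst_cool", "acclim_warm", "acclim_cool",
                            "diurnal_amp_c", "warm_month", "cold_month"),
                "climate cells file")
  check_columns(monthly$df, c("cell_id", "month", "t_air_c", "t_sst_c"),
                "climate monthly file")
  cfg_path <- file.path(dir, "config.json")
  config <- if (file.exists(cfg_path)) {
    structure(jsonlite::fromJSON(cfg_path),
              class = "thermofill_climate_config")
  } else NULL
  df <- cells$df
  for (cl in c("cell_id", "row", "col")) df[[cl]] <- as.integer(df[[cl]])
  structure(list(spec = cells$spec, cells = df,
                 monthly = monthly$df, config = config),
            class = "thermofill_climate")
}

SPECIES_REQUIRED <- c("species_id", "realm", "upper_limit_c",
                      "lower_limit_c", "metric_type")
SPECIES_REALMS <- c("terrestrial", "intertidal", "subtidal")

#' Read a species table
#'
#' Reads the species CSV (one row per species) and validates its schema:
#' required columns must be present, the realm must be one of
#' `terrestrial`/`intertidal`/`subtidal`, every species needs at least one
#' tolerance limit with `upper > lower` when both are present, and ARR
#' values must lie in `[0, 1]`. Missing optional columns (dormancy, traits,
#' plasticity, behaviour, elevation/depth bounds) are filled with defaults.
#'
#' @param path CSV path.
#' @return A `thermofill_species` tibble.
#' @export
read_species_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  df <- tibble::as_tibble(as.data.frame(df))
  check_columns(df, SPECIES_REQUIRED, "species table")
  bad_realm <- setdiff(unique(df$realm), SPECIES_REALMS)
  if (length(bad_realm)) {
    rlang::abort(message = paste0("unknown realm label(s): ",
                                  paste(bad_realm, collapse = ", ")),
                 class = "thermofill_validation_error")
  }
  if (any(is.na(df$upper_limit_c) & is.na(df$lower_limit_c))) {
    rlang::abort("every species needs at least one thermal limit",
                 class = "thermofill_validation_error")
  }
  both <- !is.na(df$upper_limit_c) & !is.na(df$lower_limit_c)
  if (any(both & df$upper_limit_c <= df$lower_limit_c)) {
    rlang::abort("upper_limit_c must exceed lower_limit_c (breadth > 0)",
                 class = "thermofill_validation_error")
  }
  for (cl in c("arr_upper", "arr_lower")) {
    if (cl %in% names(df)) {
      v <- df[[cl]]
      if (any(!is.na(v) & (v < 0 | v > 1))) {
        rlang::abort(paste0(cl, " must lie in [0, 1]"),
                     class = "thermofill_validation_error")
      }
    }
  }
  defaults <- list(
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, species = NA_character_,
    body_mass_g = NA_real_, dispersal_km = NA_real_, dormancy = "none",
    arr_upper = NA_real_, arr_lower = NA_real_,
    assay_acclimation_c = NA_real_, t_pref_c = NA_real_,
    elevation_min_m = NA_real_, elevation_max_m = NA_real_,
    depth_min_m = NA_real_, depth_max_m = NA_real_)
  for (nm in names(defaults)) {
    if (!nm %in% names(df)) df[[nm]] <- defaults[[nm]]
  }
  df$dormancy[is.na(df$dormancy)] <- "none"
  class(df) <- c("thermofill_species", class(tibble::tibble()))
  df
}

#' @rdname read_species_table
#' @param species A `thermofill_species` tibble.
#' @export
write_species_table <- function(species, path) {
  readr::write_csv(tibble::as_tibble(species), path, progress = FALSE)
  invisible(path)
}
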