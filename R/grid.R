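#' Define a regular latitude-longitude grid
#'
#' All rasters in an analysis share a single grid specification. Cells are
#' centre-registered: the centre of cell `(row, col)` lies at
#' `origin + (index - 1 + 0.5) * cell_size_deg`, with `row` increasing
#' south to north and `col` increasing with longitude.
#'
#' @param n_lat Number of latitude rows.
#' @param n_lon Number of longitude columns.
#' @param cell_size_deg Degrees per cell (same in both directions).
#' @param lat_origin,lon_origin Degrees of the south-west corner of cell
#'   `(1, 1)`.
#' @param periodic_lon Whether longitude wraps modulo 360.
#' @return A `thermofill_gridspec` object.
#' @export
grid_spec <- function(n_lat, n_lon, cell_size_deg = 1,
                      lat_origin = -n_lat * cell_size_deg / 2,
                      lon_origin = 0, periodic_lon = FALSE) {
  stopifnot(n_lat >= 1, n_lon >= 1, cell_size_deg > 0)
  cell_size_deg <- as.numeric(cell_size_deg)
  lat_origin <- as.numeric(lat_origin)
  lon_origin <- as.numeric(lon_origin)
  lats <- lat_origin + (seq_len(n_lat) - 0.5) * cell_size_deg
  if (any(lats <= -90) || any(lats >= 90)) {
    stop("latitude cell centres must lie strictly within (-90, 90)",
         call. = FALSE)
  }
  structure(
    list(n_lat = as.integer(n_lat), n_lon = as.integer(n_lon),
         cell_size_deg = cell_size_deg, lat_origin = lat_origin,
         lon_origin = lon_origin, periodic_lon = isTRUE(periodic_lon)),
    class = "thermofill_gridspec"
  )
}

#' @export
print.thermofill_gridspec <- function(x, ...) {
  cat(sprintf(
    "<grid %d x %d at %g deg, SW corner (%g, %g)%s>\n",
    x$n_lat, x$n_lon, x$cell_size_deg, x$lat_origin, x$lon_origin,
    if (x$periodic_lon) ", periodic lon" else ""))
  invisible(x)
}

#' Cell-centre latitudes and longitudes of a grid
#' @param spec A [grid_spec()].
#' @return Numeric vector of cell-centre coordinates.
#' @export
grid_lats <- function(spec) {
  spec$lat_origin + (seq_len(spec$n_lat) - 0.5) * spec$cell_size_deg
}

#' @rdname grid_lats
#' @export
grid_lons <- function(spec) {
  spec$lon_origin + (seq_len(spec$n_lon) - 0.5) * spec$cell_size_deg
}

#' All cells of a grid as a tibble
#'
#' @param spec A [grid_spec()].
#' @return A tibble with one row per cell: `cell_id` (row-major), `row`,
#'   `col`, `lat`, `lon` (cell centres).
#' @export
grid_cells <- function(spec) {
  rows <- rep(seq_len(spec$n_lat), times = spec$n_lon)
  cols <- rep(seq_len(spec$n_lon), each = spec$n_lat)
  tibble::tibble(
    cell_id = (cols - 1L) * spec$n_lat + rows,
    row = rows, col = cols,
    lat = grid_lats(spec)[rows],
    lon = grid_lons(spec)[cols]
  )
}

spec_of <- function(x) {
  s <- attr(x, "spec", exact = TRUE)
  if (is.null(s) && is.list(x) && !is.null(x$spec)) s <- x$spec
  if (is.null(s)) stop("object carries no grid spec", call. = FALSE)
  s
}

same_spec <- function(a, b) identical(unclass(a), unclass(b))

check_same_spec <- function(...) {
  specs <- lapply(list(...), spec_of)
  for (i in seq_along(specs)[-1]) {
    if (!same_spec(specs[[1]], specs[[i]])) {
      stop("grid specs differ between inputs; all rasters of one analysis ",
           "must share a single grid spec", call. = FALSE)
    }
  }
  invisible(specs[[1]])
}

#' Coarsen a raster by block-wise extremes
#'
#' Aggregates a fine-resolution raster of temperatures to a coarser grid by
#' taking the maximum (or minimum) over each `factor` x `factor` block, the
#' operation used to bring high-resolution extreme climatologies onto the
#' analysis grid. Missing values are ignored unless a whole block is missing.
#'
#' @param fine Numeric matrix (rows = latitude, columns = longitude).
#' @param factor Integer aggregation factor; both dimensions of `fine` must
#'   be divisible by it.
#' @param mode `"max"` or `"min"`.
#' @return A matrix of dimension `dim(fine) / factor`.
#' @export
aggregate_extremes <- function(fine, factor, mode = c("max", "min")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(fine), length(factor) == 1, factor >= 1)
  factor <- as.integer(factor)
  if (nrow(fine) %% factor != 0 || ncol(fine) %% factor != 0) {
    stop(sprintf("dimensions %d x %d not divisible by factor %d",
                 nrow(fine), ncol(fine), factor), call. = FALSE)
  }
  if (factor == 1L) return(fine)
  nr <- nrow(fine) %/% factor
  nc <- ncol(fine) %/% factor
  f <- if (mode == "max") max else min
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      block <- fine[(i - 1L) * factor + seq_len(factor),
                    (j - 1L) * factor + seq_len(factor)]
      if (all(is.na(block))) next
      out[i, j] <- f(block, na.rm = TRUE)
    }
  }
  out
}

#' Construct a presence range from a set of cells
#'
#' @param cells A data frame with at least `row` and `col` (or `cell_id`)
#'   identifying occupied cells.
#' @param spec The shared [grid_spec()].
#' @param species_id Identifier attached to the range.
#' @return A `thermofill_range` tibble with columns `cell_id`, `row`, `col`,
#'   `lat`, `lon`. May be empty (legal for potential ranges).
#' @export
range_from_cells <- function(cells, spec, species_id = NA_character_) {
  all_cells <- grid_cells(spec)
  if (!is.data.frame(cells)) stop("`cells` must be a data frame", call. = FALSE)
  if ("cell_id" %in% names(cells)) {
    out <- dplyr::semi_join(all_cells, cells["cell_id"], by = "cell_id")
  } else if (all(c("row", "col") %in% names(cells))) {
    out <- dplyr::semi_join(all_cells, cells[c("row", "col")],
                            by = c("row", "col"))
  } else {
    stop("`cells` needs either a `cell_id` or `row`+`col` columns",
         call. = FALSE)
  }
  new_range(out, spec, species_id)
}

new_range <- function(cells, spec, species_id = NA_character_) {
  out <- dplyr::arrange(
    tibble::as_tibble(cells[c("cell_id", "row", "col", "lat", "lon")]),
    .data$cell_id)
  attr(out, "spec") <- spec
  attr(out, "species_id") <- species_id
  class(out) <- c("thermofill_range", class(tibble::tibble()))
  out
}

#' Latitudinal midpoint of a range
#'
#' The midpoint of the latitudinal extent of occupied cell centres,
#' `(max(lat) + min(lat)) / 2`. Signed; take `abs()` for absolute-latitude
#' covariates.
#'
#' @param range A `thermofill_range` (or any data frame with a `lat` column
#'   of occupied cell-centre latitudes).
#' @return Midpoint latitude in degrees.
#' @export
latitudinal_midpoint <- function(range) {
  if (nrow(range) == 0) {
    stop("latitudinal midpoint is undefined for an empty range",
         call. = FALSE)
  }
  (max(range$lat) + min(range$lat)) / 2
}

# value of a possibly absent column of a one-row species tibble
trait <- function(species, nm, default = NA_real_) {
  if (nm %in% names(species)) species[[nm]] else default
}
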