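#' Configuration for a synthetic world
#'
#' Defaults describe the package's standard study conditions: a 1-degree
#' regional sector spanning latitudes -70..70 and 40 degrees of longitude,
#' two continents partitioned into five biogeographic realms, and roughly a
#' third of cells as land. Coastal definitions follow the grid-native rules
#' used throughout: coastal land has at least one ocean cell among its eight
#' neighbours; coastal ocean lies within `coastal_ocean_km` great-circle
#' distance of a coastal-land cell centre.
#'
#' @param n_lat,n_lon,cell_size_deg,lat_origin,lon_origin Grid geometry, see
#'   [grid_spec()].
#' @param n_continents Number of land blobs (0 gives an all-ocean world).
#' @param n_realms Total number of terrestrial biogeographic realms,
#'   partitioned latitudinally within continents.
#' @param land_fraction Target fraction of cells that are land.
#' @param continent_lat_range Latitude band containing continent centres.
#' @param coastal_ocean_km Distance threshold for the coastal-ocean mask (km).
#' @param elevation_relief_m Scale of terrestrial elevation (m).
#' @param mean_depth_m Scale of ocean depth (m, positive down).
#' @return A list of class `thermofill_world_config`.
#' @export
world_config <- function(n_lat = 140, n_lon = 40, cell_size_deg = 1,
                         lat_origin = -70, lon_origin = 0,
                         n_continents = 2, n_realms = 5,
                         land_fraction = 0.35,
                         continent_lat_range = c(-65, 65),
                         coastal_ocean_km = 200,
                         elevation_relief_m = 1500,
                         mean_depth_m = 3000) {
  stopifnot(n_continents >= 0, n_realms >= 0,
            land_fraction >= 0, land_fraction < 1)
  structure(as.list(environment()), class = "thermofill_world_config")
}

# Smoothed gaussian random field on an n_lat x n_lon matrix, sd ~ 1.
smooth_noise <- function(n_lat, n_lon, k = 7) {
  z <- matrix(stats::rnorm(n_lat * n_lon), n_lat, n_lon)
  w <- rep(1 / k, k)
  pad_filter <- function(m) {
    # moving average along rows with edge padding
    p <- (k - 1) %/% 2
    mm <- rbind(m[rep(1, p), , drop = FALSE], m, m[rep(nrow(m), p), , drop = FALSE])
    out <- apply(mm, 2, function(v) stats::filter(v, w, sides = 2))
    out[(p + 1):(p + nrow(m)), , drop = FALSE]
  }
  z <- pad_filter(z)
  z <- t(pad_filter(t(z)))
  s <- stats::sd(z)
  if (is.na(s) || s == 0) s <- 1
  z / s
}

#' Simulate a world grid
#'
#' Generates land/ocean masks, coastal masks, terrestrial biogeographic
#' realms, elevation and depth. Continents are smooth elliptical blobs with
#' noisy boundaries; the land mask is thresholded so the realised land
#' fraction matches `config$land_fraction`. Each connected land component is
#' partitioned into latitudinally stacked realms (the contiguity units used
#' when constructing encounterable habitat). Deterministic under `seed`.
#'
#' @param config A [world_config()].
#' @param seed Integer seed.
#' @return A `thermofill_world` tibble, one row per cell, with columns
#'   `is_land`, `is_ocean`, `is_coastal_land`, `is_coastal_ocean`,
#'   `realm_id` (0 on ocean), `elevation_m` (NA on ocean) and `depth_m`
#'   (NA on land); the [grid_spec()] is carried as an attribute.
#' @export
simulate_world <- function(config = world_config(), seed = 1) {
  stopifnot(inherits(config, "thermofill_world_config"))
  spec <- grid_spec(config$n_lat, config$n_lon, config$cell_size_deg,
                    config$lat_origin, config$lon_origin)
  cells <- grid_cells(spec)
  withr::with_seed(seed, {
    nlat <- spec$n_lat; nlon <- spec$n_lon
    lat_m <- matrix(cells$lat[order(cells$cell_id)], nlat, nlon)
    lon_m <- matrix(cells$lon[order(cells$cell_id)], nlat, nlon)
    if (config$n_continents == 0 || config$land_fraction == 0) {
      land <- matrix(FALSE, nlat, nlon)
    } else {
      score <- matrix(-Inf, nlat, nlon)
      lat_span <- diff(range(config$continent_lat_range))
      for (i in seq_len(config$n_continents)) {
        c_lat <- stats::runif(1, config$continent_lat_range[1] * 0.4,
                              config$continent_lat_range[2] * 0.4)
        c_lon <- stats::runif(1, min(lon_m), max(lon_m))
        a <- max(lat_span / 2 * stats::runif(1, 0.8, 1.1), 10)
        b <- max(diff(range(lon_m)) / config$n_continents *
                   stats::runif(1, 0.5, 0.9), 5)
        # superellipse: near-uniform continent width across its latitude
        # span, tapering only near the ends
        sc <- 1 - ((lat_m - c_lat) / a)^4 - ((lon_m - c_lon) / b)^2
        score <- pmax(score, sc)
      }
      score <- score + 0.25 * smooth_noise(nlat, nlon)
      thr <- stats::quantile(score, 1 - config$land_fraction, names = FALSE)
      land <- score > thr
    }
    realm <- assign_realms(land, config$n_realms, grid_lats(spec))
    elev <- pmax(0, config$elevation_relief_m *
                   (0.4 + 0.6 * smooth_noise(nlat, nlon)))
    depth <- config$mean_depth_m * (0.6 + 0.5 * abs(smooth_noise(nlat, nlon)))
    coastal_land <- land & neighbour_any(!land)
    coastal_ocean <- coastal_ocean_mask(land, coastal_land, lat_m, lon_m,
                                        config$coastal_ocean_km)
    out <- cells
    idx <- cbind(out$row, out$col)
    out$is_land <- land[idx]
    out$is_ocean <- !out$is_land
    out$is_coastal_land <- coastal_land[idx]
    out$is_coastal_ocean <- coastal_ocean[idx]
    out$realm_id <- realm[idx]
    out$elevation_m <- ifelse(out$is_land, elev[idx], NA_real_)
    out$depth_m <- ifelse(out$is_ocean, depth[idx], NA_real_)
    attr(out, "spec") <- spec
    class(out) <- c("thermofill_world", class(tibble::tibble()))
    out
  })
}

# TRUE where any 8-neighbour of the mask is TRUE
neighbour_any <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  shifts <- expand.grid(dr = -1:1, dc = -1:1)
  shifts <- shifts[!(shifts$dr == 0 & shifts$dc == 0), ]
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts$dr[s]; dc <- shifts$dc[s]
    rs <- seq_len(nr) + dr; cs <- seq_len(nc) + dc
    ok_r <- rs >= 1 & rs <= nr; ok_c <- cs >= 1 & cs <= nc
    out[ok_r, ok_c] <- out[ok_r, ok_c] | mask[rs[ok_r], cs[ok_c]]
  }
  out
}

coastal_ocean_mask <- function(land, coastal_land, lat_m, lon_m, max_km) {
  out <- matrix(FALSE, nrow(land), ncol(land))
  if (!any(coastal_land) || !any(!land)) return(out)
  ocean_idx <- which(!land)
  cl_idx <- which(coastal_land)
  d <- geosphere::distm(
    cbind(lon_m[ocean_idx], lat_m[ocean_idx]),
    cbind(lon_m[cl_idx], lat_m[cl_idx]),
    fun = geosphere::distHaversine)
  out[ocean_idx] <- apply(d, 1, min) <= max_km * 1000
  out
}

# Flood-fill connected components (4-connectivity), then split each
# component into latitudinal realm bands. Realms never span the equator
# (as with real biogeographic realms), so a trans-equatorial continent is
# split into northern and southern realm stacks. Returns an integer
# matrix, 0 on ocean.
flood_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  comp <- matrix(0L, nr, nc)
  next_comp <- 0L
  for (start in which(mask & comp == 0L)) {
    if (comp[start] != 0L) next
    next_comp <- next_comp + 1L
    queue <- start
    comp[start] <- next_comp
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (cur - 1L) %% nr + 1L
      c <- (cur - 1L) %/% nr + 1L
      for (d in list(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))) {
        if (d[1] >= 1 && d[1] <= nr && d[2] >= 1 && d[2] <= nc) {
          j <- (d[2] - 1L) * nr + d[1]
          if (mask[j] && comp[j] == 0L) {
            comp[j] <- next_comp
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  comp
}

assign_realms <- function(land, n_realms, row_lats) {
  nr <- nrow(land); nc <- ncol(land)
  comp <- flood_components(land)
  next_comp <- max(comp)
  realm <- matrix(0L, nr, nc)
  if (next_comp == 0L || n_realms == 0L) return(realm)
  # split components at the equator: realm stacks are hemisphere-confined
  hemi <- matrix(rep(ifelse(row_lats >= 0, 1L, 2L), nc), nr, nc)
  grp <- ifelse(comp > 0L, (comp - 1L) * 2L + hemi, 0L)
  grp_ids <- sort(unique(grp[grp > 0L]))
  grp <- matrix(match(grp, grp_ids), nr, nc)
  grp[is.na(grp)] <- 0L
  n_grp <- length(grp_ids)
  sizes <- tabulate(grp[grp > 0L], nbins = n_grp)
  # distribute realms across groups proportionally to size, each >= 1
  n_each <- pmax(1L, round(n_realms * sizes / sum(sizes)))
  while (sum(n_each) > max(n_realms, n_grp)) {
    i <- which.max(n_each)
    n_each[i] <- n_each[i] - 1L
  }
  next_id <- 0L
  for (k in seq_len(n_grp)) {
    idx <- which(grp == k)
    rows <- (idx - 1L) %% nr + 1L
    nb <- min(n_each[k], length(unique(rows)))
    # latitudinal bands of roughly equal cell count; a whole grid row of the
    # component always belongs to a single realm
    tab <- table(rows)
    cum_mid <- (cumsum(as.numeric(tab)) - as.numeric(tab) / 2) / length(rows)
    band_of_row <- pmin(nb, pmax(1L, ceiling(nb * cum_mid)))
    band <- band_of_row[match(as.character(rows), names(tab))]
    realm[idx] <- next_id + band
    next_id <- next_id + nb
  }
  realm
}
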