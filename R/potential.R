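new_potential <- function(range, species_id, limits_used, log, flags = character()) {
  structure(
    list(species_id = species_id, range = range, limits_used = limits_used,
         restriction_log = log, flags = flags),
    class = "thermofill_potential")
}

#' @export
print.thermofill_potential <- function(x, ...) {
  cat(sprintf("<potential range of %s: %d cells (limits: %s)%s>\n",
              x$species_id, nrow(x$range), x$limits_used,
              if (length(x$flags)) paste0("; flags: ",
                                          paste(x$flags, collapse = ",")) else ""))
  invisible(x)
}

limits_used_of <- function(species) {
  # +/-Inf are legal sentinels (a present but vacuous limit); only NA means
  # the limit was never assayed
  has_u <- !is.na(trait(species, "upper_limit_c"))
  has_l <- !is.na(trait(species, "lower_limit_c"))
  if (has_u && has_l) "both"
  else if (has_u) "upper_only"
  else if (has_l) "lower_only"
  else stop("species has neither an upper nor a lower thermal limit",
            call. = FALSE)
}

#' Encounterable habitat of a species
#'
#' The habitat a species could reach, before any thermal restriction:
#' subtidal species may reach all ocean cells; intertidal species the
#' coastal band (coastal-ocean plus coastal-land cells); terrestrial species
#' every cell of the biogeographic realm(s) their realized range intersects
#' (realms are the contiguity units, so any intersected realm is available
#' in full).
#'
#' @param species One-row species tibble (needs `realm`).
#' @param world The world grid.
#' @param realized The species' realized range (`thermofill_range`); only
#'   used for terrestrial species, to determine intersected realms.
#' @param contiguity For terrestrial species: `"realm"` (default) takes
#'   every intersected realm in full, treating realms as the contiguity
#'   units; `"flood"` restricts further to the connected components
#'   (4-neighbourhood) of the intersected realms' cells that actually touch
#'   the realized range, for sensitivity analysis.
#' @return A `thermofill_range` of habitat cells.
#' @export
encounterable_habitat <- function(species, world, realized = NULL,
                                  contiguity = c("realm", "flood")) {
  contiguity <- match.arg(contiguity)
  spec <- spec_of(world)
  realm <- species$realm
  if (realm == "subtidal") {
    cells <- world[world$is_ocean, ]
  } else if (realm == "intertidal") {
    cells <- world[world$is_coastal_ocean | world$is_coastal_land, ]
  } else if (realm == "terrestrial") {
    if (is.null(realized) || nrow(realized) == 0) {
      stop("terrestrial habitat requires a non-empty realized range",
           call. = FALSE)
    }
    check_same_spec(world, realized)
    realms <- unique(world$realm_id[match(realized$cell_id, world$cell_id)])
    realms <- realms[!is.na(realms) & realms > 0]
    if (!length(realms)) {
      rlang::abort("realized range intersects no terrestrial realm",
                   class = "thermofill_empty_habitat")
    }
    cells <- world[world$realm_id %in% realms, ]
    if (contiguity == "flood") {
      mask <- matrix(FALSE, spec$n_lat, spec$n_lon)
      mask[cbind(cells$row, cells$col)] <- TRUE
      comp <- flood_components(mask)
      seed_rows <- match(realized$cell_id, world$cell_id)
      keep_comp <- unique(comp[cbind(world$row[seed_rows],
                                     world$col[seed_rows])])
      keep_comp <- keep_comp[!is.na(keep_comp) & keep_comp > 0]
      cells <- cells[comp[cbind(cells$row, cells$col)] %in% keep_comp, ]
    }
  } else {
    stop("unknown realm: ", realm, call. = FALSE)
  }
  new_range(cells, spec, species$species_id)
}

#' Habitat of all cells in given realms (used when synthesising species)
#' @param world The world grid.
#' @param realm_ids Integer realm ids.
#' @return A `thermofill_range`.
#' @export
realm_habitat <- function(world, realm_ids) {
  new_range(world[world$realm_id %in% realm_ids, ], spec_of(world),
            NA_character_)
}

#' Clip habitat by fundamental thermal limits
#'
#' Removes habitat cells where the species' extreme body temperatures are
#' hotter than its upper limit or colder than its lower limit; species with
#' only one limit are clipped on that side only. Habitat cells with no body
#' temperature data are dropped and logged. An empty result is legal and
#' flagged.
#'
#' @param habitat A `thermofill_range` of encounterable habitat.
#' @param fields The species' `thermofill_bodytemp`.
#' @param species One-row species tibble (supplies the limits).
#' @param limits_grid Optional tibble of cell-specific limits (`cell_id`,
#'   `upper_limit_c`, `lower_limit_c`) overriding the static limits, used
#'   for acclimatized niches.
#' @return A `thermofill_potential` with the retained range, the limits
#'   used, and a restriction log recording every removed cell once with its
#'   removal reason (`no_climate`, `too_hot`, `too_cold`, `too_hot_cold`).
#' @export
thermal_clip <- function(habitat, fields, species, limits_grid = NULL) {
  check_same_spec(habitat, fields)
  limits_used <- limits_used_of(species)
  j <- match(habitat$cell_id, fields$cell_id)
  warm <- fields$tbody_warm[j]
  cool <- fields$tbody_cool[j]
  if (is.null(limits_grid)) {
    upper <- rep(trait(species, "upper_limit_c"), nrow(habitat))
    lower <- rep(trait(species, "lower_limit_c"), nrow(habitat))
  } else {
    k <- match(habitat$cell_id, limits_grid$cell_id)
    upper <- limits_grid$upper_limit_c[k]
    lower <- limits_grid$lower_limit_c[k]
  }
  use_u <- limits_used %in% c("both", "upper_only")
  use_l <- limits_used %in% c("both", "lower_only")
  no_data <- is.na(warm) | is.na(cool)
  too_hot <- use_u & !no_data & warm > upper
  too_cold <- use_l & !no_data & cool < lower
  keep <- !no_data & !too_hot & !too_cold
  reason <- dplyr::case_when(
    no_data ~ "no_climate",
    too_hot & too_cold ~ "too_hot_cold",
    too_hot ~ "too_hot",
    too_cold ~ "too_cold",
    .default = NA_character_
  )
  log <- tibble::tibble(cell_id = habitat$cell_id[!keep],
                        row = habitat$row[!keep], col = habitat$col[!keep],
                        lat = habitat$lat[!keep],
                        reason = reason[!keep], step = "thermal_clip")
  flags <- character()
  if (!any(keep)) flags <- "empty_potential"
  new_potential(new_range(habitat[keep, ], spec_of(habitat),
                          species$species_id),
                species$species_id, limits_used, log, flags)
}

#' Remove cells of uninhabitable elevation or depth
#'
#' Drops cells whose terrestrial elevation or ocean depth falls outside the
#' species' habitable bounds (`elevation_min_m`/`elevation_max_m`,
#' `depth_min_m`/`depth_max_m`). When no bounds are recorded the range is
#' returned unchanged. Applied to both potential and realized ranges.
#'
#' @param range A `thermofill_range` or `thermofill_potential`.
#' @param species One-row species tibble.
#' @param world The world grid.
#' @return Object of the same class as `range` with offending cells removed
#'   (and, for potentials, logged with reason `depth_elevation`).
#' @export
depth_elevation_correct <- function(range, species, world) {
  is_pot <- inherits(range, "thermofill_potential")
  rng <- if (is_pot) range$range else range
  check_same_spec(rng, world)
  get_bound <- function(nm) {
    v <- trait(species, nm)
    if (length(v) == 0) NA_real_ else v
  }
  e_min <- get_bound("elevation_min_m"); e_max <- get_bound("elevation_max_m")
  d_min <- get_bound("depth_min_m"); d_max <- get_bound("depth_max_m")
  for (b in list(c(e_min, e_max), c(d_min, d_max))) {
    if (!is.na(b[1]) && !is.na(b[2]) && b[1] > b[2]) {
      stop("inverted elevation/depth bounds (min > max)", call. = FALSE)
    }
  }
  j <- match(rng$cell_id, world$cell_id)
  elev <- world$elevation_m[j]
  depth <- world$depth_m[j]
  bad <- rep(FALSE, nrow(rng))
  if (!is.na(e_min)) bad <- bad | (!is.na(elev) & elev < e_min)
  if (!is.na(e_max)) bad <- bad | (!is.na(elev) & elev > e_max)
  if (!is.na(d_min)) bad <- bad | (!is.na(depth) & depth < d_min)
  if (!is.na(d_max)) bad <- bad | (!is.na(depth) & depth > d_max)
  kept <- new_range(rng[!bad, ], spec_of(rng), attr(rng, "species_id"))
  if (!is_pot) return(kept)
  log <- tibble::tibble(cell_id = rng$cell_id[bad], row = rng$row[bad],
                        col = rng$col[bad], lat = rng$lat[bad],
                        reason = "depth_elevation",
                        step = "depth_elevation_correct")
  new_potential(kept, range$species_id, range$limits_used,
                dplyr::bind_rows(range$restriction_log, log),
                union(range$flags,
                      if (nrow(kept) == 0) "empty_potential" else character()))
}

#' Construct the potential thermal range of a species
#'
#' Successive restriction: encounterable habitat (realm rule), thermal
#' clipping by fundamental limits, then depth/elevation correction. The
#' steps commute in outcome; the order here mirrors the analysis narrative.
#'
#' @param species One-row species tibble.
#' @param fields The species' `thermofill_bodytemp`.
#' @param world The world grid.
#' @param realized Realized range (used for the terrestrial realm rule).
#' @param habitat Optional pre-computed habitat range (overrides the realm
#'   rule; used when synthesising species before a realized range exists).
#' @param limits_grid Optional cell-specific limits (see [thermal_clip()]).
#' @return A `thermofill_potential`.
#' @export
potential_range <- function(species, fields, world, realized = NULL,
                            habitat = NULL, limits_grid = NULL) {
  if (is.null(habitat)) {
    habitat <- encounterable_habitat(species, world, realized)
  }
  pot <- thermal_clip(habitat, fields, species, limits_grid = limits_grid)
  depth_elevation_correct(pot, species, world)
}
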