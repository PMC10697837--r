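#' Class- and realm-averaged ARR fallback tables
#'
#' @param species A `thermofill_species` tibble.
#' @return A list with `class` and `realm` tibbles of mean ARR values,
#'   suitable for [resolve_arr()].
#' @export
arr_fallback_tables <- function(species) {
  list(
    class = species |>
      dplyr::group_by(.data$class) |>
      dplyr::summarise(arr_upper = mean(.data$arr_upper, na.rm = TRUE),
                       arr_lower = mean(.data$arr_lower, na.rm = TRUE),
                       .groups = "drop"),
    realm = species |>
      dplyr::group_by(.data$realm) |>
      dplyr::summarise(arr_upper = mean(.data$arr_upper, na.rm = TRUE),
                       arr_lower = mean(.data$arr_lower, na.rm = TRUE),
                       .groups = "drop")
  )
}

#' Run the full synthetic analysis pipeline
#'
#' Generates a world and climatology, simulates a species pool under a
#' hypothesis scenario, and for every species computes extreme body
#' temperatures, the potential thermal range, a scenario-realized range,
#' the analysis potential range (re-derived from the realized range, as in
#' a real-data analysis), and all filling statistics. Optionally adds the
#' acclimatization and behavioural-thermoregulation sensitivity columns.
#' Fully deterministic under `seed`.
#'
#' @param world_config,climate_config,scenario Configurations; see
#'   [world_config()], [climate_config()], [scenario_config()].
#' @param seed Integer seed driving all stages.
#' @param acclimatize Also compute acclimatized potential ranges and
#'   filling (columns suffixed `_acclim`).
#' @param behaviour Also compute the behaviourally adjusted warm filling
#'   (`warm_filling_behav_c`) for terrestrial species with a preferred
#'   temperature.
#' @param out_dir Optional directory; when given, writes `world.csv`,
#'   `climate/`, `species.csv`, `ranges.csv`, `filling.csv` and a
#'   provenance JSON.
#' @return A `thermofill_run` list: `world`, `climate`, `species`,
#'   `ranges` (named list of realized ranges), `potentials` (named list of
#'   `thermofill_potential`s), `filling` (tibble, one row per analysed
#'   species), `excluded` (tibble of skipped species with reasons), `seed`.
#' @export
run_pipeline <- function(world_config = thermofill::world_config(),
                         climate_config = thermofill::climate_config(),
                         scenario = scenario_config(),
                         seed = 1, acclimatize = FALSE, behaviour = FALSE,
                         out_dir = NULL) {
  world <- simulate_world(world_config, seed = seed)
  climate <- simulate_climate(world, climate_config, seed = seed + 1L)
  pool <- simulate_species_pool(world, climate, scenario, seed = seed + 2L)
  fallbacks <- if (acclimatize) arr_fallback_tables(pool) else NULL
  ranges <- list()
  potentials <- list()
  filling_rows <- list()
  excluded <- list()
  for (i in seq_len(nrow(pool))) {
    sp <- pool[i, ]
    res <- tryCatch(
      analyse_species(sp, world, climate, scenario,
                      acclimatize = acclimatize, behaviour = behaviour,
                      fallbacks = fallbacks),
      error = function(e) e)
    if (inherits(res, "error")) {
      excluded[[sp$species_id]] <- tibble::tibble(
        species_id = sp$species_id, reason = conditionMessage(res))
      next
    }
    ranges[[sp$species_id]] <- res$realized
    potentials[[sp$species_id]] <- res$potential
    filling_rows[[sp$species_id]] <- res$stats
  }
  filling <- dplyr::bind_rows(filling_rows)
  out <- structure(
    list(world = world, climate = climate, species = pool, ranges = ranges,
         potentials = potentials, filling = filling,
         excluded = dplyr::bind_rows(excluded), seed = seed,
         scenario = scenario),
    class = "thermofill_run")
  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

analyse_species <- function(sp, world, climate, scenario,
                            acclimatize = FALSE, behaviour = FALSE,
                            fallbacks = NULL) {
  if (isTRUE(sp$unplaceable)) {
    stop("unplaceable: thermal band intersects no encounterable cells",
         call. = FALSE)
  }
  habitat <- if (identical(sp$realm, "terrestrial")) {
    realm_habitat(world, sp$target_realm_id)
  } else {
    encounterable_habitat(sp, world)
  }
  fields <- body_temperatures(sp, climate, world, cells = habitat$cell_id)
  pot_synth <- potential_range(sp, fields, world, habitat = habitat)
  if (nrow(pot_synth$range) == 0) {
    stop("empty potential range at synthesis", call. = FALSE)
  }
  realized <- realize_range(sp, pot_synth, scenario)
  realized <- depth_elevation_correct(realized, sp, world)
  if (nrow(realized) == 0) {
    stop("realized range empty after depth/elevation correction",
         call. = FALSE)
  }
  potential <- potential_range(sp, fields, world, realized = realized)
  stats <- filling_stats(realized, potential, fields, sp)
  stats$abs_lat_mid <- abs(latitudinal_midpoint(realized))
  stats$range_size_cells <- nrow(realized)
  for (tr in c("realm", "metric_type", "dispersal_km", "body_mass_g",
               "dormancy", "class", "order", "family", "genus",
               "target_lat_deg")) {
    stats[[tr]] <- sp[[tr]]
  }
  if (acclimatize) {
    acc <- tryCatch({
      limits <- acclimatize_limits(sp, climate, fallbacks)
      pot_acc <- acclimatized_potential_range(sp, limits, fields, world,
                                              realized = realized)
      filling_stats(realized, pot_acc, fields, sp)
    }, error = function(e) NULL)
    stats$warm_filling_acclim_c <-
      if (is.null(acc)) NA_real_ else acc$warm_filling_c
    stats$cool_filling_acclim_c <-
      if (is.null(acc)) NA_real_ else acc$cool_filling_c
    stats$range_filling_acclim <-
      if (is.null(acc)) NA_real_ else acc$range_filling
  }
  if (behaviour) {
    beh <- tryCatch(
      behavioural_realized_warm_limit(sp, realized, climate, world),
      error = function(e) NULL)
    stats$warm_filling_behav_c <- if (is.null(beh)) NA_real_ else
      as.numeric(beh) - stats$potential_warm_c
  }
  list(realized = realized, potential = potential, stats = stats,
       fields = fields)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_world(run$world, file.path(out_dir, "world.csv"))
  write_climate(run$climate, file.path(out_dir, "climate"))
  write_species_table(run$species, file.path(out_dir, "species.csv"))
  readr::write_csv(run$filling, file.path(out_dir, "filling.csv"),
                   progress = FALSE)
  long <- purrr::imap(run$ranges, function(r, id) {
    dplyr::mutate(tibble::as_tibble(r), species_id = id, .before = 1)
  })
  readr::write_csv(dplyr::bind_rows(long), file.path(out_dir, "ranges.csv"),
                   progress = FALSE)
  prov <- list(
    seed = run$seed,
    package_version = as.character(utils::packageVersion("thermofill")),
    r_version = as.character(getRversion()),
    scenario = unclass(run$scenario)[c("scenario", "k", "n_species")],
    config_hash = rlang::hash(list(unclass(run$scenario),
                                   spec_of(run$world))))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.thermofill_run <- function(x, ...) {
  cat(sprintf(
    "<thermofill run: scenario %s (k = %g), %d species analysed, %d excluded>\n",
    x$scenario$scenario, x$scenario$k, nrow(x$filling), nrow(x$excluded)))
  invisible(x)
}

#' The canonical 10-cell toy strip fixture
#'
#' A single-column, 10-cell world (cell-centre latitudes 0.5..9.5) with
#' analytically simple body-temperature fields: `tbody_warm = 40 - lat`,
#' `tbody_cool = 20 - 2 * lat`. A species with upper limit 37 and lower
#' limit 5 has the potential range at latitudes 3.5..7.5 and potential
#' niche limits (36.5, 5.0). Three realized-range variants exercise the
#' four headline outcomes:
#' * `interior` (cells 5.5, 6.5): warm and cool niche underfilling of
#'   -2 degC each, range filling 0.4, equatorward bias +1/6;
#' * `perfect` (the potential itself): zero filling everywhere, range
#'   filling 1;
#' * `overhanging` (interior plus cell 8.5): cool niche underprediction of
#'   +2 degC.
#' The manifest carries each expected value with its derivation note.
#'
#' @return A list with `world`, `fields`, `species`, `habitat`,
#'   `potential`, `realized` (named list of the three variants) and
#'   `manifest` (tibble of expected values).
#' @export
make_toy_strip <- function() {
  spec <- grid_spec(n_lat = 10, n_lon = 1, cell_size_deg = 1,
                    lat_origin = 0, lon_origin = 0)
  cells <- grid_cells(spec)
  world <- cells
  world$is_land <- TRUE
  world$is_ocean <- FALSE
  world$is_coastal_land <- FALSE
  world$is_coastal_ocean <- FALSE
  world$realm_id <- 1L
  world$elevation_m <- 100
  world$depth_m <- NA_real_
  attr(world, "spec") <- spec
  class(world) <- c("thermofill_world", class(tibble::tibble()))
  fields <- new_bodytemp(
    dplyr::mutate(cells,
                  tbody_warm = 40 - .data$lat,
                  tbody_cool = 20 - 2 * .data$lat,
                  tbody_warm_sun = 42 - .data$lat,
                  tbody_cool_shade = 21 - 2 * .data$lat,
                  medium = "air"),
    spec, "toy")
  species <- tibble::tibble(
    species_id = "toy", class = "Reptilia", order = "Reptilia_ord1",
    family = "Reptilia_ord1_fam1", genus = "Reptilia_ord1_fam1_gen1",
    species = "toy_sp", realm = "terrestrial",
    upper_limit_c = 37, lower_limit_c = 5, metric_type = "critical",
    body_mass_g = 10, dispersal_km = 1, dormancy = "none",
    arr_upper = 0.2, arr_lower = 0.2, assay_acclimation_c = 20,
    t_pref_c = 30, elevation_min_m = NA_real_, elevation_max_m = NA_real_,
    depth_min_m = NA_real_, depth_max_m = NA_real_)
  habitat <- new_range(world, spec, "toy")
  potential <- thermal_clip(habitat, fields, species)
  pick <- function(lats) {
    range_from_cells(cells[cells$lat %in% lats, ], spec, "toy")
  }
  realized <- list(
    interior = pick(c(5.5, 6.5)),
    perfect = potential$range,
    overhanging = pick(c(5.5, 6.5, 8.5)))
  manifest <- tibble::tribble(
    ~quantity, ~variant, ~value, ~derivation,
    "potential_warm_c", NA, 36.5, "max(40 - lat) over retained lats 3.5..7.5",
    "potential_cool_c", NA, 5.0, "min(20 - 2 lat) over retained lats 3.5..7.5",
    "realized_warm_c", "interior", 34.5, "max(40 - lat) over {5.5, 6.5}",
    "realized_cool_c", "interior", 7.0, "min(20 - 2 lat) over {5.5, 6.5}",
    "warm_filling_c", "interior", -2.0, "34.5 - 36.5",
    "cool_filling_c", "interior", -2.0, "5.0 - 7.0",
    "range_filling", "interior", 0.4, "2 occupied of 5 potential cells",
    "equatorward_bias", "interior", 1 / 6,
    "split at 6.0: eq {3.5,4.5,5.5} underfilled 2/3, pole {6.5,7.5} underfilled 1/2",
    "warm_filling_c", "perfect", 0, "realized equals potential",
    "cool_filling_c", "perfect", 0, "realized equals potential",
    "range_filling", "perfect", 1, "realized equals potential",
    "equatorward_bias", "perfect", 0, "realized equals potential",
    "cool_filling_c", "overhanging", 2.0,
    "5.0 - min(20 - 2 lat) over {5.5, 6.5, 8.5} = 5 - 3",
    "warm_filling_c", "overhanging", -2.0, "warm edge unchanged by 8.5")
  list(world = world, fields = fields, species = species, habitat = habitat,
       potential = potential, realized = realized, manifest = manifest)
}
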