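# Shared small fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

small_world <- function() {
  fixture("small_world", function() {
    simulate_world(world_config(n_lat = 40, n_lon = 16, cell_size_deg = 1,
                                lat_origin = -20, n_continents = 1,
                                n_realms = 3), seed = 101)
  })
}

small_climate <- function() {
  fixture("small_climate", function() {
    simulate_climate(small_world(), climate_config(), seed = 102)
  })
}

# Random species x world draw used by the oracle-equivalence and fuzz
# suites. Body-temperature fields are arbitrary smooth random surfaces (the
# oracle check targets range construction and filling statistics, not the
# heat-balance model). Returns everything both implementations need.
random_case <- function(seed) {
  withr::with_seed(seed, {
    worlds <- fixture("case_worlds", function() {
      withr::with_seed(7777, {
        lapply(1:6, function(i) {
          simulate_world(world_config(
            n_lat = sample(8:20, 1) + i, n_lon = sample(6:18, 1),
            cell_size_deg = 2, lat_origin = -sample(10:25, 1),
            n_continents = sample(1:2, 1), n_realms = sample(1:4, 1),
            land_fraction = stats::runif(1, 0.25, 0.5)), seed = 7000 + i)
        })
      })
    })
    world <- worlds[[sample(length(worlds), 1)]]
    spec <- attr(world, "spec")
    n <- nrow(world)
    base <- 30 - 0.5 * abs(world$lat) + stats::rnorm(n, 0, 2)
    span <- stats::runif(1, 3, 10)
    realm <- sample(c("terrestrial", "subtidal", "intertidal"), 1)
    fields_cells <- switch(realm,
      terrestrial = world[world$is_land & world$realm_id > 0, ],
      subtidal = world[world$is_ocean, ],
      intertidal = world[world$is_coastal_land | world$is_coastal_ocean, ])
    if (nrow(fields_cells) == 0) {
      fields_cells <- world[world$is_land | world$is_ocean, ]
      realm <- if (any(fields_cells$is_land)) "terrestrial" else "subtidal"
      fields_cells <- if (realm == "terrestrial") {
        world[world$is_land & world$realm_id > 0, ]
      } else world[world$is_ocean, ]
    }
    j <- match(fields_cells$cell_id, world$cell_id)
    fields <- tibble::tibble(
      cell_id = fields_cells$cell_id, row = fields_cells$row,
      col = fields_cells$col, lat = fields_cells$lat,
      lon = fields_cells$lon,
      tbody_warm = base[j] + span / 2,
      tbody_cool = base[j] - span / 2,
      medium = "x")
    # occasionally punch climate holes
    if (stats::runif(1) < 0.3 && nrow(fields) > 4) {
      holes <- sample(nrow(fields), ceiling(nrow(fields) * 0.1))
      fields$tbody_warm[holes] <- NA_real_
      fields$tbody_cool[holes] <- NA_real_
    }
    fields <- thermofill:::new_bodytemp(
      dplyr::mutate(fields, tbody_warm_sun = .data$tbody_warm,
                    tbody_cool_shade = .data$tbody_cool, .after = "tbody_cool"),
      spec, "rnd")
    one_limit <- stats::runif(1) < 0.3
    upper <- stats::runif(1, 25, 38)
    lower <- upper - stats::runif(1, 6, 25)
    species <- tibble::tibble(
      species_id = "rnd", realm = realm,
      upper_limit_c = if (one_limit && stats::runif(1) < 0.5) NA_real_ else upper,
      lower_limit_c = NA_real_, metric_type = "critical",
      body_mass_g = 10, dispersal_km = 1, dormancy = "none",
      elevation_min_m = NA_real_,
      elevation_max_m = if (stats::runif(1) < 0.3) stats::runif(1, 500, 2000)
                        else NA_real_,
      depth_min_m = NA_real_,
      depth_max_m = if (stats::runif(1) < 0.3) stats::runif(1, 1500, 4000)
                    else NA_real_)
    if (is.na(species$upper_limit_c) || !one_limit) {
      species$lower_limit_c <- lower
    }
    # realized range: random subset of the medium cells, biased toward the
    # species' tolerable cells, sometimes overhanging them
    cand <- fields_cells
    if (nrow(cand) < 2) return(random_case(seed + 13))
    n_occ <- sample(seq_len(min(nrow(cand), 40)), 1)
    occ <- cand[sample(nrow(cand), n_occ), ]
    realized <- range_from_cells(occ, spec, "rnd")
    list(world = world, spec = spec, fields = fields, species = species,
         realized = realized)
  })
}
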