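#' Scenario configuration for synthetic species pools
#'
#' Defines the hypothesis scenario under which realized ranges are carved
#' out of potential ranges, plus the tolerance-breadth model and trait
#' distributions of the pool. The breadth model is linear in absolute target
#' latitude per realm: wide on land (`b1_terrestrial`, reflecting strong
#' latitudinal widening of terrestrial tolerance breadths) and nearly flat
#' in the ocean (`b1_marine`).
#'
#' Scenarios:
#' * `perfect` — realized equals potential (perfect niche filling).
#' * `temperate_tradeoff` — the equatorward-most fraction
#'   `k * |lat_mid| / 90` of potential cells is removed (biotic exclusion of
#'   high-latitude species at their equatorward edges).
#' * `reduced_abiotic` — a fraction `k * (1 - |lat_mid| / 90)` is removed,
#'   split equally between the equatorward-most and poleward-most cells
#'   (ranges at low latitude less abiotically limited at both edges).
#' * `cold_underprediction` — the potential range plus up to
#'   `ceiling(k * |lat_mid| / 15)` grid rows of thermally excluded cells
#'   beyond the poleward cold edge (emulating plasticity or microclimate
#'   buffering that lets species occupy cells colder than their lower
#'   limit).
#'
#' @param scenario Scenario name.
#' @param k Scenario strength in `[0, 1]`.
#' @param n_species Number of species in the pool.
#' @param realm_mix Named proportions for realms
#'   (`terrestrial`/`intertidal`/`subtidal`); normalised internally.
#' @param b0_terrestrial,b1_terrestrial,b0_marine,b1_marine Intercept and
#'   slope (degC per degree absolute latitude) of the tolerance-breadth
#'   model per realm class.
#' @param breadth_sd SD of interspecific scatter around the breadth model
#'   (degC).
#' @param one_limit_rate Probability a species has only one tolerance limit.
#' @param one_limit_upper_share Among one-limit species, share that keep the
#'   upper limit.
#' @param dormancy_probs Named probabilities for `none`, `summer`, `winter`,
#'   `both` (terrestrial species only).
#' @param arr_missing_rate Probability that a species lacks ARR estimates.
#' @param t_pref_rate Probability a terrestrial species has a preferred
#'   temperature estimate.
#' @param bounds_rate Probability a species has elevation/depth bounds.
#' @param max_tries Placement retries before a species is flagged
#'   unplaceable.
#' @return A list of class `thermofill_scenario_config`.
#' @export
scenario_config <- function(scenario = c("perfect", "temperate_tradeoff",
                                         "reduced_abiotic",
                                         "cold_underprediction"),
                            k = 0.5, n_species = 300,
                            realm_mix = c(terrestrial = 0.7,
                                          intertidal = 0.1, subtidal = 0.2),
                            b0_terrestrial = 22, b1_terrestrial = 0.25,
                            b0_marine = 12, b1_marine = 0.02,
                            breadth_sd = 2,
                            one_limit_rate = 0.5,
                            one_limit_upper_share = 0.8,
                            dormancy_probs = c(none = 0.8, summer = 0.05,
                                               winter = 0.1, both = 0.05),
                            arr_missing_rate = 0.3,
                            t_pref_rate = 0.7,
                            bounds_rate = 0.15,
                            max_tries = 30) {
  scenario <- match.arg(scenario)
  stopifnot(k >= 0, k <= 1, n_species >= 1)
  realm_mix <- realm_mix / sum(realm_mix)
  structure(as.list(environment()), class = "thermofill_scenario_config")
}

taxonomy_pools <- list(
  terrestrial = c("Reptilia", "Amphibia", "Insecta"),
  intertidal = c("Gastropoda", "Malacostraca"),
  subtidal = c("Actinopterygii", "Echinoidea")
)

#' Simulate a species pool on a synthetic world
#'
#' Each species gets a realm, a target cell in its encounterable medium, a
#' tolerance breadth from the per-realm linear breadth model, and tolerance
#' limits centred on the local span of extreme temperatures at the target
#' (so its thermal band intersects encounterable temperatures there).
#' Placement is retried at a new target when the drawn breadth cannot cover
#' the local annual span; species that never place are flagged
#' `unplaceable`. Taxonomy is assigned hierarchically so higher taxa are
#' shared within realms, and traits (mass, dispersal, dormancy, ARR,
#' preferred temperature, elevation/depth bounds) are drawn from simple
#' configurable distributions.
#'
#' @param world,climate Matching world and climate grids.
#' @param config A [scenario_config()].
#' @param seed Integer seed.
#' @return A `thermofill_species` tibble, one row per species, including the
#'   generator ground truth columns `target_lat_deg` and `target_realm_id`.
#' @export
simulate_species_pool <- function(world, climate, config = scenario_config(),
                                  seed = 1) {
  stopifnot(inherits(config, "thermofill_scenario_config"))
  check_same_spec(world, climate)
  cc <- climate$cells
  medium_extremes <- function(realm) {
    m <- if (realm == "terrestrial") {
      sel <- which(world$is_land & world$realm_id > 0)
      list(sel = sel, warm = cc$air_warm[sel], cool = cc$air_cool[sel],
           margin = 3)
    } else if (realm == "subtidal") {
      sel <- which(world$is_ocean)
      list(sel = sel, warm = cc$sst_warm[sel], cool = cc$sst_cool[sel],
           margin = 1)
    } else {
      sel <- which(world$is_coastal_ocean | world$is_coastal_land)
      list(sel = sel, warm = pmax(cc$air_warm[sel], cc$sst_warm[sel],
                                  na.rm = TRUE),
           cool = pmin(cc$air_cool[sel], cc$sst_cool[sel], na.rm = TRUE),
           margin = 2)
    }
    # zonal (per-row) mean extremes of the medium, used to centre each
    # species' thermal band on its target latitude
    rows <- world$row[m$sel]
    m$zonal <- tibble::tibble(
      row = sort(unique(rows)),
      lat = world$lat[m$sel][match(sort(unique(rows)), rows)],
      warm = as.numeric(tapply(m$warm, rows, mean, na.rm = TRUE)),
      cool = as.numeric(tapply(m$cool, rows, mean, na.rm = TRUE)))
    m
  }
  # local equatorward/poleward gradients (degC per degree of |lat|) of the
  # zonal extreme curves around a target latitude, same hemisphere only
  local_gradients <- function(zonal, lat_t, window = 8) {
    same_side <- sign(zonal$lat) == sign(lat_t) | zonal$lat == 0 | lat_t == 0
    win <- zonal[same_side &
                   abs(abs(zonal$lat) - abs(lat_t)) <= window, ]
    if (nrow(win) < 3) {
      win <- zonal[same_side &
                     abs(abs(zonal$lat) - abs(lat_t)) <= 2 * window, ]
    }
    if (nrow(win) < 3) return(c(g_warm = NA_real_, g_cool = NA_real_))
    x <- abs(win$lat)
    c(g_warm = max(0.02, -stats::coef(stats::lm(win$warm ~ x))[[2]]),
      g_cool = max(0.02, -stats::coef(stats::lm(win$cool ~ x))[[2]]))
  }
  n <- config$n_species
  withr::with_seed(seed, {
    realms <- sample(names(config$realm_mix), n, replace = TRUE,
                     prob = config$realm_mix)
    for (r in c("terrestrial", "intertidal", "subtidal")) {
      if (any(realms == r) && length(medium_extremes(r)$sel) == 0) {
        stop("world has no cells for planned realm ", r, call. = FALSE)
      }
    }
    med <- lapply(stats::setNames(nm = unique(realms)), medium_extremes)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      realm <- realms[i]
      m <- med[[realm]]
      terrestrial <- realm == "terrestrial"
      b0 <- if (terrestrial) config$b0_terrestrial else config$b0_marine
      b1 <- if (terrestrial) config$b1_terrestrial else config$b1_marine
      placed <- FALSE
      for (try in seq_len(config$max_tries)) {
        j <- sample(length(m$sel), 1)
        lat_t <- world$lat[m$sel[j]]
        breadth <- b0 + b1 * abs(lat_t) + stats::rnorm(1, 0, config$breadth_sd)
        zr <- m$zonal[m$zonal$row == world$row[m$sel[j]], ]
        span <- zr$warm - zr$cool
        if (is.finite(span) && breadth >= span + m$margin) {
          placed <- TRUE
          break
        }
      }
      # position the band so its thermal edges sit symmetrically (in
      # latitude) around the target: the slack beyond the local span is
      # shared between the warm (equatorward) and cool (poleward) edges in
      # inverse proportion to the local temperature gradients
      slack <- breadth - span
      g <- local_gradients(m$zonal, lat_t)
      warm_margin <- if (anyNA(g)) slack / 2 else
        slack * g[["g_warm"]] / (g[["g_warm"]] + g[["g_cool"]])
      upper <- zr$warm + warm_margin
      lower <- upper - breadth
      centre <- (upper + lower) / 2
      cls <- sample(taxonomy_pools[[realm]], 1)
      ord <- paste0(cls, "_ord", sample(3, 1))
      fam <- paste0(ord, "_fam", sample(4, 1))
      gen <- paste0(fam, "_gen", sample(5, 1))
      one_limit <- stats::runif(1) < config$one_limit_rate
      keep_upper <- !one_limit || stats::runif(1) < config$one_limit_upper_share
      keep_lower <- !one_limit || !keep_upper
      dorm <- if (terrestrial) {
        sample(names(config$dormancy_probs), 1, prob = config$dormancy_probs)
      } else "none"
      has_bounds <- stats::runif(1) < config$bounds_rate
      rows[[i]] <- tibble::tibble(
        species_id = sprintf("sp%04d", i),
        class = cls, order = ord, family = fam, genus = gen,
        species = paste0(gen, "_sp", i),
        realm = realm,
        upper_limit_c = if (keep_upper) upper else NA_real_,
        lower_limit_c = if (keep_lower) lower else NA_real_,
        metric_type = sample(c("critical", "lethal"), 1, prob = c(0.8, 0.2)),
        body_mass_g = exp(stats::rnorm(1, log(10), 1.5)),
        dispersal_km = sample(c(0.1, 1, 10, 100), 1),
        dormancy = dorm,
        arr_upper = if (stats::runif(1) < config$arr_missing_rate) NA_real_
                    else round(stats::runif(1, 0.05, 0.45), 2),
        arr_lower = if (stats::runif(1) < config$arr_missing_rate) NA_real_
                    else round(stats::runif(1, 0.05, 0.45), 2),
        assay_acclimation_c = round(stats::runif(1, 18, 25), 1),
        t_pref_c = if (terrestrial && stats::runif(1) < config$t_pref_rate) {
          round(centre + stats::runif(1, 2, 8), 1)
        } else NA_real_,
        elevation_min_m = if (terrestrial && has_bounds) 0 else NA_real_,
        elevation_max_m = if (terrestrial && has_bounds) {
          round(stats::runif(1, 800, 3000))
        } else NA_real_,
        depth_min_m = if (!terrestrial && has_bounds) 0 else NA_real_,
        depth_max_m = if (!terrestrial && has_bounds) {
          round(stats::runif(1, 1500, 4500))
        } else NA_real_,
        target_lat_deg = lat_t,
        target_realm_id = world$realm_id[m$sel[j]],
        unplaceable = !placed
      )
    }
    out <- dplyr::bind_rows(rows)
    class(out) <- c("thermofill_species", class(tibble::tibble()))
    out
  })
}

#' Carve a realized range out of a potential range under a scenario
#'
#' Applies the geographic exclusion rule of the configured scenario (see
#' [scenario_config()]) to the species' potential range. Exclusion operates
#' on latitude-ordered cell lists (equatorward distance = ascending absolute
#' latitude, ties broken by longitude index), mirroring a geographic
#' mechanism at the range edge; the filling statistics downstream must
#' recover its thermal signature. Removal counts are rounded to the nearest
#' cell. If removal would empty the range, the single most poleward cell is
#' retained and the range flagged.
#'
#' @param species One-row species tibble.
#' @param potential A `thermofill_potential` (preferred; required for
#'   `cold_underprediction`) or bare `thermofill_range`.
#' @param scenario A [scenario_config()].
#' @param seed Unused by the deterministic scenario rules; kept so future
#'   stochastic scenarios keep the same interface.
#' @return A `thermofill_range`; attribute `flags` records degenerate cases.
#' @export
realize_range <- function(species, potential, scenario = scenario_config(),
                          seed = NULL) {
  is_pot <- inherits(potential, "thermofill_potential")
  pot <- if (is_pot) potential$range else potential
  if (nrow(pot) == 0) {
    stop("cannot realize a range from an empty potential", call. = FALSE)
  }
  flags <- character()
  spec <- spec_of(pot)
  if (scenario$scenario == "perfect") {
    # perfect filling: realized is the potential, verbatim
    out <- new_range(pot, spec, species$species_id)
    attr(out, "flags") <- flags
    return(out)
  }
  # a realized range grows from one colonized region: when the potential
  # consists of several disjoint latitudinal bands (e.g. mirror-image bands
  # in both hemispheres of an unobstructed ocean), only the band containing
  # the species' target latitude is occupied
  target_lat <- trait(species, "target_lat_deg")
  if (!is.na(target_lat)) {
    rows <- sort(unique(pot$row))
    band_id <- cumsum(c(1L, diff(rows) > 1L))
    target_row <- pot$row[which.min(abs(pot$lat - target_lat))]
    keep_band <- band_id[match(target_row, rows)]
    pot <- new_range(pot[pot$row %in% rows[band_id == keep_band], ], spec,
                     species$species_id)
  }
  n <- nrow(pot)
  lat_mid <- latitudinal_midpoint(pot)
  eq_order <- order(abs(pot$lat), pot$col)     # equatorward-most first
  pole_order <- rev(eq_order)
  keep <- rep(TRUE, n)
  if (scenario$scenario == "perfect") {
    # realized equals potential
  } else if (scenario$scenario == "temperate_tradeoff") {
    f <- scenario$k * abs(lat_mid) / 90
    n_rm <- round(f * n)
    if (n_rm >= n) {
      keep[] <- FALSE
      keep[pole_order[1]] <- TRUE
      flags <- c(flags, "truncated_to_single")
    } else {
      keep[eq_order[seq_len(n_rm)]] <- FALSE
    }
  } else if (scenario$scenario == "reduced_abiotic") {
    g <- scenario$k * (1 - abs(lat_mid) / 90)
    # equal split between the two ends; an odd removal count loses its
    # remainder rather than biasing one end
    n_eq <- n_pole <- floor(round(g * n) / 2)
    n_rm <- n_eq + n_pole
    if (n_rm >= n) {
      keep[] <- FALSE
      central <- order(abs(pot$lat - lat_mid))[1]
      keep[central] <- TRUE
      flags <- c(flags, "truncated_to_single")
    } else {
      if (n_eq > 0) keep[eq_order[seq_len(n_eq)]] <- FALSE
      if (n_pole > 0) keep[pole_order[seq_len(n_pole)]] <- FALSE
    }
  } else if (scenario$scenario == "cold_underprediction") {
    if (!is_pot) {
      stop("cold_underprediction needs a `thermofill_potential` (its ",
           "restriction log supplies the thermally excluded cells)",
           call. = FALSE)
    }
    log <- potential$restriction_log
    cold <- log[log$reason == "too_cold", ]
    d <- ceiling(scenario$k * abs(lat_mid) / 15)
    if (d > 0 && nrow(cold) > 0) {
      if (lat_mid >= 0) {
        edge <- max(pot$row)
        add <- cold[cold$row > edge & cold$row <= edge + d, ]
      } else {
        edge <- min(pot$row)
        add <- cold[cold$row < edge & cold$row >= edge - d, ]
      }
      if (nrow(add) > 0) {
        spec <- spec_of(pot)
        extra <- grid_cells(spec)
        extra <- extra[match(add$cell_id, extra$cell_id), ]
        out <- new_range(rbind(pot[keep, names(extra)], extra), spec,
                         species$species_id)
        attr(out, "flags") <- flags
        return(out)
      }
    }
  } else {
    stop("unknown scenario: ", scenario$scenario, call. = FALSE)
  }
  out <- new_range(pot[keep, ], spec_of(pot), species$species_id)
  attr(out, "flags") <- flags
  out
}
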