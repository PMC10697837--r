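SIGMA_SB <- 5.670374419e-8   # W m-2 K-4
CP_MOLAR <- 29.3             # J mol-1 K-1, molar heat capacity of air
LAMBDA_MOLAR <- 44000        # J mol-1, molar latent heat of vaporisation
P_ATM_KPA <- 101.3

# Magnus saturation vapour pressure (kPa) and its temperature derivative
sat_vp <- function(t_c) 0.611 * exp(17.502 * t_c / (t_c + 240.97))
sat_vp_slope <- function(t_c) {
  sat_vp(t_c) * 17.502 * 240.97 / (t_c + 240.97)^2
}

#' Heat-balance parameters for an ectotherm
#'
#' Lumped parameters of the steady-state energy balance used to compute
#' operative temperatures. The characteristic dimension is derived from body
#' mass assuming unit density (`d = (mass_g * 1e-6)^(1/3)` metres), so a 1 g
#' animal has `d` = 1 cm and a 1 kg animal `d` = 10 cm. Boundary-layer
#' conductances scale as `sqrt(wind / d)` (Campbell-Norman forced
#' convection), so larger animals are more decoupled from air temperature.
#'
#' @param body_mass_g Body mass in grams (required).
#' @param absorptance Shortwave absorptance of the skin, in `[0, 1]`.
#' @param emissivity Longwave emissivity, in `[0, 1]`.
#' @param skin_wetness Effective fraction of a free-water surface, `[0, 1]`.
#' @param shade_solar_fraction Fraction of solar flux reaching an animal in
#'   full shade, `[0, 1]`.
#' @return A list of class `thermofill_heat_params`.
#' @export
heat_balance_params <- function(body_mass_g, absorptance = 0.85,
                                emissivity = 0.95, skin_wetness = 0.1,
                                shade_solar_fraction = 0.1) {
  if (length(body_mass_g) != 1 || is.na(body_mass_g) || body_mass_g <= 0) {
    stop_missing_trait("body_mass_g",
                       "a positive body mass is required to model operative temperatures")
  }
  for (nm in c("absorptance", "emissivity", "skin_wetness",
               "shade_solar_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1) {
      stop(sprintf("`%s` must be a single value in [0, 1]", nm),
           call. = FALSE)
    }
  }
  structure(
    list(body_mass_g = body_mass_g, absorptance = absorptance,
         emissivity = emissivity, skin_wetness = skin_wetness,
         shade_solar_fraction = shade_solar_fraction,
         characteristic_dimension_m = (body_mass_g * 1e-6)^(1 / 3)),
    class = "thermofill_heat_params"
  )
}

stop_missing_trait <- function(trait, msg) {
  rlang::abort(message = sprintf("missing trait `%s`: %s", trait, msg),
               class = "thermofill_missing_trait", trait = trait)
}

# Vectorised Newton solve of the steady-state energy balance
#   a*S + e*sigma*Ta_K^4 = e*sigma*Te_K^4 + cp*gH*(Te - Ta)
#                          + w*lambda*gv*(es(Te) - rh*es(Ta))/P
# The right-hand side is strictly increasing in Te, so the root is unique.
te_solve <- function(t_air_c, solar_wm2, wind_ms, rh_frac, params,
                     tol = 1e-8, max_iter = 100) {
  n <- max(length(t_air_c), length(solar_wm2), length(wind_ms),
           length(rh_frac))
  t_air_c <- rep_len(t_air_c, n); solar_wm2 <- rep_len(solar_wm2, n)
  wind_ms <- rep_len(wind_ms, n); rh_frac <- rep_len(rh_frac, n)
  if (any(!is.finite(t_air_c))) {
    stop("non-finite air temperatures in energy balance input", call. = FALSE)
  }
  d <- params$characteristic_dimension_m
  u <- pmax(wind_ms, 0.1)
  g_h <- 1.4 * 0.135 * sqrt(u / d)           # mol m-2 s-1
  g_v <- 1.4 * 0.147 * sqrt(u / d)
  e <- params$emissivity
  w <- params$skin_wetness
  load <- params$absorptance * solar_wm2 +
    e * SIGMA_SB * (t_air_c + 273.15)^4 -
    w * LAMBDA_MOLAR * g_v * (-rh_frac * sat_vp(t_air_c)) / P_ATM_KPA
  te <- t_air_c
  for (iter in seq_len(max_iter)) {
    te_k <- te + 273.15
    f <- load - e * SIGMA_SB * te_k^4 - CP_MOLAR * g_h * (te - t_air_c) -
      w * LAMBDA_MOLAR * g_v * sat_vp(te) / P_ATM_KPA
    if (all(abs(f) <= tol)) return(te)
    fp <- -(4 * e * SIGMA_SB * te_k^3 + CP_MOLAR * g_h +
              w * LAMBDA_MOLAR * g_v * sat_vp_slope(te) / P_ATM_KPA)
    te <- te - f / fp
  }
  bad <- sum(abs(f) > tol)
  rlang::abort(
    message = sprintf(
      "energy balance failed to converge for %d of %d cases (max residual %.3g W m-2 after %d iterations)",
      bad, n, max(abs(f)), max_iter),
    class = "thermofill_numeric_error")
}

#' Equilibrium (operative) body temperature
#'
#' Solves the steady-state heat balance of an ectotherm: absorbed shortwave
#' radiation plus incoming longwave (at air temperature) equals emitted
#' longwave, convective exchange and evaporative cooling from wet skin. With
#' zero solar load and dry skin the solution is exactly air temperature.
#' The solution is found by Newton iteration to a residual below `tol`
#' (W m-2); uniqueness follows from monotonicity of the dissipation terms in
#' body temperature.
#'
#' @param env A data frame with columns `t_air_c`, `solar_wm2`, `wind_ms`,
#'   `rh_frac` (one row per case), e.g. from [day_profile()].
#' @param params A [heat_balance_params()].
#' @param tol Convergence tolerance on the energy residual (W m-2).
#' @return Numeric vector of operative temperatures (degC), one per row.
#' @export
equilibrium_body_temperature <- function(env, params, tol = 1e-8) {
  req <- c("t_air_c", "solar_wm2", "wind_ms", "rh_frac")
  missing_cols <- setdiff(req, names(env))
  if (length(missing_cols)) {
    stop("`env` lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  te_solve(env$t_air_c, env$solar_wm2, env$wind_ms, env$rh_frac, params,
           tol = tol)
}

new_bodytemp <- function(df, spec, species_id) {
  out <- tibble::as_tibble(df)
  attr(out, "spec") <- spec
  attr(out, "species_id") <- species_id
  class(out) <- c("thermofill_bodytemp", class(tibble::tibble()))
  out
}

params_for_species <- function(species, params) {
  if (!is.null(params)) return(params)
  heat_balance_params(body_mass_g = species$body_mass_g)
}

# month x cell matrices of monthly means for a cell subset (world order
# indices `sel` into climate$cells)
monthly_matrix <- function(climate, sel, what = c("air", "sst")) {
  what <- match.arg(what)
  v <- if (what == "air") climate$monthly$t_air_c else climate$monthly$t_sst_c
  idx <- rep((sel - 1L) * 12L, each = 12L) + rep(1:12, length(sel))
  matrix(v[idx], nrow = 12)
}

# Warmest (or coldest) month per cell among active months; ties go to the
# lowest month index. `metric` is a 12 x k matrix, `active` a 12 x k logical.
pick_month <- function(metric, active, which = c("warmest", "coldest")) {
  which <- match.arg(which)
  m <- metric
  m[!active] <- NA_real_
  if (which == "coldest") m <- -m
  apply(m, 2, which.max)
}

# Active-month masks per cell for a dormancy class. Ranking metric is the
# medium's monthly mean (12 x k matrix).
active_months <- function(metric_warm, metric_cool, dormancy) {
  k <- ncol(metric_warm)
  act <- matrix(TRUE, 12, k)
  if (dormancy %in% c("summer", "both")) {
    for (j in seq_len(k)) {
      warm6 <- order(metric_warm[, j], decreasing = TRUE)[1:6]
      act[warm6, j] <- FALSE
    }
  }
  if (dormancy %in% c("winter", "both")) {
    act2 <- matrix(TRUE, 12, k)
    for (j in seq_len(k)) {
      cold6 <- order(metric_cool[, j], decreasing = FALSE)[1:6]
      act2[cold6, j] <- FALSE
    }
    return(list(warm = act, cool = act2))
  }
  list(warm = act, cool = matrix(TRUE, 12, k))
}

#' Gridded extreme operative temperatures of a terrestrial species
#'
#' For every land cell, computes hourly operative temperatures across the
#' hottest and coldest days of the year and summarises them the way the
#' niche analysis needs: the warm extreme is the hottest hourly *shaded*
#' operative temperature (animals are assumed to retreat to shade during
#' heat extremes) and the cool extreme is the coldest hourly *sun-exposed*
#' operative temperature (animals bask during cold extremes). Full-sun warm
#' and full-shade cool auxiliaries are kept for the behavioural
#' thermoregulation analysis.
#'
#' @param species One-row species tibble (needs `body_mass_g` unless
#'   `params` is given).
#' @param climate A [simulate_climate()] object.
#' @param world The world grid.
#' @param params Optional [heat_balance_params()] override.
#' @param active Optional list of 12 x n-cell logical matrices (`warm`,
#'   `cool`) restricting which months may contribute (used by dormancy
#'   masking).
#' @param cells Optional vector of cell ids (must be land) to compute on;
#'   default all land cells.
#' @return A `thermofill_bodytemp` tibble over land cells with columns
#'   `tbody_warm`, `tbody_cool`, `tbody_warm_sun`, `tbody_cool_shade` and
#'   `medium = "air"`.
#' @export
terrestrial_extremes <- function(species, climate, world, params = NULL,
                                 active = NULL, cells = NULL) {
  check_same_spec(world, climate)
  params <- params_for_species(species, params)
  if (is.null(cells)) {
    land <- which(world$is_land)
  } else {
    land <- match(cells, world$cell_id)
    if (anyNA(land) || !all(world$is_land[land])) {
      stop("`cells` must be land cells of the world grid", call. = FALSE)
    }
  }
  if (!length(land)) stop("world has no land cells", call. = FALSE)
  air <- monthly_matrix(climate, land, "air")
  if (is.null(active)) {
    active <- list(warm = matrix(TRUE, 12, length(land)),
                   cool = matrix(TRUE, 12, length(land)))
  }
  ids <- world$cell_id[land]
  m_warm <- pick_month(air, active$warm, "warmest")
  m_cool <- pick_month(air, active$cool, "coldest")
  hot <- day_profile(climate, ids, month = m_warm)
  cold <- day_profile(climate, ids, month = m_cool)
  sh <- params$shade_solar_fraction
  te_hot_shade <- te_solve(hot$t_air_c, hot$solar_wm2 * sh, hot$wind_ms,
                           hot$rh_frac, params)
  te_hot_sun <- te_solve(hot$t_air_c, hot$solar_wm2, hot$wind_ms,
                         hot$rh_frac, params)
  te_cold_sun <- te_solve(cold$t_air_c, cold$solar_wm2, cold$wind_ms,
                          cold$rh_frac, params)
  te_cold_shade <- te_solve(cold$t_air_c, cold$solar_wm2 * sh, cold$wind_ms,
                            cold$rh_frac, params)
  per_cell <- function(v, f) apply(matrix(v, nrow = 24), 2, f)
  df <- tibble::tibble(
    cell_id = ids, row = world$row[land], col = world$col[land],
    lat = world$lat[land], lon = world$lon[land],
    tbody_warm = per_cell(te_hot_shade, max),
    tbody_cool = per_cell(te_cold_sun, min),
    tbody_warm_sun = per_cell(te_hot_sun, max),
    tbody_cool_shade = per_cell(te_cold_shade, min),
    medium = "air"
  )
  new_bodytemp(df, spec_of(world), species$species_id)
}

#' Gridded extreme body temperatures of a marine species
#'
#' Subtidal species: body temperature equals sea surface temperature, so the
#' warm/cool extremes are the annual extreme daily SSTs on every ocean cell.
#' Intertidal species live in the coastal band (coastal-ocean plus
#' coastal-land cells) and experience both media where both exist: on
#' coastal-ocean cells the warm extreme is the more extreme of the air and
#' SST warm extremes (and the cool extreme the more extreme minimum); on
#' coastal-land cells only air is available.
#'
#' @inheritParams terrestrial_extremes
#' @return A `thermofill_bodytemp` tibble over the species'
#'   encounterable-medium cells, with `medium` one of `"sst"`, `"air"`,
#'   `"both"`.
#' @export
marine_extremes <- function(species, climate, world, active = NULL,
                            cells = NULL) {
  check_same_spec(world, climate)
  realm <- species$realm
  if (!is.null(cells)) {
    sel <- match(cells, world$cell_id)
    if (anyNA(sel)) stop("unknown cell ids in `cells`", call. = FALSE)
  } else if (realm == "subtidal") {
    sel <- which(world$is_ocean)
  } else if (realm == "intertidal") {
    sel <- which(world$is_coastal_ocean | world$is_coastal_land)
  } else {
    stop("marine_extremes() handles subtidal or intertidal species",
         call. = FALSE)
  }
  if (!length(sel)) stop("no cells for realm ", realm, call. = FALSE)
  k <- length(sel)
  if (is.null(active)) {
    active <- list(warm = matrix(TRUE, 12, k), cool = matrix(TRUE, 12, k))
  }
  air <- monthly_matrix(climate, sel, "air")
  sst <- monthly_matrix(climate, sel, "sst")
  half_d <- climate$cells$diurnal_amp_c[sel] / 2
  month_extreme <- function(metric, act, f, offset = 0) {
    m <- metric
    m[!act] <- NA_real_
    vapply(seq_len(k), function(j) {
      v <- m[, j]
      if (all(is.na(v))) return(NA_real_)
      f(v, na.rm = TRUE)
    }, numeric(1)) + offset
  }
  air_warm <- month_extreme(air, active$warm, max, half_d)
  air_cool <- month_extreme(air, active$cool, min, -half_d)
  sst_warm <- month_extreme(sst, active$warm, max)
  sst_cool <- month_extreme(sst, active$cool, min)
  is_oc <- world$is_ocean[sel]
  if (realm == "subtidal") {
    warm <- sst_warm; cool <- sst_cool; medium <- rep("sst", k)
  } else {
    # more extreme of the two media where both exist (coastal-ocean cells);
    # air only on coastal-land cells
    warm <- ifelse(is_oc, pmax(air_warm, sst_warm), air_warm)
    cool <- ifelse(is_oc, pmin(air_cool, sst_cool), air_cool)
    medium <- ifelse(is_oc, "both", "air")
  }
  df <- tibble::tibble(
    cell_id = world$cell_id[sel], row = world$row[sel], col = world$col[sel],
    lat = world$lat[sel], lon = world$lon[sel],
    tbody_warm = warm, tbody_cool = cool,
    tbody_warm_sun = warm, tbody_cool_shade = cool,
    medium = medium
  )
  new_bodytemp(df, spec_of(world), species$species_id)
}

#' Per-species gridded extreme body temperatures
#'
#' Dispatches on the species' realm ([terrestrial_extremes()] or
#' [marine_extremes()]) and applies seasonal dormancy masking when the
#' species has a dormancy class.
#'
#' @inheritParams terrestrial_extremes
#' @param apply_dormancy Apply [apply_dormancy_mask()] for species with
#'   `dormancy != "none"`.
#' @return A `thermofill_bodytemp` tibble.
#' @export
body_temperatures <- function(species, climate, world, params = NULL,
                              apply_dormancy = TRUE, cells = NULL) {
  fields <- if (identical(species$realm, "terrestrial")) {
    terrestrial_extremes(species, climate, world, params, cells = cells)
  } else {
    marine_extremes(species, climate, world, cells = cells)
  }
  dorm <- trait(species, "dormancy", "none")
  if (apply_dormancy && !is.na(dorm) && dorm != "none") {
    fields <- apply_dormancy_mask(fields, species, climate, world,
                                  params = params)
  }
  fields
}

#' Mask dormancy months out of extreme body temperatures
#'
#' Species with seasonal dormancy do not experience the year's most extreme
#' months: summer dormancy masks the six warmest months of each cell before
#' the warm extreme is selected, winter dormancy masks the six coldest
#' months before the cool extreme, `"both"` applies both. Months are ranked
#' per cell by the medium's monthly mean temperature (air on land, SST in
#' the ocean, the more extreme of the two on both-media cells), with ties
#' broken by month index. Extremes are recomputed from the monthly/diurnal
#' climate model restricted to the active months, so masking is idempotent
#' and can only cool the warm extreme / warm the cool extreme.
#'
#' @param fields A `thermofill_bodytemp` from [body_temperatures()].
#' @param species One-row species tibble (supplies `dormancy`).
#' @param climate,world Climate and world grids of the same spec.
#' @param params Optional [heat_balance_params()] override (terrestrial).
#' @return A `thermofill_bodytemp` with masked extremes; identical to the
#'   input when `dormancy = "none"`.
#' @export
apply_dormancy_mask <- function(fields, species, climate, world,
                                params = NULL) {
  dorm <- trait(species, "dormancy", "none")
  if (is.na(dorm) || dorm == "none") return(fields)
  if (!dorm %in% c("summer", "winter", "both")) {
    stop("unknown dormancy class: ", dorm, call. = FALSE)
  }
  check_same_spec(fields, climate, world)
  sel <- match(fields$cell_id, world$cell_id)
  if (identical(species$realm, "terrestrial")) {
    air <- monthly_matrix(climate, sel, "air")
    act <- active_months(air, air, dorm)
    out <- terrestrial_extremes(species, climate, world, params,
                                active = act, cells = fields$cell_id)
  } else {
    air <- monthly_matrix(climate, sel, "air")
    sst <- monthly_matrix(climate, sel, "sst")
    if (identical(species$realm, "subtidal")) {
      warm_metric <- sst; cool_metric <- sst
    } else {
      warm_metric <- pmax(air, sst, na.rm = TRUE)
      cool_metric <- pmin(air, sst, na.rm = TRUE)
    }
    act <- active_months(warm_metric, cool_metric, dorm)
    out <- marine_extremes(species, climate, world, active = act,
                           cells = fields$cell_id)
  }
  # masking never touches the opposite edge
  if (dorm == "summer") {
    out$tbody_cool <- fields$tbody_cool
    out$tbody_cool_shade <- fields$tbody_cool_shade
  } else if (dorm == "winter") {
    out$tbody_warm <- fields$tbody_warm
    out$tbody_warm_sun <- fields$tbody_warm_sun
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
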