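#' Resolve acclimation response ratios for a species
#'
#' ARR (acclimation response ratio) is the slope of a tolerance limit
#' against experimental acclimation temperature. Species-specific values
#' are used when present; otherwise class-averaged, then realm-averaged
#' fallbacks are taken from the supplied tables.
#'
#' @param species One-row species tibble.
#' @param fallbacks Optional list with tibbles `class` (`class`,
#'   `arr_upper`, `arr_lower`) and/or `realm` (`realm`, `arr_upper`,
#'   `arr_lower`).
#' @return A list with `arr_upper`, `arr_lower` and `source`
#'   (`species`/`class`/`realm`).
#' @export
resolve_arr <- function(species, fallbacks = NULL) {
  u <- trait(species, "arr_upper")
  l <- trait(species, "arr_lower")
  # ARR is only needed for the limit(s) the species actually has
  need_u <- !is.na(trait(species, "upper_limit_c"))
  need_l <- !is.na(trait(species, "lower_limit_c"))
  if (!need_u) u <- 0
  if (!need_l) l <- 0
  src <- "species"
  for (lvl in c("class", "realm")) {
    if (!is.na(u) && !is.na(l)) break
    tab <- fallbacks[[lvl]]
    if (is.null(tab)) next
    row <- tab[tab[[lvl]] == species[[lvl]], ]
    if (nrow(row) == 1) {
      if (is.na(u)) u <- row$arr_upper
      if (is.na(l)) l <- row$arr_lower
      src <- lvl
    }
  }
  if (is.na(u) || is.na(l)) {
    stop_missing_trait("arr", "no species ARR and no class/realm fallback available")
  }
  list(arr_upper = u, arr_lower = l, source = src)
}

#' Acclimatized tolerance limits per grid cell
#'
#' Shifts each tolerance limit by the ARR times the difference between the
#' local acclimation temperature and the assay acclimation temperature:
#' the upper limit acclimatizes to the warmest temperature of the week
#' before the hottest day, the lower limit to the coldest temperature of
#' the seven weeks before the coldest day (both emitted by the climate
#' generator as `acclim_warm`/`acclim_cool`). With ARR = 0 the grids are
#' spatially constant and equal the assay limits.
#'
#' @param species One-row species tibble (needs `assay_acclimation_c`).
#' @param climate A [simulate_climate()] object.
#' @param fallbacks See [resolve_arr()].
#' @return A tibble (`cell_id`, `upper_limit_c`, `lower_limit_c`) of
#'   cell-specific limits, with the ARR source as attribute.
#' @export
acclimatize_limits <- function(species, climate, fallbacks = NULL) {
  assay <- trait(species, "assay_acclimation_c")
  if (is.na(assay)) {
    stop("`assay_acclimation_c` is required to acclimatize limits ",
         "(no silent default)", call. = FALSE)
  }
  arr <- resolve_arr(species, fallbacks)
  cc <- climate$cells
  upper <- trait(species, "upper_limit_c")
  lower <- trait(species, "lower_limit_c")
  out <- tibble::tibble(
    cell_id = cc$cell_id,
    upper_limit_c = if (is.na(upper)) NA_real_ else
      upper + arr$arr_upper * (cc$acclim_warm - assay),
    lower_limit_c = if (is.na(lower)) NA_real_ else
      lower + arr$arr_lower * (cc$acclim_cool - assay)
  )
  attr(out, "arr_source") <- arr$source
  attr(out, "species_id") <- species$species_id
  out
}

#' Potential range under acclimatized limits
#'
#' Identical to [potential_range()] but clipping each habitat cell against
#' the species' acclimatized limits in that cell.
#'
#' @inheritParams potential_range
#' @param limits Cell-specific limits from [acclimatize_limits()].
#' @return A `thermofill_potential`.
#' @export
acclimatized_potential_range <- function(species, limits, fields, world,
                                         realized = NULL, habitat = NULL) {
  potential_range(species, fields, world, realized = realized,
                  habitat = habitat, limits_grid = limits)
}

#' Behaviourally adjusted realized warm niche limit
#'
#' Relaxes the assumption that terrestrial animals always retreat to shade
#' during heat extremes: an animal thermoregulating toward its preferred
#' temperature can hold any body temperature between the shaded and
#' sun-exposed operative temperatures of a given hour. The achievable
#' temperature in a cell-hour is the value in that interval closest to
#' `t_pref_c`, and the adjusted realized warm limit is the maximum achieved
#' value over all occupied cells and hot-day hours. It therefore never
#' exceeds the all-sun maximum nor drops below the all-shade maximum.
#'
#' @param species One-row species tibble (terrestrial, with `t_pref_c`).
#' @param realized The realized range.
#' @param climate,world Climate and world grids.
#' @param params Optional [heat_balance_params()] override.
#' @return The adjusted realized warm limit (degC), with attribute
#'   `n_cells` (occupied land cells used).
#' @export
behavioural_realized_warm_limit <- function(species, realized, climate,
                                            world, params = NULL) {
  if (!identical(species$realm, "terrestrial")) {
    stop("behavioural thermoregulation analysis applies to terrestrial ",
         "species only", call. = FALSE)
  }
  t_pref <- trait(species, "t_pref_c")
  if (is.na(t_pref)) {
    stop_missing_trait("t_pref_c",
                       "preferred temperature is required for the behaviour analysis")
  }
  check_same_spec(realized, climate, world)
  params <- params_for_species(species, params)
  occ <- realized$cell_id[realized$cell_id %in%
                            world$cell_id[world$is_land]]
  if (!length(occ)) {
    stop("realized range contains no land cells with climate", call. = FALSE)
  }
  hot <- day_profile(climate, occ, day = "hot")
  te_shade <- te_solve(hot$t_air_c, hot$solar_wm2 * params$shade_solar_fraction,
                       hot$wind_ms, hot$rh_frac, params)
  te_sun <- te_solve(hot$t_air_c, hot$solar_wm2, hot$wind_ms, hot$rh_frac,
                     params)
  lo <- pmin(te_shade, te_sun)
  hi <- pmax(te_shade, te_sun)
  achieved <- pmin(pmax(t_pref, lo), hi)
  out <- max(achieved)
  attr(out, "n_cells") <- length(occ)
  out
}
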