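#' Warm and cool niche limits of a range
#'
#' The span of extreme body temperatures across a presence grid: the warm
#' limit is the maximum warm extreme and the cool limit the minimum cool
#' extreme over occupied cells with body-temperature data. The fraction of
#' occupied cells covered by data is reported rather than guessing a
#' coverage threshold.
#'
#' @param range A `thermofill_range`.
#' @param fields The species' `thermofill_bodytemp`.
#' @return A list with `warm`, `cool` (degC, NA when no covered cells),
#'   `coverage` (fraction of occupied cells with data) and `n_covered`.
#' @export
niche_limits <- function(range, fields) {
  check_same_spec(range, fields)
  j <- match(range$cell_id, fields$cell_id)
  warm <- fields$tbody_warm[j]
  cool <- fields$tbody_cool[j]
  covered <- !is.na(warm) & !is.na(cool)
  if (!any(covered)) {
    return(list(warm = NA_real_, cool = NA_real_, coverage = 0,
                n_covered = 0L))
  }
  list(warm = max(warm[covered]), cool = min(cool[covered]),
       coverage = mean(covered), n_covered = sum(covered))
}

#' Warm and cool niche filling
#'
#' Niche filling is the signed difference between realized and potential
#' niche extremes, in degC: `warm = realized_warm - potential_warm` and
#' `cool = potential_cool - realized_cool`. Negative values denote
#' underfilling (the species does not occupy all extreme temperatures
#' available to it); positive values denote underprediction (the realized
#' niche exceeds what the tolerance limits predict). Only the side(s)
#' corresponding to available limits are produced.
#'
#' @param potential_limits,realized_limits Lists from [niche_limits()].
#' @param limits_used `"both"`, `"upper_only"` or `"lower_only"`.
#' @return A list with `warm_filling_c` and `cool_filling_c` (NA for sides
#'   without a limit).
#' @export
niche_filling <- function(potential_limits, realized_limits,
                          limits_used = "both") {
  warm <- if (limits_used %in% c("both", "upper_only")) {
    realized_limits$warm - potential_limits$warm
  } else NA_real_
  cool <- if (limits_used %in% c("both", "lower_only")) {
    potential_limits$cool - realized_limits$cool
  } else NA_real_
  list(warm_filling_c = warm, cool_filling_c = cool)
}

#' Range filling
#'
#' The proportion of potential-range cells the species occupies,
#' `|realized intersect potential| / |potential|`; occupied cells outside
#' the potential range (geographic underprediction) are ignored. Defined
#' only for species with both limits whose realized and potential ranges
#' overlap; otherwise NA with the reason flagged by [filling_stats()].
#'
#' @param realized,potential `thermofill_range`s (the potential may be a
#'   `thermofill_potential`).
#' @return Proportion in `[0, 1]`, or NA when the potential is empty or the
#'   ranges do not overlap.
#' @export
range_filling <- function(realized, potential) {
  pot <- if (inherits(potential, "thermofill_potential")) potential$range
         else potential
  if (nrow(pot) == 0) return(NA_real_)
  check_same_spec(realized, pot)
  n_overlap <- sum(realized$cell_id %in% pot$cell_id)
  if (n_overlap == 0) return(NA_real_)
  n_overlap / nrow(pot)
}

#' Equatorward bias of range underfilling
#'
#' Splits the potential range in half latitudinally at the midlatitude of
#' occupied cells, computes the underfilled proportion of each half and
#' returns equatorward minus poleward underfilling. Positive values mean
#' underfilling is concentrated toward the equatorward range edge. Halves
#' are assigned by absolute latitude relative to the absolute split
#' latitude (cells exactly at the split go to the equatorward half), which
#' also gives a deterministic rule for ranges spanning the equator.
#'
#' @param realized,potential `thermofill_range`s.
#' @return Value in `[-1, 1]`, or NA when the ranges do not overlap or one
#'   half of the potential range is empty.
#' @export
equatorward_bias <- function(realized, potential) {
  pot <- if (inherits(potential, "thermofill_potential")) potential$range
         else potential
  if (nrow(pot) == 0 || nrow(realized) == 0) return(NA_real_)
  check_same_spec(realized, pot)
  if (!any(realized$cell_id %in% pot$cell_id)) return(NA_real_)
  split <- abs(latitudinal_midpoint(realized))
  eq_half <- abs(pot$lat) <= split + 1e-9
  n_eq <- sum(eq_half); n_pole <- sum(!eq_half)
  if (n_eq == 0 || n_pole == 0) return(NA_real_)
  occupied <- pot$cell_id %in% realized$cell_id
  underfill_eq <- 1 - sum(occupied[eq_half]) / n_eq
  underfill_pole <- 1 - sum(occupied[!eq_half]) / n_pole
  underfill_eq - underfill_pole
}

#' All filling statistics for one species
#'
#' Computes the four headline statistics (warm and cool niche filling in
#' degC, range filling as a proportion, equatorward bias of range
#' underfilling) plus niche limits, tolerance breadth and exclusion flags.
#'
#' @param realized The realized range (`thermofill_range`).
#' @param potential A `thermofill_potential` from [potential_range()].
#' @param fields The species' `thermofill_bodytemp`.
#' @param species Optional one-row species tibble (adds identifiers and
#'   breadth).
#' @return A one-row tibble (`thermofill_filling`).
#' @export
filling_stats <- function(realized, potential, fields, species = NULL) {
  limits_used <- potential$limits_used
  pot_rng <- potential$range
  real_lim <- niche_limits(realized, fields)
  pot_lim <- if (nrow(pot_rng) > 0) niche_limits(pot_rng, fields) else
    list(warm = NA_real_, cool = NA_real_, coverage = NA_real_,
         n_covered = 0L)
  no_climate <- real_lim$n_covered == 0L
  fill <- if (no_climate) list(warm_filling_c = NA_real_,
                               cool_filling_c = NA_real_) else
    niche_filling(pot_lim, real_lim, limits_used)
  both <- limits_used == "both"
  rf <- if (both && !no_climate) range_filling(realized, pot_rng) else NA_real_
  n_overlap <- sum(realized$cell_id %in% pot_rng$cell_id)
  no_overlap <- both && (n_overlap == 0 || nrow(pot_rng) == 0)
  bias <- if (both && !no_climate) equatorward_bias(realized, pot_rng) else
    NA_real_
  breadth <- if (!is.null(species) && both) {
    species$upper_limit_c - species$lower_limit_c
  } else NA_real_
  tibble::tibble(
    species_id = potential$species_id,
    limits_used = limits_used,
    potential_warm_c = if (limits_used != "lower_only") pot_lim$warm else NA_real_,
    potential_cool_c = if (limits_used != "upper_only") pot_lim$cool else NA_real_,
    realized_warm_c = real_lim$warm,
    realized_cool_c = real_lim$cool,
    warm_filling_c = fill$warm_filling_c,
    cool_filling_c = fill$cool_filling_c,
    range_filling = rf,
    equatorward_bias = bias,
    breadth_c = breadth,
    n_potential = nrow(pot_rng),
    n_realized = nrow(realized),
    n_overlap = n_overlap,
    realized_coverage = real_lim$coverage,
    flag_no_climate = no_climate,
    flag_no_overlap = no_overlap,
    flag_one_limit = !both,
    flag_empty_potential = nrow(pot_rng) == 0
  )
}
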