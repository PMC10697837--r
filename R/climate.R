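#' Configuration for a synthetic climatology
#'
#' The synthetic climate has three nested structures: a latitudinal gradient
#' in the annual mean, a seasonal (monthly) cycle whose amplitude grows with
#' absolute latitude (the tropics are more seasonally stable), and a diurnal
#' cycle on land (ocean diurnal amplitude is zero). Monthly mean air
#' temperature at a cell is
#' `t_eq_air - lapse_air * |lat| + A(|lat|) * cos(2*pi*(month - peak)/12) + noise`
#' with `A(|lat|) = amp0_air + amp_lat_air * |lat|` and a hemisphere-dependent
#' peak month (July in the north, January in the south). Sea-surface
#' temperature follows the same form with its own, flatter parameters and a
#' freezing floor. Annual extremes are the extreme monthly means plus/minus
#' half the diurnal amplitude; hourly profiles on the hottest and coldest
#' days are sinusoidal around the extreme months' means.
#'
#' Acclimation temperatures emulate the temperature an organism experienced
#' shortly before each annual extreme (the week before the hottest day, the
#' seven weeks before the coldest day). They are emitted directly as the
#' extreme minus/plus a configurable offset, because only the resulting
#' acclimation temperature enters the plasticity analysis.
#'
#' @param t_eq_air,lapse_air Equatorial annual-mean air temperature (degC)
#'   and its decline per degree of absolute latitude.
#' @param amp0_air,amp_lat_air Seasonal amplitude of air temperature at the
#'   equator (degC) and its growth per degree latitude.
#' @param diurnal_amp_land Peak-to-trough diurnal air range on land (degC).
#' @param t_eq_sst,lapse_sst,amp0_sst,amp_lat_sst Same for sea surface
#'   temperature.
#' @param sst_floor Freezing floor for SST (degC).
#' @param solar_max Clear-sky solar noon flux at the equator (W m-2); scaled
#'   by `cos(lat)` per cell.
#' @param wind_mean Mean wind speed (m s-1); log-normal scatter across cells.
#' @param rh_mean Mean relative humidity (fraction).
#' @param noise_sd SD of the smooth spatial noise added to temperature
#'   fields (degC); constant across months within a cell.
#' @param acclim_warm_offset,acclim_cool_offset Offsets (degC) between the
#'   annual extreme and the pre-extreme acclimation temperature.
#' @param peak_month_north,peak_month_south Warmest month per hemisphere.
#' @return A list of class `thermofill_climate_config`.
#' @export
climate_config <- function(t_eq_air = 28, lapse_air = 0.6,
                           amp0_air = 2, amp_lat_air = 0.125,
                           diurnal_amp_land = 8,
                           t_eq_sst = 27, lapse_sst = 0.35,
                           amp0_sst = 1, amp_lat_sst = 0.02,
                           sst_floor = -1.8,
                           solar_max = 900, wind_mean = 2, rh_mean = 0.6,
                           noise_sd = 0.5,
                           acclim_warm_offset = 2, acclim_cool_offset = 4,
                           peak_month_north = 7, peak_month_south = 1) {
  structure(as.list(environment()), class = "thermofill_climate_config")
}

#' Simulate a climatology on a world grid
#'
#' @param world A [simulate_world()] grid.
#' @param config A [climate_config()].
#' @param seed Integer seed.
#' @return A `thermofill_climate` object: a list with the grid `spec`, a
#'   `cells` tibble (annual extreme air and sea temperatures, acclimation
#'   temperatures, diurnal amplitude, solar/wind/humidity, warmest and
#'   coldest month per cell per medium) and a `monthly` tibble of monthly
#'   mean air and sea temperature. Hourly profiles for the hottest and
#'   coldest days are derived on demand with [day_profile()].
#' @export
simulate_climate <- function(world, config = climate_config(), seed = 1) {
  stopifnot(inherits(config, "thermofill_climate_config"))
  spec <- spec_of(world)
  withr::with_seed(seed, {
    n <- nrow(world)
    noise <- smooth_noise(spec$n_lat, spec$n_lon)[cbind(world$row, world$col)] *
      config$noise_sd
    noise_sst <- smooth_noise(spec$n_lat, spec$n_lon)[cbind(world$row, world$col)] *
      config$noise_sd * 0.5
    wind <- config$wind_mean * exp(stats::rnorm(n, 0, 0.2))
    rh <- pmin(0.98, pmax(0.05, config$rh_mean + stats::rnorm(n, 0, 0.05)))

    peak <- ifelse(world$lat >= 0, config$peak_month_north,
                   config$peak_month_south)
    amp_air <- config$amp0_air + config$amp_lat_air * abs(world$lat)
    amp_sst <- config$amp0_sst + config$amp_lat_sst * abs(world$lat)
    base_air <- config$t_eq_air - config$lapse_air * abs(world$lat) + noise
    base_sst <- config$t_eq_sst - config$lapse_sst * abs(world$lat) + noise_sst

    monthly <- tidyr::expand_grid(cell_id = world$cell_id, month = 1:12)
    ord <- match(monthly$cell_id, world$cell_id)
    seas <- cos(2 * pi * (monthly$month - peak[ord]) / 12)
    monthly$t_air_c <- base_air[ord] + amp_air[ord] * seas
    monthly$t_sst_c <- ifelse(world$is_ocean[ord],
                              pmax(config$sst_floor,
                                   base_sst[ord] + amp_sst[ord] * seas),
                              NA_real_)

    # warmest/coldest month per cell (ties broken by month index)
    air_m <- matrix(monthly$t_air_c, nrow = 12)  # month x cell
    sst_m <- matrix(monthly$t_sst_c, nrow = 12)
    warm_month <- apply(air_m, 2, which.max)
    cold_month <- apply(air_m, 2, which.min)
    diurnal <- ifelse(world$is_land, config$diurnal_amp_land, 0)

    cells <- tibble::tibble(
      cell_id = world$cell_id, row = world$row, col = world$col,
      lat = world$lat, lon = world$lon, is_land = world$is_land,
      air_warm = air_m[cbind(warm_month, seq_len(n))] + diurnal / 2,
      air_cool = air_m[cbind(cold_month, seq_len(n))] - diurnal / 2,
      sst_warm = suppressWarnings(apply(sst_m, 2, function(v)
        if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))),
      sst_cool = suppressWarnings(apply(sst_m, 2, function(v)
        if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))),
      diurnal_amp_c = diurnal,
      solar_max_wm2 = config$solar_max * pmax(0, cos(world$lat * pi / 180)),
      wind_ms = wind, rh_frac = rh,
      warm_month = warm_month, cold_month = cold_month
    )
    cells$acclim_warm <- ifelse(cells$is_land, cells$air_warm,
                                cells$sst_warm) - config$acclim_warm_offset
    cells$acclim_cool <- ifelse(cells$is_land, cells$air_cool,
                                cells$sst_cool) + config$acclim_cool_offset
    structure(list(spec = spec, cells = cells, monthly = monthly,
                   config = config),
              class = "thermofill_climate")
  })
}

#' @export
print.thermofill_climate <- function(x, ...) {
  cat(sprintf("<climatology on %d x %d grid; %d cells>\n",
              x$spec$n_lat, x$spec$n_lon, nrow(x$cells)))
  invisible(x)
}

#' Hourly air-temperature and solar profile for one day
#'
#' Builds the 24-hour profile of a day in the given month for each requested
#' cell: air temperature is the monthly mean plus a sinusoidal diurnal cycle
#' peaking at 14:00 (amplitude zero over the ocean); solar flux follows a
#' half-sine between 06:00 and 18:00 scaled by the cell's clear-sky maximum.
#'
#' @param climate A [simulate_climate()] object.
#' @param cell_ids Cells to include (default: all).
#' @param month Integer month (default: each cell's warmest month for
#'   `day = "hot"`, coldest for `day = "cold"`). May be a vector with one
#'   month per cell.
#' @param day `"hot"` or `"cold"` (selects the default month).
#' @return Tibble with `cell_id`, `hour` (0-23), `t_air_c`, `solar_wm2`,
#'   `wind_ms`, `rh_frac`.
#' @export
day_profile <- function(climate, cell_ids = NULL, month = NULL,
                        day = c("hot", "cold")) {
  day <- match.arg(day)
  full <- climate$cells
  sel <- if (is.null(cell_ids)) seq_len(nrow(full)) else
    match(cell_ids, full$cell_id)
  if (anyNA(sel)) stop("unknown cell ids in `cell_ids`", call. = FALSE)
  cc <- full[sel, ]
  if (is.null(month)) {
    month <- if (day == "hot") cc$warm_month else cc$cold_month
  }
  month <- rep_len(month, nrow(cc))
  # monthly rows are stored cell-major with month varying fastest
  base <- climate$monthly$t_air_c[(sel - 1L) * 12L + month]
  hours <- 0:23
  out <- tidyr::expand_grid(i = seq_len(nrow(cc)), hour = hours)
  out$cell_id <- cc$cell_id[out$i]
  out$t_air_c <- base[out$i] +
    cc$diurnal_amp_c[out$i] / 2 * cos(2 * pi * (out$hour - 14) / 24)
  out$solar_wm2 <- cc$solar_max_wm2[out$i] *
    pmax(0, sin(pi * (out$hour - 6) / 12))
  out$wind_ms <- cc$wind_ms[out$i]
  out$rh_frac <- cc$rh_frac[out$i]
  out$i <- NULL
  out[c("cell_id", "hour", "t_air_c", "solar_wm2", "wind_ms", "rh_frac")]
}

#' @rdname day_profile
#' @export
hot_day_hourly <- function(climate, cell_ids = NULL) {
  day_profile(climate, cell_ids, day = "hot")
}

#' @rdname day_profile
#' @export
cold_day_hourly <- function(climate, cell_ids = NULL) {
  day_profile(climate, cell_ids, day = "cold")
}
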