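# Independent brute-force implementations (plain loops, no vectorisation)
# used as oracles against the package's vectorised code paths.

oracle_aggregate <- function(fine, factor, mode) {
  nr <- nrow(fine) %/% factor
  nc <- ncol(fine) %/% factor
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      vals <- c()
      for (a in seq_len(factor)) {
        for (b in seq_len(factor)) {
          v <- fine[(i - 1) * factor + a, (j - 1) * factor + b]
          if (!is.na(v)) vals <- c(vals, v)
        }
      }
      if (length(vals)) {
        out[i, j] <- if (mode == "max") max(vals) else min(vals)
      }
    }
  }
  out
}

# Potential-range construction by per-cell loop over the habitat.
# Returns sorted cell ids.
oracle_potential_cells <- function(habitat, fields, species, world) {
  keep <- integer(0)
  for (i in seq_len(nrow(habitat))) {
    id <- habitat$cell_id[i]
    j <- which(fields$cell_id == id)
    if (length(j) == 0) next
    warm <- fields$tbody_warm[j]
    cool <- fields$tbody_cool[j]
    if (is.na(warm) || is.na(cool)) next
    ok <- TRUE
    if (!is.na(species$upper_limit_c) && warm > species$upper_limit_c) {
      ok <- FALSE
    }
    if (!is.na(species$lower_limit_c) && cool < species$lower_limit_c) {
      ok <- FALSE
    }
    k <- which(world$cell_id == id)
    elev <- world$elevation_m[k]
    depth <- world$depth_m[k]
    if (!is.na(species$elevation_min_m) && !is.na(elev) &&
          elev < species$elevation_min_m) ok <- FALSE
    if (!is.na(species$elevation_max_m) && !is.na(elev) &&
          elev > species$elevation_max_m) ok <- FALSE
    if (!is.na(species$depth_min_m) && !is.na(depth) &&
          depth < species$depth_min_m) ok <- FALSE
    if (!is.na(species$depth_max_m) && !is.na(depth) &&
          depth > species$depth_max_m) ok <- FALSE
    if (ok) keep <- c(keep, id)
  }
  sort(keep)
}

oracle_limits <- function(range, fields) {
  warm <- -Inf
  cool <- Inf
  any_cov <- FALSE
  for (i in seq_len(nrow(range))) {
    j <- which(fields$cell_id == range$cell_id[i])
    if (length(j) == 0) next
    w <- fields$tbody_warm[j]; c0 <- fields$tbody_cool[j]
    if (is.na(w) || is.na(c0)) next
    any_cov <- TRUE
    if (w > warm) warm <- w
    if (c0 < cool) cool <- c0
  }
  if (!any_cov) return(c(warm = NA_real_, cool = NA_real_))
  c(warm = warm, cool = cool)
}

oracle_range_filling <- function(realized, potential) {
  if (nrow(potential) == 0) return(NA_real_)
  n_overlap <- 0
  for (i in seq_len(nrow(realized))) {
    if (realized$cell_id[i] %in% potential$cell_id) {
      n_overlap <- n_overlap + 1
    }
  }
  if (n_overlap == 0) return(NA_real_)
  n_overlap / nrow(potential)
}

oracle_bias <- function(realized, potential) {
  if (nrow(potential) == 0 || nrow(realized) == 0) return(NA_real_)
  if (!any(realized$cell_id %in% potential$cell_id)) return(NA_real_)
  split <- abs((max(realized$lat) + min(realized$lat)) / 2)
  n_eq <- n_pole <- occ_eq <- occ_pole <- 0
  for (i in seq_len(nrow(potential))) {
    occ <- potential$cell_id[i] %in% realized$cell_id
    if (abs(potential$lat[i]) <= split + 1e-9) {
      n_eq <- n_eq + 1
      occ_eq <- occ_eq + occ
    } else {
      n_pole <- n_pole + 1
      occ_pole <- occ_pole + occ
    }
  }
  if (n_eq == 0 || n_pole == 0) return(NA_real_)
  (1 - occ_eq / n_eq) - (1 - occ_pole / n_pole)
}

# Per-hour oracle for terrestrial extremes on a few cells
oracle_terrestrial <- function(species, climate, world, params, cell_ids) {
  res <- NULL
  for (id in cell_ids) {
    hot <- day_profile(climate, id, day = "hot")
    cold <- day_profile(climate, id, day = "cold")
    te <- function(row, frac) {
      equilibrium_body_temperature(
        data.frame(t_air_c = row$t_air_c,
                   solar_wm2 = row$solar_wm2 * frac,
                   wind_ms = row$wind_ms, rh_frac = row$rh_frac), params)
    }
    warm_sh <- warm_sun <- -Inf
    cool_sun <- cool_sh <- Inf
    for (h in seq_len(24)) {
      warm_sh <- max(warm_sh, te(hot[h, ], params$shade_solar_fraction))
      warm_sun <- max(warm_sun, te(hot[h, ], 1))
      cool_sun <- min(cool_sun, te(cold[h, ], 1))
      cool_sh <- min(cool_sh, te(cold[h, ], params$shade_solar_fraction))
    }
    res <- rbind(res, data.frame(cell_id = id, tbody_warm = warm_sh,
                                 tbody_cool = cool_sun,
                                 tbody_warm_sun = warm_sun,
                                 tbody_cool_shade = cool_sh))
  }
  res
}
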