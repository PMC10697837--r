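test_that("with no solar load and dry skin the operative temperature is air temperature", {
  grid <- expand.grid(t_air_c = c(-20, 0, 15, 40),
                      wind_ms = c(0.2, 1, 5),
                      mass = c(0.5, 10, 1000))
  for (i in seq_len(nrow(grid))) {
    p <- heat_balance_params(grid$mass[i], skin_wetness = 0)
    te <- equilibrium_body_temperature(
      data.frame(t_air_c = grid$t_air_c[i], solar_wm2 = 0,
                 wind_ms = grid$wind_ms[i], rh_frac = 0.5), p)
    expect_lt(abs(te - grid$t_air_c[i]), 1e-6)
  }
})

test_that("solar load warms the body, more so for larger bodies", {
  p9 <- heat_balance_params(10, absorptance = 0.9, skin_wetness = 0)
  env <- data.frame(t_air_c = 25, solar_wm2 = 800, wind_ms = 1,
                    rh_frac = 0.5)
  expect_gt(equilibrium_body_temperature(env, p9), 25)
  small <- heat_balance_params(1, skin_wetness = 0)
  big <- heat_balance_params(1000, skin_wetness = 0)
  dt_small <- abs(equilibrium_body_temperature(env, small) - 25)
  dt_big <- abs(equilibrium_body_temperature(env, big) - 25)
  expect_gt(dt_big, dt_small)
})

test_that("operative temperature is monotone in air temperature and solar flux", {
  p <- heat_balance_params(20)
  t_grid <- seq(-10, 45, by = 5)
  te_t <- equilibrium_body_temperature(
    data.frame(t_air_c = t_grid, solar_wm2 = 300, wind_ms = 2,
               rh_frac = 0.6), p)
  expect_true(all(diff(te_t) > 0))
  s_grid <- seq(0, 1000, by = 100)
  te_s <- equilibrium_body_temperature(
    data.frame(t_air_c = 20, solar_wm2 = s_grid, wind_ms = 2,
               rh_frac = 0.6), p)
  expect_true(all(diff(te_s) > 0))
})

test_that("the solver drives the energy residual below tolerance", {
  p <- heat_balance_params(35, skin_wetness = 0.2)
  env <- data.frame(t_air_c = c(-5, 18, 33), solar_wm2 = c(0, 450, 900),
                    wind_ms = c(0.5, 2, 6), rh_frac = c(0.3, 0.6, 0.9))
  te <- equilibrium_body_temperature(env, p)
  # recompute the balance by hand
  d <- p$characteristic_dimension_m
  g_h <- 1.4 * 0.135 * sqrt(pmax(env$wind_ms, 0.1) / d)
  g_v <- 1.4 * 0.147 * sqrt(pmax(env$wind_ms, 0.1) / d)
  es <- function(t) 0.611 * exp(17.502 * t / (t + 240.97))
  resid <- p$absorptance * env$solar_wm2 +
    p$emissivity * 5.670374419e-8 * (env$t_air_c + 273.15)^4 -
    p$emissivity * 5.670374419e-8 * (te + 273.15)^4 -
    29.3 * g_h * (te - env$t_air_c) -
    p$skin_wetness * 44000 * g_v * (es(te) - env$rh_frac * es(env$t_air_c)) /
      101.3
  expect_true(all(abs(resid) < 1e-6))
})

test_that("terrestrial extremes equal the per-hour oracle and respect shade identities", {
  w <- small_world()
  cl <- small_climate()
  sp <- tibble::tibble(species_id = "t", realm = "terrestrial",
                       upper_limit_c = 40, lower_limit_c = 0,
                       metric_type = "critical", body_mass_g = 15,
                       dormancy = "none")
  p <- heat_balance_params(15)
  ids <- w$cell_id[w$is_land][c(1, 20, 47)]
  fields <- terrestrial_extremes(sp, cl, w, params = p, cells = ids)
  oracle <- oracle_terrestrial(sp, cl, w, p, ids)
  for (col in c("tbody_warm", "tbody_cool", "tbody_warm_sun",
                "tbody_cool_shade")) {
    expect_equal(fields[[col]], oracle[[col]], tolerance = 1e-8)
  }
  # shaded warm extreme never exceeds the sunny one
  all_fields <- terrestrial_extremes(sp, cl, w, params = p)
  expect_true(all(all_fields$tbody_warm <= all_fields$tbody_warm_sun + 1e-9))
  expect_true(all(all_fields$tbody_warm >= all_fields$tbody_cool))

  # with shade_solar_fraction = 1 shade is no refuge
  p1 <- heat_balance_params(15, shade_solar_fraction = 1)
  f1 <- terrestrial_extremes(sp, cl, w, params = p1, cells = ids)
  expect_equal(f1$tbody_warm, f1$tbody_warm_sun, tolerance = 1e-12)
})

test_that("without diurnal cycle, sun or seasonality both extremes collapse to air temperature", {
  w <- small_world()
  flat <- simulate_climate(w, climate_config(
    diurnal_amp_land = 0, solar_max = 0, amp0_air = 0, amp_lat_air = 0,
    noise_sd = 0), seed = 3)
  sp <- tibble::tibble(species_id = "t", realm = "terrestrial",
                       upper_limit_c = 40, lower_limit_c = 0,
                       metric_type = "critical", body_mass_g = 15,
                       dormancy = "none")
  p <- heat_balance_params(15, skin_wetness = 0)
  f <- terrestrial_extremes(sp, flat, w, params = p)
  air <- flat$cells$air_warm[match(f$cell_id, flat$cells$cell_id)]
  expect_equal(f$tbody_warm, air, tolerance = 1e-6)
  expect_equal(f$tbody_cool, air, tolerance = 1e-6)
})

test_that("marine extremes use SST offshore and the more extreme medium on coastal cells", {
  w <- small_world()
  cl <- small_climate()
  sub <- tibble::tibble(species_id = "m", realm = "subtidal",
                        upper_limit_c = 30, lower_limit_c = 5,
                        metric_type = "critical", dormancy = "none")
  f <- marine_extremes(sub, cl, w)
  cc <- cl$cells[match(f$cell_id, cl$cells$cell_id), ]
  expect_equal(f$tbody_warm, cc$sst_warm, tolerance = 1e-9)
  expect_equal(f$tbody_cool, cc$sst_cool, tolerance = 1e-9)
  expect_equal(nrow(f), sum(w$is_ocean))

  # forced coastal example: air (35, -5) vs sea (28, 4) -> (35, -5)
  cl2 <- cl
  target <- w$cell_id[w$is_coastal_ocean][1]
  sel <- which(cl2$monthly$cell_id == target)
  cl2$monthly$t_air_c[sel] <- rep(c(-5, 35), each = 6)
  cl2$monthly$t_sst_c[sel] <- rep(c(4, 28), each = 6)
  int <- tibble::tibble(species_id = "i", realm = "intertidal",
                        upper_limit_c = 40, lower_limit_c = -10,
                        metric_type = "critical", dormancy = "none")
  fi <- marine_extremes(int, cl2, w)
  j <- which(fi$cell_id == target)
  expect_equal(fi$tbody_warm[j], 35)
  expect_equal(fi$tbody_cool[j], -5)
  expect_equal(fi$medium[j], "both")

  # full coastal band equals the per-cell month-scan oracle
  fi <- marine_extremes(int, cl, w)
  for (j in seq_len(min(nrow(fi), 25))) {
    id <- fi$cell_id[j]
    m <- cl$monthly[cl$monthly$cell_id == id, ]
    is_oc <- w$is_ocean[w$cell_id == id]
    half_d <- cl$cells$diurnal_amp_c[cl$cells$cell_id == id] / 2
    aw <- max(m$t_air_c) + half_d
    ac <- min(m$t_air_c) - half_d
    if (is_oc) {
      expect_equal(fi$tbody_warm[j], max(aw, max(m$t_sst_c)),
                   tolerance = 1e-9)
      expect_equal(fi$tbody_cool[j], min(ac, min(m$t_sst_c)),
                   tolerance = 1e-9)
    } else {
      expect_equal(fi$tbody_warm[j], aw, tolerance = 1e-9)
      expect_equal(fi$tbody_cool[j], ac, tolerance = 1e-9)
    }
  }
})

test_that("dormancy masking is an identity for non-dormant species and idempotent otherwise", {
  w <- small_world()
  cl <- small_climate()
  p <- heat_balance_params(15)
  base <- tibble::tibble(species_id = "d", realm = "terrestrial",
                         upper_limit_c = 45, lower_limit_c = -20,
                         metric_type = "critical", body_mass_g = 15,
                         dormancy = "none")
  f0 <- body_temperatures(base, cl, w, params = p)
  expect_identical(apply_dormancy_mask(f0, base, cl, w, params = p), f0)

  for (dorm in c("summer", "winter", "both")) {
    sp <- base
    sp$dormancy <- dorm
    f1 <- apply_dormancy_mask(f0, sp, cl, w, params = p)
    f2 <- apply_dormancy_mask(f1, sp, cl, w, params = p)
    expect_equal(f1$tbody_warm, f2$tbody_warm, tolerance = 1e-9)
    expect_equal(f1$tbody_cool, f2$tbody_cool, tolerance = 1e-9)
    # masking only cools warm extremes and warms cool extremes
    expect_true(all(f1$tbody_warm <= f0$tbody_warm + 1e-9))
    expect_true(all(f1$tbody_cool >= f0$tbody_cool - 1e-9))
    if (dorm %in% c("summer", "both")) {
      expect_true(any(f1$tbody_warm < f0$tbody_warm - 1e-6))
    } else {
      expect_equal(f1$tbody_warm, f0$tbody_warm, tolerance = 1e-12)
    }
  }
})

test_that("winter dormancy masks the six coldest months per the sinusoidal closed form", {
  w <- small_world()
  cl0 <- simulate_climate(w, climate_config(noise_sd = 0), seed = 6)
  sp <- tibble::tibble(species_id = "d", realm = "terrestrial",
                       upper_limit_c = 45, lower_limit_c = -20,
                       metric_type = "critical", body_mass_g = 15,
                       dormancy = "winter")
  p <- heat_balance_params(15, skin_wetness = 0)
  f0 <- body_temperatures(sp, cl0, w, params = p, apply_dormancy = FALSE)
  f1 <- apply_dormancy_mask(f0, sp, cl0, w, params = p)
  # after excluding the 6 coldest months the coldest active month sits at
  # the zero phase of the seasonal cosine: cool extreme = annual mean - D/2
  # (night-time, no sun, dry skin -> operative = air temperature)
  cfg <- cl0$config
  expected <- cfg$t_eq_air - cfg$lapse_air * abs(f1$lat) -
    cfg$diurnal_amp_land / 2
  expect_equal(f1$tbody_cool, expected, tolerance = 1e-6)
  amp <- cfg$amp0_air + cfg$amp_lat_air * abs(f1$lat)
  expect_equal(f0$tbody_cool, expected - amp, tolerance = 1e-6)

  # no seasonality: all months tie and masking changes nothing
  flat <- simulate_climate(w, climate_config(amp0_air = 0, amp_lat_air = 0,
                                             amp0_sst = 0, amp_lat_sst = 0),
                           seed = 6)
  g0 <- body_temperatures(sp, flat, w, params = p, apply_dormancy = FALSE)
  g1 <- apply_dormancy_mask(g0, sp, flat, w, params = p)
  expect_equal(g1$tbody_cool, g0$tbody_cool, tolerance = 1e-9)
  expect_equal(g1$tbody_warm, g0$tbody_warm, tolerance = 1e-9)
})

test_that("species without body mass cannot be modelled and are reported as such", {
  expect_error(heat_balance_params(NA_real_),
               class = "thermofill_missing_trait")
  sp <- tibble::tibble(species_id = "x", realm = "terrestrial",
                       upper_limit_c = 30, lower_limit_c = 0,
                       metric_type = "critical", body_mass_g = NA_real_,
                       dormancy = "none")
  expect_error(body_temperatures(sp, small_climate(), small_world()),
               class = "thermofill_missing_trait")
})
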