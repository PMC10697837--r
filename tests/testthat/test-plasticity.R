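test_that("zero ARR reproduces the assay limits everywhere", {
  cl <- small_climate()
  sp <- tibble::tibble(species_id = "a", realm = "terrestrial",
                       upper_limit_c = 34, lower_limit_c = 1,
                       metric_type = "critical",
                       arr_upper = 0, arr_lower = 0,
                       assay_acclimation_c = 22)
  lim <- acclimatize_limits(sp, cl)
  expect_true(all(lim$upper_limit_c == 34))
  expect_true(all(lim$lower_limit_c == 1))
})

test_that("acclimatized limits follow the linear ARR formula per cell", {
  cl <- small_climate()
  sp <- tibble::tibble(species_id = "a", realm = "terrestrial",
                       upper_limit_c = 34, lower_limit_c = 1,
                       metric_type = "critical",
                       arr_upper = 0.2, arr_lower = 0.35,
                       assay_acclimation_c = 25)
  lim <- acclimatize_limits(sp, cl)
  # forced example: a cell whose acclimation temperature is 30 C raises the
  # upper limit by 0.2 * (30 - 25) = 1.0 C
  idx <- which.min(abs(cl$cells$acclim_warm - 30))
  if (abs(cl$cells$acclim_warm[idx] - 30) < 2) {
    expect_equal(lim$upper_limit_c[idx],
                 34 + 0.2 * (cl$cells$acclim_warm[idx] - 25))
  }
  # enumeration oracle over the full grid
  for (i in seq(1, nrow(lim), by = 37)) {
    expect_equal(lim$upper_limit_c[i],
                 34 + 0.2 * (cl$cells$acclim_warm[i] - 25))
    expect_equal(lim$lower_limit_c[i],
                 1 + 0.35 * (cl$cells$acclim_cool[i] - 25))
  }
  sp_bad <- sp
  sp_bad$assay_acclimation_c <- NA_real_
  expect_error(acclimatize_limits(sp_bad, cl), "assay")
})

test_that("ARR fallbacks go species -> class -> realm and fail loudly otherwise", {
  cl <- small_climate()
  sp <- tibble::tibble(species_id = "a", realm = "terrestrial",
                       class = "Amphibia",
                       upper_limit_c = 34, lower_limit_c = 1,
                       arr_upper = NA_real_, arr_lower = NA_real_,
                       assay_acclimation_c = 20)
  fb <- list(class = tibble::tibble(class = "Amphibia", arr_upper = 0.1,
                                    arr_lower = 0.2),
             realm = tibble::tibble(realm = "terrestrial", arr_upper = 0.3,
                                    arr_lower = 0.4))
  expect_equal(resolve_arr(sp, fb)$source, "class")
  expect_equal(resolve_arr(sp, fb)$arr_upper, 0.1)
  fb$class <- NULL
  expect_equal(resolve_arr(sp, fb)$source, "realm")
  expect_error(resolve_arr(sp, NULL), class = "thermofill_missing_trait")
})

test_that("zero ARR leaves the potential range and filling bit-identical", {
  toy <- make_toy_strip()
  sp <- toy$species
  sp$arr_upper <- 0
  sp$arr_lower <- 0
  fake_climate <- list(cells = tibble::tibble(
    cell_id = toy$fields$cell_id,
    acclim_warm = toy$fields$tbody_warm - 2,
    acclim_cool = toy$fields$tbody_cool + 4))
  lim <- acclimatize_limits(sp, fake_climate)
  pot_acc <- thermal_clip(toy$habitat, toy$fields, sp, limits_grid = lim)
  expect_identical(pot_acc$range$cell_id, toy$potential$range$cell_id)
  st0 <- filling_stats(toy$realized$interior, toy$potential, toy$fields,
                       toy$species)
  st1 <- filling_stats(toy$realized$interior, pot_acc, toy$fields, sp)
  for (col in c("warm_filling_c", "cool_filling_c", "range_filling",
                "equatorward_bias")) {
    expect_identical(st0[[col]], st1[[col]])
  }
})

test_that("warm-edge acclimatization extends the toy potential per the hand solve", {
  toy <- make_toy_strip()
  sp <- toy$species
  sp$arr_upper <- 0.5
  sp$arr_lower <- 0
  fake_climate <- list(cells = tibble::tibble(
    cell_id = toy$fields$cell_id,
    acclim_warm = toy$fields$tbody_warm - 2,
    acclim_cool = toy$fields$tbody_cool + 4))
  lim <- acclimatize_limits(sp, fake_climate)
  pot_acc <- thermal_clip(toy$habitat, toy$fields, sp, limits_grid = lim)
  # upper(cell) = 37 + 0.5 * ((40 - lat - 2) - 20) = 46 - lat / 2, which
  # exceeds tbody_warm = 40 - lat everywhere, so only the cold edge clips:
  # retained cells are lats 0.5..7.5
  expect_equal(sort(pot_acc$range$lat), seq(0.5, 7.5))
  expect_true(all(toy$potential$range$cell_id %in% pot_acc$range$cell_id))
})

test_that("behavioural thermoregulation clamps toward the preferred temperature", {
  w <- small_world()
  cl <- small_climate()
  spec <- attr(w, "spec")
  sp <- tibble::tibble(species_id = "b", realm = "terrestrial",
                       upper_limit_c = 40, lower_limit_c = 0,
                       metric_type = "critical", body_mass_g = 12,
                       dormancy = "none", t_pref_c = NA_real_)
  land <- w[w$is_land, ]
  occ <- range_from_cells(land[1:3, ], spec, "b")
  p <- heat_balance_params(12)
  hot <- day_profile(cl, occ$cell_id, day = "hot")
  te_sh <- equilibrium_body_temperature(
    transform(hot, solar_wm2 = solar_wm2 * p$shade_solar_fraction), p)
  te_sun <- equilibrium_body_temperature(hot, p)

  expect_error(behavioural_realized_warm_limit(sp, occ, cl, w, params = p),
               class = "thermofill_missing_trait")

  # preferred temperature attainable every hour -> limit equals t_pref
  sp$t_pref_c <- mean(c(max(pmin(te_sh, te_sun)), min(pmax(te_sh, te_sun))))
  if (sp$t_pref_c > max(pmin(te_sh, te_sun))) {
    lim <- behavioural_realized_warm_limit(sp, occ, cl, w, params = p)
    expect_equal(as.numeric(lim), sp$t_pref_c)
  }

  # cold-preferring species: behaves like the all-shade main analysis
  sp$t_pref_c <- min(te_sh, te_sun) - 5
  lim_cold <- behavioural_realized_warm_limit(sp, occ, cl, w, params = p)
  expect_equal(as.numeric(lim_cold), max(pmin(te_sh, te_sun)),
               tolerance = 1e-9)

  # brute-force clamp oracle over cells x hours, plus the bounds invariant
  sp$t_pref_c <- 28
  lim_mid <- behavioural_realized_warm_limit(sp, occ, cl, w, params = p)
  achieved <- numeric(0)
  for (i in seq_along(te_sh)) {
    lo <- min(te_sh[i], te_sun[i]); hi <- max(te_sh[i], te_sun[i])
    achieved <- c(achieved, min(max(28, lo), hi))
  }
  expect_equal(as.numeric(lim_mid), max(achieved), tolerance = 1e-9)
  expect_lte(as.numeric(lim_mid), max(te_sun) + 1e-9)
  expect_gte(as.numeric(lim_mid), max(pmin(te_sh, te_sun)) - 1e-9)

  marine <- tibble::tibble(species_id = "m", realm = "subtidal",
                           t_pref_c = 20)
  expect_error(behavioural_realized_warm_limit(marine, occ, cl, w),
               "terrestrial")
})
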