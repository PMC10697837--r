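test_that("encounterable habitat follows the realm rules", {
  w <- small_world()
  spec <- attr(w, "spec")
  sub <- tibble::tibble(species_id = "m", realm = "subtidal")
  expect_equal(nrow(encounterable_habitat(sub, w)), sum(w$is_ocean))

  int <- tibble::tibble(species_id = "i", realm = "intertidal")
  expect_equal(nrow(encounterable_habitat(int, w)),
               sum(w$is_coastal_land | w$is_coastal_ocean))

  terr <- tibble::tibble(species_id = "t", realm = "terrestrial")
  realms <- setdiff(unique(w$realm_id), 0)
  r1 <- realms[1]
  occupied <- range_from_cells(w[w$realm_id == r1, ][1:3, ], spec, "t")
  hab <- encounterable_habitat(terr, w, occupied)
  expect_setequal(hab$cell_id, w$cell_id[w$realm_id == r1])
  # a range straddling two realms gets their union, each realm in full
  if (length(realms) >= 2) {
    r2 <- realms[2]
    strad <- range_from_cells(
      rbind(w[w$realm_id == r1, ][1:2, ], w[w$realm_id == r2, ][1:2, ]),
      spec, "t")
    hab2 <- encounterable_habitat(terr, w, strad)
    expect_setequal(hab2$cell_id, w$cell_id[w$realm_id %in% c(r1, r2)])
  }
  ocean_only <- range_from_cells(w[w$is_ocean, ][1:2, ], spec, "t")
  expect_error(encounterable_habitat(terr, w, ocean_only),
               class = "thermofill_empty_habitat")
})

test_that("thermal clipping retains exactly the tolerable cells of the toy strip", {
  toy <- make_toy_strip()
  expect_equal(sort(toy$potential$range$lat), seq(3.5, 7.5))
  expect_equal(toy$potential$limits_used, "both")

  up_only <- toy$species
  up_only$lower_limit_c <- NA_real_
  p_up <- thermal_clip(toy$habitat, toy$fields, up_only)
  expect_equal(sort(p_up$range$lat), seq(3.5, 9.5))
  expect_equal(p_up$limits_used, "upper_only")

  # infinite sentinels are a no-op clip
  wide <- toy$species
  wide$upper_limit_c <- Inf
  wide$lower_limit_c <- -Inf
  p_wide <- thermal_clip(toy$habitat, toy$fields, wide)
  expect_setequal(p_wide$range$cell_id, toy$habitat$cell_id)

  # two-limit potential is contained in each one-limit potential
  low_only <- toy$species
  low_only$upper_limit_c <- NA_real_
  p_low <- thermal_clip(toy$habitat, toy$fields, low_only)
  expect_true(all(toy$potential$range$cell_id %in% p_up$range$cell_id))
  expect_true(all(toy$potential$range$cell_id %in% p_low$range$cell_id))
})

test_that("every removed cell is logged exactly once with its reason", {
  toy <- make_toy_strip()
  fields <- toy$fields
  fields$tbody_warm[fields$lat == 4.5] <- NA_real_
  fields$tbody_cool[fields$lat == 4.5] <- NA_real_
  pot <- thermal_clip(toy$habitat, fields, toy$species)
  log <- pot$restriction_log
  expect_equal(sort(c(pot$range$cell_id, log$cell_id)),
               sort(toy$habitat$cell_id))
  expect_equal(anyDuplicated(log$cell_id), 0)
  expect_equal(log$reason[log$lat == 4.5], "no_climate")
  expect_true(all(log$reason[log$lat < 3] == "too_hot"))
  expect_true(all(log$reason[log$lat > 8] == "too_cold"))
})

test_that("depth and elevation bounds filter cells like a per-cell scan", {
  w <- small_world()
  spec <- attr(w, "spec")
  rng <- range_from_cells(w, spec, "x")
  no_bounds <- tibble::tibble(species_id = "x",
                              elevation_min_m = NA_real_,
                              elevation_max_m = NA_real_,
                              depth_min_m = NA_real_, depth_max_m = NA_real_)
  expect_equal(nrow(depth_elevation_correct(rng, no_bounds, w)), nrow(rng))

  hi_cell <- w$cell_id[which.max(w$elevation_m)]
  capped <- no_bounds
  capped$elevation_min_m <- 0
  capped$elevation_max_m <- max(w$elevation_m, na.rm = TRUE) - 1
  out <- depth_elevation_correct(rng, capped, w)
  expect_false(hi_cell %in% out$cell_id)

  withr::with_seed(31, {
    for (i in 1:5) {
      sp <- tibble::tibble(
        species_id = "x",
        upper_limit_c = 50, lower_limit_c = -50,
        elevation_min_m = sample(c(NA, runif(1, 0, 200)), 1),
        elevation_max_m = sample(c(NA, runif(1, 500, 2500)), 1),
        depth_min_m = sample(c(NA, runif(1, 0, 500)), 1),
        depth_max_m = sample(c(NA, runif(1, 1000, 4000)), 1))
      got <- depth_elevation_correct(rng, sp, w)
      keep <- vapply(seq_len(nrow(rng)), function(j) {
        k <- which(w$cell_id == rng$cell_id[j])
        elev <- w$elevation_m[k]; depth <- w$depth_m[k]
        !((!is.na(sp$elevation_min_m) && !is.na(elev) &&
             elev < sp$elevation_min_m) ||
            (!is.na(sp$elevation_max_m) && !is.na(elev) &&
               elev > sp$elevation_max_m) ||
            (!is.na(sp$depth_min_m) && !is.na(depth) &&
               depth < sp$depth_min_m) ||
            (!is.na(sp$depth_max_m) && !is.na(depth) &&
               depth > sp$depth_max_m))
      }, logical(1))
      expect_setequal(got$cell_id, rng$cell_id[keep])
    }
  })

  inv <- no_bounds
  inv$elevation_min_m <- 1000
  inv$elevation_max_m <- 10
  expect_error(depth_elevation_correct(rng, inv, w), "inverted")
})

test_that("habitat restriction, clipping and correction commute", {
  w <- small_world()
  cl <- small_climate()
  sp <- tibble::tibble(species_id = "c", realm = "terrestrial",
                       upper_limit_c = 32, lower_limit_c = 2,
                       metric_type = "critical", body_mass_g = 12,
                       dormancy = "none",
                       elevation_min_m = 0, elevation_max_m = 900,
                       depth_min_m = NA_real_, depth_max_m = NA_real_)
  hab <- realm_habitat(w, setdiff(unique(w$realm_id), 0)[1])
  fields <- body_temperatures(sp, cl, w, cells = hab$cell_id)
  a <- depth_elevation_correct(thermal_clip(hab, fields, sp), sp, w)
  b <- thermal_clip(depth_elevation_correct(hab, sp, w), fields, sp)
  expect_setequal(a$range$cell_id, b$range$cell_id)
})

test_that("strict flood-fill contiguity is a subset of realm membership", {
  w <- small_world()
  spec <- attr(w, "spec")
  terr <- tibble::tibble(species_id = "t", realm = "terrestrial")
  r1 <- setdiff(unique(w$realm_id), 0)[1]
  occupied <- range_from_cells(w[w$realm_id == r1, ][1:3, ], spec, "t")
  hab_realm <- encounterable_habitat(terr, w, occupied)
  hab_flood <- encounterable_habitat(terr, w, occupied, contiguity = "flood")
  expect_true(all(hab_flood$cell_id %in% hab_realm$cell_id))
  expect_true(all(occupied$cell_id %in% hab_flood$cell_id))
})
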