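# Synthetic filling table with known linear structure
make_trend_table <- function(n = 300, slope = -0.1, sigma = 0.5,
                             realm = "terrestrial", seed = 77) {
  withr::with_seed(seed, {
    tibble::tibble(
      species_id = sprintf("s%03d", seq_len(n)),
      realm = realm,
      abs_lat_mid = stats::runif(n, 0, 60),
      dispersal_km = sample(c(0.1, 1, 10, 100), n, replace = TRUE),
      body_mass_g = exp(stats::rnorm(n, 2, 1)),
      range_size_cells = sample(20:400, n, replace = TRUE),
      metric_type = sample(c("critical", "lethal"), n, replace = TRUE),
      warm_filling_c = slope * abs_lat_mid + stats::rnorm(n, 0, sigma),
      cool_filling_c = stats::rnorm(n, 0, sigma),
      range_filling = stats::runif(n, 0.05, 1),
      equatorward_bias = stats::runif(n, -0.2, 0.2),
      breadth_c = 22 + 0.25 * abs_lat_mid + stats::rnorm(n, 0, 0.001),
      class = sample(c("Reptilia", "Amphibia"), n, replace = TRUE))
  })
}

test_that("a known latitudinal slope is recovered within three standard errors", {
  tab <- make_trend_table(n = 300, slope = -0.1, sigma = 0.5)
  fit <- fit_filling_trend(tab, "warm")
  sl <- fit$realm_slopes
  expect_equal(nrow(sl), 1)
  expect_lt(abs(sl$slope - (-0.1)), 3 * sl$std.error)
  expect_equal(fit$backend, "lm")
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(all(c("term", "estimate", "p.value") %in% names(tidy(fit))))
  expect_equal(glance(fit)$n, fit$n)
})

test_that("a constant response yields zero slopes", {
  tab <- make_trend_table(n = 80)
  tab$warm_filling_c <- -1.5
  fit <- suppressWarnings(fit_filling_trend(tab, "warm"))
  expect_equal(fit$realm_slopes$slope, 0, tolerance = 1e-9)
  non_int <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
  expect_equal(non_int$estimate, rep(0, nrow(non_int)), tolerance = 1e-9)
})

test_that("duplicated covariates raise a rank-deficiency error naming the terms", {
  tab <- make_trend_table(n = 100)
  tab$dispersal_km2 <- tab$dispersal_km
  expect_error(
    fit_filling_trend(tab, "warm",
                      covariates = c("dispersal_km", "dispersal_km2")),
    "aliased")
})

test_that("range filling is log-transformed with zero rows excluded and counted", {
  tab <- make_trend_table(n = 120)
  tab$range_filling[1:5] <- 0
  fit <- fit_filling_trend(tab, "range")
  expect_equal(fit$n_zero_excluded, 5L)
  expect_equal(fit$n, 115)
  # the range-size covariate is dropped for this response
  expect_false(any(grepl("log_range_size", fit$coefficients$term)))
})

test_that("breadth relationships recover generator truth per realm", {
  terr <- make_trend_table(n = 150, seed = 11)
  mar <- make_trend_table(n = 80, realm = "subtidal", seed = 12)
  mar$breadth_c <- 12 + withr::with_seed(13, 0.01 * stats::rnorm(80))
  tab <- dplyr::bind_rows(terr, mar)
  fits <- suppressWarnings(fit_breadth_relationships(tab))
  sl <- fits$breadth_lat$realm_slopes
  expect_equal(sl$slope[sl$realm == "terrestrial"], 0.25, tolerance = 1e-3)
  mar_sl <- sl[sl$realm == "subtidal", ]
  expect_lt(abs(mar_sl$slope), 3 * mar_sl$std.error + 1e-3)

  single <- suppressWarnings(fit_breadth_relationships(terr))
  expect_equal(nrow(single$breadth_lat$realm_slopes), 1)

  few <- dplyr::bind_rows(terr, mar[1:2, ])
  expect_warning(fit_breadth_relationships(few), "omitting")
})

test_that("scenario signatures discriminate the two hypotheses", {
  perfect <- make_trend_table(n = 200, slope = 0, sigma = 0)
  perfect$warm_filling_c <- 0
  perfect$equatorward_bias <- 0
  sig_p <- scenario_signature(perfect)
  expect_equal(sig_p$warm_slope, 0)
  expect_equal(sig_p$mean_bias, 0)
  expect_equal(sig_p$signature, "no_signal")

  tt <- make_trend_table(n = 200, slope = -0.08, sigma = 0.3, seed = 5)
  tt$equatorward_bias <- 0.004 * tt$abs_lat_mid +
    withr::with_seed(6, stats::rnorm(200, 0, 0.02))
  sig_tt <- scenario_signature(list(tt = tt))
  expect_equal(sig_tt$signature, "temperate_tradeoff")
  expect_lt(sig_tt$warm_slope, 0)
  expect_gt(sig_tt$bias_slope, 0)
})

test_that("collinear covariates are flagged by the variance-inflation report", {
  tab <- make_trend_table(n = 150, seed = 21)
  tab$body_mass_g <- exp(tab$abs_lat_mid / 10 +
                           withr::with_seed(22, stats::rnorm(150, 0, 0.05)))
  fit <- fit_filling_trend(tab, "warm")
  v <- fit$diagnostics$vif
  expect_false(is.null(v))
  expect_true(any(v$flagged))
})

test_that("true coefficients fall inside 99% intervals in nearly all replicates", {
  hits <- 0
  for (r in 1:100) {
    tab <- make_trend_table(n = 200, slope = -0.1, sigma = 1, seed = 1000 + r)
    fit <- fit_filling_trend(tab, "warm")
    sl <- fit$realm_slopes
    ci <- sl$slope + c(-1, 1) * stats::qnorm(0.995) * sl$std.error
    if (ci[1] <= -0.1 && -0.1 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("taxonomic random intercepts are used when requested", {
  tab <- make_trend_table(n = 200, seed = 31)
  withr::with_seed(32, {
    tab$order <- paste0(tab$class, "_o", sample(1:2, 200, replace = TRUE))
    tab$family <- paste0(tab$order, "_f1")
    tab$genus <- paste0(tab$family, "_g", sample(1:3, 200, replace = TRUE))
  })
  fit <- fit_filling_trend(tab, "warm", random_effects = TRUE)
  expect_true(fit$backend %in% c("lmer", "lm"))
  expect_equal(nrow(fit$realm_slopes), 1)
})
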