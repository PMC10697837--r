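response_column <- c(warm = "warm_filling_c", cool = "cool_filling_c",
                     range = "range_filling", bias = "equatorward_bias")

#' Fit a latitudinal trend model to a niche-filling response
#'
#' Linear model of a filling statistic on realm, absolute latitudinal
#' midpoint of the realized range (with a realm-by-latitude interaction),
#' dispersal distance, log body mass, log realized range size, and thermal
#' limit metric type. Range filling is log-transformed before fitting and,
#' because of the circularity between range size and geographic range
#' filling, the range-size covariate is dropped for that response;
#' zero-proportion rows cannot be log-transformed and are excluded and
#' counted. Metric type is dropped automatically when it is aliased with
#' realm; any other rank deficiency is an error naming the aliased terms.
#' Only complete-case rows are modelled.
#'
#' @param data Filling table: one row per species with columns `realm`,
#'   `abs_lat_mid`, `dispersal_km`, `body_mass_g`, `range_size_cells`,
#'   `metric_type` and the response column (`warm_filling_c`,
#'   `cool_filling_c`, `range_filling` or `equatorward_bias`).
#' @param response `"warm"`, `"cool"`, `"range"` or `"bias"`.
#' @param covariates Trait covariates to include.
#' @param random_effects Fit nested taxonomic random intercepts
#'   (class/order/family/genus) with `lme4` when available; otherwise plain
#'   least squares. The backend actually used is recorded in the fit.
#' @param min_n Minimum complete-case rows; below this the fit is refused.
#' @return A `thermofill_trend` object; see [tidy.thermofill_trend()].
#' @export
fit_filling_trend <- function(data,
                              response = c("warm", "cool", "range", "bias"),
                              covariates = c("dispersal_km", "log_body_mass",
                                             "log_range_size", "metric_type"),
                              random_effects = FALSE, min_n = 10) {
  response <- match.arg(response)
  ycol <- response_column[[response]]
  check_columns(data, c("realm", "abs_lat_mid", ycol), "filling table")
  df <- tibble::as_tibble(data)
  n_zero_excluded <- 0L
  if (response == "range") {
    covariates <- setdiff(covariates, "log_range_size")
    n_zero_excluded <- sum(!is.na(df[[ycol]]) & df[[ycol]] == 0)
    df <- df[is.na(df[[ycol]]) | df[[ycol]] > 0, ]
    df$.y <- log(df[[ycol]])
  } else {
    df$.y <- df[[ycol]]
  }
  if ("log_body_mass" %in% covariates) df$log_body_mass <- log(df$body_mass_g)
  if ("log_range_size" %in% covariates) {
    df$log_range_size <- log(df$range_size_cells)
  }
  covariates <- intersect(covariates, names(df))
  keep <- stats::complete.cases(df[c(".y", "realm", "abs_lat_mid",
                                     covariates)])
  df <- df[keep, ]
  if (nrow(df) < min_n) {
    stop(sprintf("only %d complete-case rows (minimum %d); refusing to fit",
                 nrow(df), min_n), call. = FALSE)
  }
  df$realm <- factor(df$realm)
  multi_realm <- nlevels(df$realm) > 1
  if ("metric_type" %in% covariates && length(unique(df$metric_type)) < 2) {
    covariates <- setdiff(covariates, "metric_type")
  }
  rhs <- c(if (multi_realm) "realm * abs_lat_mid" else "abs_lat_mid",
           covariates)
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- stats::lm(form, data = df)
  aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  if (length(aliased) && multi_realm && "metric_type" %in% covariates &&
      all(grepl("metric_type", aliased))) {
    covariates <- setdiff(covariates, "metric_type")
    rhs <- c("realm * abs_lat_mid", covariates)
    form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
    fit <- stats::lm(form, data = df)
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
  }
  if (length(aliased)) {
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  backend <- "lm"
  if (random_effects && requireNamespace("lme4", quietly = TRUE) &&
      all(c("class", "order", "family", "genus") %in% names(df))) {
    reform <- stats::as.formula(
      paste(".y ~", paste(rhs, collapse = " + "),
            "+ (1 | class/order/family/genus)"))
    fit_re <- tryCatch(
      lme4::lmer(reform, data = df, REML = TRUE),
      error = function(e) NULL)
    if (!is.null(fit_re)) {
      fit <- fit_re
      backend <- "lmer"
    }
  }
  new_trend(fit, df, response = response, slope_var = "abs_lat_mid",
            backend = backend, n_zero_excluded = n_zero_excluded)
}

coef_table <- function(fit, backend) {
  sm <- if (backend == "lmer") {
    as.data.frame(summary(fit)$coefficients)
  } else {
    as.data.frame(summary(fit)$coefficients)
  }
  out <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1],
    std.error = sm[, 2],
    statistic = sm[, 3],
    p.value = if (ncol(sm) >= 4) sm[, ncol(sm)] else NA_real_)
  out
}

# Per-realm slope of the response against `slope_var`: the main-effect
# coefficient plus the realm interaction, with SE from the covariance.
realm_slope_table <- function(fit, df, slope_var, backend) {
  cf <- if (backend == "lmer") lme4::fixef(fit) else stats::coef(fit)
  V <- as.matrix(stats::vcov(fit))
  realms <- if (is.factor(df$realm)) levels(df$realm) else "all"
  n_fit <- nrow(df)
  res_df <- if (backend == "lmer") Inf else fit$df.residual
  out <- lapply(realms, function(r) {
    w <- stats::setNames(numeric(length(cf)), names(cf))
    if (!slope_var %in% names(cf)) return(NULL)
    w[slope_var] <- 1
    for (nm in c(paste0("realm", r, ":", slope_var),
                 paste0(slope_var, ":realm", r))) {
      if (nm %in% names(cf)) w[nm] <- 1
    }
    est <- sum(w * cf)
    se <- sqrt(drop(t(w) %*% V %*% w))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), df = res_df)
    tibble::tibble(realm = r, slope = est, std.error = se,
                   statistic = tval, p.value = p,
                   n = if (length(realms) > 1) sum(df$realm == r) else n_fit)
  })
  dplyr::bind_rows(out)
}

vif_report <- function(df, slope_var) {
  candidates <- c("realm", slope_var, "dispersal_km", "log_body_mass",
                  "log_range_size", "metric_type")
  main <- intersect(candidates, names(df))
  if ("realm" %in% main &&
      (!is.factor(df$realm) || nlevels(df$realm) < 2)) {
    main <- setdiff(main, "realm")
  }
  if ("metric_type" %in% main && length(unique(df$metric_type)) < 2) {
    main <- setdiff(main, "metric_type")
  }
  if (length(main) < 2) return(NULL)
  form <- stats::as.formula(paste(".y ~", paste(main, collapse = " + ")))
  v <- tryCatch(car::vif(stats::lm(form, data = df)), error = function(e) NULL)
  if (is.null(v)) return(NULL)
  if (is.matrix(v)) {
    tibble::tibble(term = rownames(v), gvif = v[, 1], df = v[, 2],
                   gvif_adj = v[, 3], flagged = v[, 3]^2 > 3)
  } else {
    tibble::tibble(term = names(v), gvif = unname(v), df = 1,
                   gvif_adj = sqrt(unname(v)), flagged = unname(v) > 3)
  }
}

new_trend <- function(fit, df, response, slope_var, backend,
                      n_zero_excluded = 0L) {
  resid_p <- if (nrow(df) >= 3 && nrow(df) <= 5000) {
    r <- stats::residuals(fit)
    if (stats::sd(r) > 0) stats::shapiro.test(r)$p.value else NA_real_
  } else NA_real_
  structure(
    list(response = response, slope_var = slope_var,
         model = fit, backend = backend,
         coefficients = coef_table(fit, backend),
         realm_slopes = realm_slope_table(fit, df, slope_var, backend),
         n = nrow(df), n_zero_excluded = n_zero_excluded,
         diagnostics = list(residual_normality_p = resid_p,
                            vif = vif_report(df, slope_var)),
         data = df),
    class = "thermofill_trend")
}

#' @export
print.thermofill_trend <- function(x, ...) {
  cat(sprintf("<trend fit: %s (~ %s), backend %s, n = %d>\n",
              x$response, x$slope_var, x$backend, x$n))
  print(x$realm_slopes)
  invisible(x)
}

#' Tidy a trend fit
#'
#' @param x A `thermofill_trend`.
#' @param ... Unused.
#' @return Tibble of coefficients (term, estimate, std.error, statistic,
#'   p.value).
#' @method tidy thermofill_trend
#' @export
#' @importFrom generics tidy
tidy.thermofill_trend <- function(x, ...) x$coefficients

#' One-row summary of a trend fit
#'
#' @param x A `thermofill_trend`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @method glance thermofill_trend
#' @export
#' @importFrom generics glance
glance.thermofill_trend <- function(x, ...) {
  s <- if (x$backend == "lm") summary(x$model) else NULL
  tibble::tibble(
    response = x$response, backend = x$backend, n = x$n,
    r.squared = if (!is.null(s)) s$r.squared else NA_real_,
    adj.r.squared = if (!is.null(s)) s$adj.r.squared else NA_real_,
    sigma = if (!is.null(s)) s$sigma else stats::sigma(x$model),
    n_zero_excluded = x$n_zero_excluded,
    residual_normality_p = x$diagnostics$residual_normality_p)
}

#' Per-realm breadth and filling relationships
#'
#' Fits, for species with both tolerance limits, (1) thermal tolerance
#' breadth (upper minus lower limit, degC) against absolute latitudinal
#' midpoint, and (2) warm niche filling against tolerance breadth, with
#' slope and intercept varying between realms. Realms with fewer than
#' `min_per_realm` two-limit species are omitted with a warning.
#'
#' @param data Filling table (see [fit_filling_trend()]) with `breadth_c`.
#' @param min_per_realm Minimum two-limit species per realm.
#' @return A list with `thermofill_trend` elements `breadth_lat` and
#'   `filling_breadth`.
#' @export
fit_breadth_relationships <- function(data, min_per_realm = 3) {
  check_columns(data, c("realm", "abs_lat_mid", "breadth_c",
                        "warm_filling_c"), "filling table")
  df <- tibble::as_tibble(data)
  df <- df[!is.na(df$breadth_c) & !is.na(df$abs_lat_mid), ]
  counts <- table(df$realm)
  drop <- names(counts)[counts < min_per_realm]
  if (length(drop)) {
    warning("omitting realm(s) with < ", min_per_realm,
            " two-limit species: ", paste(drop, collapse = ", "),
            call. = FALSE)
    df <- df[!df$realm %in% drop, ]
  }
  if (nrow(df) < min_per_realm) {
    stop("too few two-limit species to fit breadth relationships",
         call. = FALSE)
  }
  df$realm <- factor(df$realm)
  multi <- nlevels(df$realm) > 1
  fit_one <- function(y, x) {
    d <- df
    d$.y <- d[[y]]
    form <- if (multi) {
      stats::as.formula(paste(".y ~ realm *", x))
    } else {
      stats::as.formula(paste(".y ~", x))
    }
    d2 <- d[stats::complete.cases(d[c(".y", x)]), ]
    new_trend(stats::lm(form, data = d2), d2, response = y, slope_var = x,
              backend = "lm")
  }
  list(breadth_lat = fit_one("breadth_c", "abs_lat_mid"),
       filling_breadth = fit_one("warm_filling_c", "breadth_c"))
}

#' Hypothesis signature of scenario runs
#'
#' Summarises, for each filling table, the three quantities that
#' discriminate the competing range-limitation hypotheses: the slope of
#' warm niche filling against absolute latitudinal midpoint, the slope of
#' equatorward bias against absolute latitudinal midpoint, and the mean
#' equatorward bias. A temperate-trade-off world shows a negative warm
#' filling slope with a positive bias slope; a
#' reduced-abiotic-limitation world shows a positive warm filling slope
#' (less underfilling at high latitude) with near-zero mean bias.
#'
#' @param tables A filling table or named list of filling tables (one per
#'   scenario run).
#' @param alpha Significance level used for the signature label.
#' @return A tibble with one row per table: slopes, p-values, mean bias and
#'   a `signature` label.
#' @export
scenario_signature <- function(tables, alpha = 0.01) {
  if (is.data.frame(tables)) tables <- list(run = tables)
  out <- purrr::imap(tables, function(tab, nm) {
    slope_p <- function(y) {
      d <- tab[stats::complete.cases(tab[c(y, "abs_lat_mid")]), ]
      if (nrow(d) < 3 || stats::sd(d[[y]]) == 0) {
        return(c(slope = 0, p = 1))
      }
      f <- stats::lm(d[[y]] ~ d$abs_lat_mid)
      sm <- summary(f)$coefficients
      c(slope = sm[2, 1], p = sm[2, 4])
    }
    w <- slope_p("warm_filling_c")
    b <- slope_p("equatorward_bias")
    mean_bias <- mean(tab$equatorward_bias, na.rm = TRUE)
    signature <- if (w["slope"] < 0 && w["p"] < alpha &&
                       b["slope"] > 0 && b["p"] < alpha) {
      "temperate_tradeoff"
    } else if (w["slope"] > 0 && w["p"] < alpha && abs(mean_bias) < 0.05) {
      "reduced_abiotic"
    } else if (w["p"] >= alpha && b["p"] >= alpha) {
      "no_signal"
    } else {
      "mixed"
    }
    tibble::tibble(scenario = nm, n = nrow(tab),
                   warm_slope = unname(w["slope"]), warm_p = unname(w["p"]),
                   bias_slope = unname(b["slope"]), bias_p = unname(b["p"]),
                   mean_bias = mean_bias, signature = signature)
  })
  dplyr::bind_rows(out)
}
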