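#' Map a synthetic world
#'
#' Tile map of surface type (ocean, coastal bands) with terrestrial realms
#' coloured.
#'
#' @param object A `thermofill_world`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thermofill_world
#' @export
autoplot.thermofill_world <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$surface <- dplyr::case_when(
    df$is_coastal_land ~ "coastal land",
    df$is_land ~ paste("realm", df$realm_id),
    df$is_coastal_ocean ~ "coastal ocean",
    .default = "ocean")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$surface)) +
    ggplot2::geom_raster() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Map realized versus potential range of one species
#'
#' @param world The world grid (background).
#' @param potential A `thermofill_potential` or `thermofill_range`.
#' @param realized The realized `thermofill_range`.
#' @return A ggplot object.
#' @export
plot_range_map <- function(world, potential, realized) {
  pot <- if (inherits(potential, "thermofill_potential")) potential$range
         else potential
  df <- tibble::as_tibble(world)
  df$status <- dplyr::case_when(
    df$cell_id %in% pot$cell_id & df$cell_id %in% realized$cell_id ~
      "occupied potential",
    df$cell_id %in% pot$cell_id ~ "underfilled potential",
    df$cell_id %in% realized$cell_id ~ "occupied beyond potential",
    df$is_land ~ "land",
    .default = "ocean")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat,
                                   fill = .data$status)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(
      "occupied potential" = "#2c7fb8",
      "underfilled potential" = "#fdae61",
      "occupied beyond potential" = "#d7191c",
      "land" = "grey85", "ocean" = "grey97")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Niche filling versus latitude, by realm
#'
#' Scatter of a filling statistic against the absolute latitudinal
#' midpoint with per-realm least-squares lines — the standard way to read
#' the latitudinal signal of a scenario run.
#'
#' @param object A filling table (e.g. `run$filling`).
#' @param response Column to plot (default warm filling).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_filling_latitude <- function(object, response = "warm_filling_c", ...) {
  df <- object[!is.na(object[[response]]) & !is.na(object$abs_lat_mid), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$abs_lat_mid,
                                   y = .data[[response]],
                                   colour = .data$realm)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Absolute latitudinal midpoint (deg)",
                  y = response, colour = "Realm") +
    ggplot2::theme_minimal()
}

#' Coefficient plot of a trend fit
#'
#' @param object A `thermofill_trend`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot thermofill_trend
#' @export
autoplot.thermofill_trend <- function(object, ...) {
  cf <- object$coefficients
  cf <- cf[cf$term != "(Intercept)", ]
  ggplot2::ggplot(cf, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - 1.96 * .data$std.error,
                   xmax = .data$estimate + 1.96 * .data$std.error),
      height = 0.2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Estimate (95% CI)", y = NULL,
                  title = paste("Trend fit:", object$response)) +
    ggplot2::theme_minimal()
}
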