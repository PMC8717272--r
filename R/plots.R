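#' Density plot of the estimate cube
#'
#' One density panel per tip-based metric, pooling all (species, phylogeny,
#' simulation) records; a quick view of the distribution and spread of TR,
#' ST and LT.
#'
#' @param object An `estimate_cube`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.estimate_cube <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("tr", "st", "lt"),
                              names_to = "metric", values_to = "value")
  long$metric <- factor(toupper(long$metric), levels = c("TR", "ST", "LT"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_density(fill = "grey80", colour = "grey20") +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "metric value (TR unitless; ST, LT in Ma)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Map per-point assemblage metrics
#'
#' Points colored by the across-estimate mean (or SD) of one assemblage
#' metric, in projected km.
#'
#' @param summary Output of [uncertainty_summary()].
#' @param points The point sample (for coordinates).
#' @param metric `"atr"`, `"ast"` or `"alt"`.
#' @param stat `"mean"` or `"sd"`.
#' @return A ggplot object.
#' @export
plot_assemblage_map <- function(summary, points, metric = c("atr", "ast", "alt"),
                                stat = c("mean", "sd")) {
  metric <- match.arg(metric)
  stat <- match.arg(stat)
  col <- paste0(metric, "_", stat)
  df <- dplyr::inner_join(summary, points[c("point_id", "x", "y", "position")],
                          by = "point_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data[[col]],
                                   shape = .data$position)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::coord_equal() +
    ggplot2::scale_colour_viridis_c(name = toupper(col)) +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
}

#' Plot a landscape and optional range polygons
#'
#' @param landscape A `landscape`.
#' @param ranges Optional range tibble (see [synthetic_ranges()]).
#' @return A ggplot object.
#' @export
plot_landscape <- function(landscape, ranges = NULL) {
  eco <- landscape$ecoregions
  poly_df <- purrr::map2_dfr(eco$polygon, eco$ecoregion, function(p, id) {
    tibble::tibble(x = p[, 1L], y = p[, 2L], ecoregion = id)
  })
  poly_df <- dplyr::left_join(poly_df, eco[c("ecoregion", "habitat")],
                              by = "ecoregion")
  g <- ggplot2::ggplot(poly_df,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    group = .data$ecoregion,
                                    fill = .data$habitat)) +
    ggplot2::geom_polygon(colour = "grey30", alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(forest = "darkgreen",
                                          open = "wheat")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)") +
    ggplot2::theme_minimal()
  if (!is.null(ranges)) {
    rng_df <- purrr::map2_dfr(ranges$polygon, ranges$species,
                              function(p, id) {
                                tibble::tibble(x = p[, 1L], y = p[, 2L],
                                               species = id)
                              })
    g <- g + ggplot2::geom_polygon(
      data = rng_df,
      ggplot2::aes(x = .data$x, y = .data$y, group = .data$species),
      inherit.aes = FALSE, fill = NA, colour = "steelblue", linewidth = 0.3
    )
  }
  g
}

#' Heatmap of fitted Mk transition rates
#'
#' @param object An `mk_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mk_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$to, y = .data$from,
                                   fill = .data$rate)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = signif(.data$rate, 3)),
                       colour = "white") +
    ggplot2::scale_fill_viridis_c(name = "rate (per Ma)") +
    ggplot2::labs(x = "to state", y = "from state",
                  title = paste0("Mk ", object$model, " fit (AIC ",
                                 round(object$AIC, 2), ")")) +
    ggplot2::theme_minimal()
}
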