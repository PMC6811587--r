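#' Plot a Lorenz curve with its tangent construction
#'
#' Shows the sorted cumulative outflow distribution, the equality diagonal,
#' and the tangent at (1, 1) whose x-intercept is the hotspot threshold.
#'
#' @param object A `lorenz_curve` from [lorenz_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lorenz_curve <- function(object, ...) {
  n <- nrow(object) - 1
  slope <- (object$f[n + 1] - object$f[n]) * n
  ggplot2::ggplot(object, ggplot2::aes(.data$p, .data$f)) +
    ggplot2::geom_abline(slope = 1, intercept = 0,
                         linetype = "dotted", colour = "grey50") +
    ggplot2::geom_abline(slope = slope, intercept = 1 - slope,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_line(linewidth = 0.8, colour = "steelblue") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "cumulative fraction of cells",
                  y = "cumulative fraction of outflow") +
    ggplot2::theme_minimal()
}

#' Heatmap of a level-flow matrix
#'
#' Displays the normalized share of trips between each pair of hotspot
#' levels, with level 1 (most active) in the top-left corner; the
#' tri-diagonal band summed by the flow-hierarchy is outlined.
#'
#' @param object A `level_flow_matrix` from [level_flow_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.level_flow_matrix <- function(object, ...) {
  L <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(L), j = seq_len(L)) |>
    dplyr::mutate(share = as.numeric(object)[(.data$j - 1) * L + .data$i],
                  on_band = abs(.data$i - .data$j) <= 1)
  ggplot2::ggplot(df, ggplot2::aes(.data$j, .data$i, fill = .data$share)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(
      data = dplyr::filter(df, .data$on_band),
      fill = NA, colour = "goldenrod", linewidth = 0.7
    ) +
    ggplot2::scale_y_reverse(breaks = seq_len(L)) +
    ggplot2::scale_x_continuous(breaks = seq_len(L), position = "top") +
    ggplot2::scale_fill_viridis_c(name = "trip share") +
    ggplot2::labs(x = "destination level", y = "origin level") +
    ggplot2::theme_minimal()
}

#' Plot a hierarchy response curve
#'
#' Mean flow-hierarchy (with one-standard-deviation ribbon) as a function
#' of the center scattering of the synthetic city.
#'
#' @param object A `hierarchy_response` from [hierarchy_response_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hierarchy_response <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$spread, .data$mean_phi)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_phi - .data$sd_phi,
                   ymax = .data$mean_phi + .data$sd_phi),
      fill = "steelblue", alpha = 0.2
    ) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "center spread (km)", y = "mean flow-hierarchy") +
    ggplot2::theme_minimal()
}

#' Scatter plot of an indicator against the flow-hierarchy
#'
#' Points plus the LOESS fit used for the explained-variance measure,
#' annotated with the three R-squared values and significance stars.
#'
#' @param object A `correlation_result` from [correlate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  grid <- tibble::tibble(
    phi = seq(min(object$data$phi), max(object$data$phi), length.out = 200)
  )
  grid$value <- stats::predict(object$loess_fit,
                               newdata = data.frame(x = grid$phi))
  lab <- sprintf("R2P = %.2f, R2S = %.2f, R2L = %.2f %s",
                 object$r2_pearson, object$r2_spearman,
                 object$r2_loess, strrep("*", object$stars))
  ggplot2::ggplot(object$data, ggplot2::aes(.data$phi, .data$value)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(x = "flow-hierarchy", y = object$indicator,
                  subtitle = lab) +
    ggplot2::theme_minimal()
}
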