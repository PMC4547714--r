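# ggplot2 graphics for curves, models and comparisons.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

curves_long <- function(curves) {
  purrr::map(curves, tibble::as_tibble) |>
    dplyr::bind_rows(.id = "curve_id")
}

#' Plot a population of normalized curves
#'
#' Sagittal (Y vs Z) and coronal (X vs Z) views, one line per curve.
#'
#' @param curves a list of [normalized_curve()] objects.
#' @return A ggplot.
#' @export
plot_curves <- function(curves) {
  df <- curves_long(curves) |>
    tidyr::pivot_longer(c("x", "y"), names_to = "axis") |>
    dplyr::mutate(view = ifelse(.data$axis == "y", "sagittal (Y, ventral+)",
                                "coronal (X, right+)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$z,
                                   group = .data$curve_id)) +
    ggplot2::geom_path(alpha = 0.25, linewidth = 0.3) +
    ggplot2::facet_wrap(~view, scales = "free_x") +
    ggplot2::labs(x = "dimensionless offset", y = "Z (caudal 0 - cranial 1)") +
    ggplot2::theme_minimal()
}

#' Plot a population model curve
#'
#' Median curve with a pointwise +/- 1 SD band, sagittal and coronal views.
#'
#' @param object a [build_model()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.population_model <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("median_x", "median_y"), names_to = "axis",
                        values_to = "median") |>
    dplyr::mutate(sd = ifelse(.data$axis == "median_y", object$sd_y[
                    match(.data$station, object$station)],
                    object$sd_x[match(.data$station, object$station)]),
                  view = ifelse(.data$axis == "median_y",
                                "sagittal (Y, ventral+)",
                                "coronal (X, right+)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$median, .data$z)) +
    ggplot2::geom_ribbon(ggplot2::aes(xmin = .data$median - .data$sd,
                                      xmax = .data$median + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_path(linewidth = 0.7) +
    ggplot2::facet_wrap(~view, scales = "free_x") +
    ggplot2::labs(title = paste0("model '", attr(object, "label"),
                                 "' (n = ", attr(object, "n"), ")"),
                  x = "dimensionless offset",
                  y = "Z (caudal 0 - cranial 1)") +
    ggplot2::theme_minimal()
}

#' Plot a pointwise two-group comparison
#'
#' Group means per station with significant locations marked.
#'
#' @param object a [compare_pointwise()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.pointwise_comparison <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("mean_a", "mean_b"), names_to = "group",
                        values_to = "mean") |>
    dplyr::mutate(view = ifelse(.data$axis == "y", "sagittal (Y)",
                                "coronal (X)"))
  sig <- dplyr::filter(tibble::as_tibble(object), .data$p < alpha)
  sig <- tidyr::pivot_longer(sig, c("mean_a", "mean_b"), names_to = "group",
                             values_to = "mean") |>
    dplyr::mutate(view = ifelse(.data$axis == "y", "sagittal (Y)",
                                "coronal (X)"))
  ggplot2::ggplot(df, ggplot2::aes(.data$mean, .data$z,
                                   color = .data$group)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = sig, shape = 15, size = 2) +
    ggplot2::facet_wrap(~view, scales = "free_x") +
    ggplot2::labs(x = "dimensionless offset",
                  y = "Z (caudal 0 - cranial 1)",
                  caption = paste0("squares: p < ", alpha)) +
    ggplot2::theme_minimal()
}
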