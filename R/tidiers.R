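# broom-style tidiers for fitted/report objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a population model
#'
#' @param x a [build_model()] result.
#' @param ... unused.
#' @return A tibble with one row per station and columns `label`, `n`,
#'   `station`, `z`, `median_x`, `median_y`, `sd_x`, `sd_y`.
#' @export
tidy.population_model <- function(x, ...) {
  tibble::as_tibble(x) |>
    dplyr::mutate(label = attr(x, "label"), n = attr(x, "n"),
                  .before = 1)
}

#' Glance at a population model
#'
#' @inheritParams tidy.population_model
#' @return A one-row tibble with `label`, `n`, `stations`,
#'   `peak_location`, `peak_height`.
#' @export
glance.population_model <- function(x, ...) {
  pk <- model_peak_location(x)
  tibble::tibble(label = attr(x, "label"), n = attr(x, "n"),
                 stations = nrow(x), peak_location = pk,
                 peak_height = max(x$median_y))
}

#' Tidy a comparison report
#'
#' @param x a [compare_models()] result.
#' @param type `"pointwise"` (default) or `"features"`.
#' @param ... unused.
#' @return The requested comparison table as a tibble.
#' @export
tidy.comparison_report <- function(x, type = c("pointwise", "features"),
                                   ...) {
  type <- match.arg(type)
  if (type == "features") tibble::as_tibble(x$feature_tests)
  else tibble::as_tibble(x$pointwise)
}

#' Glance at a comparison report
#'
#' @inheritParams tidy.comparison_report
#' @return A one-row tibble with group sizes, alpha, and the number of
#'   significant locations per axis and significant descriptors.
#' @export
glance.comparison_report <- function(x, ...) {
  tibble::tibble(
    label_a = x$labels[1], label_b = x$labels[2],
    n_a = x$n_a, n_b = x$n_b, alpha = x$alpha,
    sig_locations_y = count_significant(
      dplyr::filter(x$pointwise, .data$axis == "y"), x$alpha),
    sig_locations_x = count_significant(
      dplyr::filter(x$pointwise, .data$axis == "x"), x$alpha),
    sig_features = sum(x$feature_tests$p < x$alpha)
  )
}
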