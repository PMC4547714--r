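# Six shape descriptors of a normalized lumbar curve.

#' Compute the six curve descriptors
#'
#' From a [normalized_curve()] computes: segment length (mm; straight
#' distance between endpoints A and B), curve length (mm; distance along the
#' curve), curvedness (curve length divided by the projected cranial-caudal
#' extent Az - Bz; 1 for a straight chord), lordosis peak location (Z of the
#' most ventral point P, measured from the caudal endpoint), and the cranial
#' (Py - Ay) and caudal (Py - By) peak heights. The four shape descriptors
#' are dimensionless; the two lengths are in mm, recovered through the
#' recorded `scale_mm`.
#'
#' If several samples attain the maximal Y within 1e-9, the median index of
#' the maximal set is used (stable on flat-topped curves). A peak on an
#' endpoint triggers a degenerate-peak warning; descriptors are still
#' returned.
#'
#' @param norm a [normalized_curve()].
#' @return A one-row tibble with columns `segment_length_mm`,
#'   `curve_length_mm`, `curvedness`, `peak_location`,
#'   `cranial_peak_height`, `caudal_peak_height`, `peak_x`, `peak_y`,
#'   `peak_z`.
#' @export
compute_features <- function(norm) {
  if (!is_normalized_curve(norm))
    stop("`norm` must be a normalized_curve", call. = FALSE)
  s <- attr(norm, "scale_mm")
  m <- curve_matrix(norm)
  n <- nrow(m)
  a <- unname(m[n, ])
  b <- unname(m[1, ]) # the origin
  chord <- sqrt(sum((a - b)^2))
  arc <- sum(sqrt(rowSums((m[-1, , drop = FALSE] -
                           m[-n, , drop = FALSE])^2)))
  proj <- a[3] - b[3] # = 1 for a valid normalized curve
  ymax <- max(m[, 2])
  peak_set <- which(m[, 2] >= ymax - 1e-9)
  p_idx <- peak_set[ceiling(length(peak_set) / 2)]
  p <- unname(m[p_idx, ])
  if (p[3] <= 0 || p[3] >= 1)
    warning("degenerate lordosis peak at a curve endpoint", call. = FALSE)
  tibble::new_tibble(list(
    segment_length_mm = chord * s,
    curve_length_mm = arc * s,
    curvedness = arc / proj,
    peak_location = p[3],
    cranial_peak_height = p[2] - a[2],
    caudal_peak_height = p[2] - b[2],
    peak_x = p[1], peak_y = p[2], peak_z = p[3]
  ), nrow = 1L)
}

#' Descriptor features for a population of curves
#'
#' @param curves a list of [normalized_curve()] objects.
#' @return A tibble with one descriptor row per curve and a `curve_id`
#'   column.
#' @export
population_features <- function(curves) {
  rows <- vapply(curves, function(crv) as.numeric(compute_features(crv)),
                 numeric(9))
  out <- as.data.frame(t(rows))
  names(out) <- c(.report_features, "peak_x", "peak_y", "peak_z")
  tibble::new_tibble(c(list(curve_id = seq_along(curves)), out),
                     nrow = length(curves))
}

.report_features <- c("segment_length_mm", "curve_length_mm", "curvedness",
                      "peak_location", "cranial_peak_height",
                      "caudal_peak_height")

#' Summarize descriptors over a group of curves
#'
#' Produces the per-descriptor mean, sample SD, min and max over a group,
#' plus two derived report columns: `pct_from_cranial` for the peak location
#' (`100 * (1 - mean)`, the peak position as a percent of segment length
#' measured from the cranial endpoint) and `mean_mm` for the two peak
#' heights (the dimensionless group mean de-scaled by the group's mean
#' segment length).
#'
#' @param features a tibble of per-curve descriptors (from
#'   [compute_features()] rows or [population_features()]), or a list of
#'   normalized curves.
#' @return A tibble with columns `feature`, `mean`, `sd`, `min`, `max`,
#'   `pct_from_cranial`, `mean_mm`.
#' @export
features_report <- function(features) {
  if (is.list(features) && !is.data.frame(features))
    features <- population_features(features)
  if (nrow(features) < 2L)
    stop("a group report needs at least 2 curves", call. = FALSE)
  seg_mean <- mean(features$segment_length_mm)
  features |>
    dplyr::select(dplyr::all_of(.report_features)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "feature") |>
    dplyr::group_by(feature = factor(.data$feature,
                                     levels = .report_features)) |>
    dplyr::summarise(mean = mean(.data$value), sd = sd(.data$value),
                     min = min(.data$value), max = max(.data$value),
                     .groups = "drop") |>
    dplyr::arrange(.data$feature) |>
    dplyr::mutate(
      feature = as.character(.data$feature),
      pct_from_cranial = ifelse(.data$feature == "peak_location",
                                100 * (1 - .data$mean), NA_real_),
      mean_mm = ifelse(.data$feature %in% c("cranial_peak_height",
                                            "caudal_peak_height"),
                       .data$mean * seg_mean, NA_real_)
    )
}
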