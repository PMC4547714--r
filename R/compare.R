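# Two-population comparison: per-descriptor t-tests and the pointwise
# station comparison on Y (sagittal) and X (coronal).

#' Two-sample t-test from summary statistics
#'
#' Pooled-variance Student t by default (`df = n_a + n_b - 2`), two-tailed;
#' Welch's unequal-variance form with `welch = TRUE`. When both SDs are
#' zero: equal means give `t = 0, p = 1`; unequal means are degenerate and
#' give `p = 0` with infinite t.
#'
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics
#'   (`n >= 2`, `sd >= 0`).
#' @param welch use the Welch unequal-variance test.
#' @return A one-row tibble with `t`, `df`, `p`.
#' @export
two_sample_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                         welch = FALSE) {
  stopifnot(n_a >= 2, n_b >= 2, sd_a >= 0, sd_b >= 0)
  if (sd_a == 0 && sd_b == 0) {
    if (mean_a == mean_b)
      return(tibble::tibble(t = 0, df = n_a + n_b - 2, p = 1))
    return(tibble::tibble(t = sign(mean_a - mean_b) * Inf,
                          df = n_a + n_b - 2, p = 0))
  }
  if (welch) {
    va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  t <- (mean_a - mean_b) / se
  tibble::tibble(t = t, df = df, p = 2 * pt(-abs(t), df))
}

as_feature_table <- function(group) {
  if (is.data.frame(group)) return(group)
  population_features(group)
}

#' Per-descriptor comparison of two groups
#'
#' The six descriptors of each group compared with [two_sample_t()], laid
#' out as a per-feature table of group mean/SD/min/max and p.
#'
#' @param group_a,group_b lists of [normalized_curve()] objects (or
#'   per-curve feature tibbles); at least 2 curves each.
#' @param welch use Welch's test.
#' @return A tibble with one row per descriptor.
#' @export
compare_features <- function(group_a, group_b, welch = FALSE) {
  fa <- as_feature_table(group_a)
  fb <- as_feature_table(group_b)
  if (nrow(fa) < 2 || nrow(fb) < 2)
    stop("each group needs at least 2 curves", call. = FALSE)
  purrr::map_dfr(.report_features, function(f) {
    a <- fa[[f]]; b <- fb[[f]]
    tt <- two_sample_t(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
                       welch = welch)
    tibble::tibble(feature = f,
                   mean_a = mean(a), sd_a = sd(a),
                   min_a = min(a), max_a = max(a),
                   mean_b = mean(b), sd_b = sd(b),
                   min_b = min(b), max_b = max(b),
                   t = tt$t, p = tt$p)
  })
}

#' Pointwise comparison of two curve populations
#'
#' Every curve is resampled at `K` equally spaced Z stations; the most
#' caudal station (the common origin B) is dropped, and at each remaining
#' station the groups' X and Y coordinates are compared with
#' [two_sample_t()]. Rows are ordered cranial first (location 1 is Z = 1).
#' No multiple-testing correction is applied by default: neighboring
#' stations are strongly dependent, for which a Bonferroni-style correction
#' would be inappropriate; `bonferroni = TRUE` applies one anyway and is a
#' documented deviation.
#'
#' @inheritParams compare_features
#' @param K number of stations (the comparison uses `K - 1` locations).
#' @param alpha significance level.
#' @param bonferroni apply a Bonferroni correction across locations.
#' @param dorsal_sign negate reported Y means (dorsal-positive display
#'   convention).
#' @return A tibble of class `pointwise_comparison` with columns `axis`
#'   (`"y"`, `"x"`), `location`, `z`, `mean_a`, `sd_a`, `mean_b`, `sd_b`,
#'   `t`, `p`, and attributes `alpha`, `n_a`, `n_b`, `K`.
#' @export
compare_pointwise <- function(group_a, group_b, K = 20, alpha = 0.05,
                              welch = FALSE, bonferroni = FALSE,
                              dorsal_sign = FALSE) {
  sta <- purrr::map(group_a, resample_stations, K = K)
  stb <- purrr::map(group_b, resample_stations, K = K)
  n_a <- length(sta); n_b <- length(stb)
  grab <- function(st, ax, j) vapply(st, function(s) s[[ax]][j], numeric(1))
  rows <- purrr::map_dfr(c("y", "x"), function(ax) {
    purrr::map_dfr(K:2, function(j) { # cranial (Z = 1) first
      a <- grab(sta, ax, j); b <- grab(stb, ax, j)
      tt <- two_sample_t(mean(a), sd(a), n_a, mean(b), sd(b), n_b,
                         welch = welch)
      tibble::tibble(axis = ax, location = K - j + 1L,
                     z = (j - 1) / (K - 1),
                     mean_a = mean(a), sd_a = sd(a),
                     mean_b = mean(b), sd_b = sd(b),
                     t = tt$t, p = tt$p)
    })
  })
  if (bonferroni) rows$p <- pmin(1, rows$p * (K - 1))
  if (dorsal_sign)
    rows <- dplyr::mutate(rows,
                          mean_a = ifelse(.data$axis == "y", -.data$mean_a,
                                          .data$mean_a),
                          mean_b = ifelse(.data$axis == "y", -.data$mean_b,
                                          .data$mean_b))
  attr(rows, "alpha") <- alpha
  attr(rows, "n_a") <- n_a
  attr(rows, "n_b") <- n_b
  attr(rows, "K") <- K
  class(rows) <- c("pointwise_comparison", class(rows))
  rows
}

#' Count significant locations in a pointwise table
#'
#' @param table a pointwise tibble with a `p` column (optionally filter to
#'   one axis first).
#' @param alpha significance level.
#' @return Number of rows with `p < alpha`.
#' @export
count_significant <- function(table, alpha = 0.05) {
  sum(table$p < alpha, na.rm = TRUE)
}

#' Full two-population comparison report
#'
#' Bundles [compare_features()] and [compare_pointwise()] into one report
#' object with [generics::tidy()] / [generics::glance()] methods.
#'
#' @inheritParams compare_pointwise
#' @param label_a,label_b group labels.
#' @return A list of class `comparison_report` with elements
#'   `feature_tests`, `pointwise`, `alpha`, `n_a`, `n_b`, `labels`.
#' @export
compare_models <- function(group_a, group_b, K = 20, alpha = 0.05,
                           welch = FALSE, dorsal_sign = FALSE,
                           label_a = "A", label_b = "B") {
  la <- attr(group_a, "label"); lb <- attr(group_b, "label")
  if (!is.null(la)) label_a <- la
  if (!is.null(lb)) label_b <- lb
  structure(
    list(feature_tests = compare_features(group_a, group_b, welch = welch),
         pointwise = compare_pointwise(group_a, group_b, K = K,
                                       alpha = alpha, welch = welch,
                                       dorsal_sign = dorsal_sign),
         alpha = alpha,
         n_a = length(group_a), n_b = length(group_b),
         labels = c(label_a, label_b)),
    class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> ", x$labels[1], " (n = ", x$n_a, ") vs ",
      x$labels[2], " (n = ", x$n_b, "), alpha = ", x$alpha, "\n", sep = "")
  ny <- count_significant(dplyr::filter(x$pointwise, .data$axis == "y"),
                          x$alpha)
  nx <- count_significant(dplyr::filter(x$pointwise, .data$axis == "x"),
                          x$alpha)
  cat("significant locations: Y =", ny, " X =", nx, "\n")
  invisible(x)
}

#' Write a comparison report as JSON
#'
#' @param report a [compare_models()] result.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(
    list(labels = report$labels, alpha = report$alpha,
         n_a = report$n_a, n_b = report$n_b,
         feature_tests = as.data.frame(report$feature_tests),
         pointwise_y = as.data.frame(
           dplyr::filter(report$pointwise, .data$axis == "y")),
         pointwise_x = as.data.frame(
           dplyr::filter(report$pointwise, .data$axis == "x"))),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Analytic power of the pooled two-sample t-test
#'
#' Closed-form power from the noncentral t distribution, for group
#' summary statistics at significance `alpha`. Serves as the independent
#' oracle for simulation-based calibration of [compare_features()].
#'
#' @inheritParams two_sample_t
#' @param alpha significance level.
#' @return Probability of rejecting the null of equal means.
#' @export
power_pooled_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           alpha = 0.05) {
  df <- n_a + n_b - 2
  sp <- sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / df)
  ncp <- (mean_a - mean_b) / (sp * sqrt(1 / n_a + 1 / n_b))
  tc <- qt(1 - alpha / 2, df)
  # the noncentral CDF warns about its last digits at large ncp; that
  # precision is far below any tolerance used here
  suppressWarnings(pt(-tc, df, ncp = ncp) + 1 - pt(tc, df, ncp = ncp))
}
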