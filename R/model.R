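# Population curve models: per-station medians and SDs of normalized
# curves, on cross-sections of constant Z.

#' Resample a normalized curve at equally spaced Z stations
#'
#' Stations are `Z = j / (K - 1)`, `j = 0 .. K - 1`. X and Y are obtained by
#' linear interpolation at each station Z after monotone-Z repair: the
#' polyline is parameterized by cumulative arc length and, for each station,
#' the first crossing of that Z is taken (extracted centerlines may locally
#' backtrack in Z). The first and last stations reproduce the endpoints B
#' and A exactly.
#'
#' @param norm a [normalized_curve()] whose Z range covers `[0, 1]`.
#' @param K number of stations (>= 2).
#' @return A tibble with columns `station` (0-based), `z`, `x`, `y`.
#' @export
resample_stations <- function(norm, K = 20) {
  if (!is_normalized_curve(norm))
    stop("`norm` must be a normalized_curve", call. = FALSE)
  if (K < 2) stop("K must be >= 2", call. = FALSE)
  m <- curve_matrix(norm)
  n <- nrow(m)
  if (min(m[, 3]) > 1e-9 || max(m[, 3]) < 1 - 1e-9)
    stop("curve Z range does not cover [0, 1]", call. = FALSE)
  zs <- seq(0, 1, length.out = K)
  xs <- ys <- numeric(K)
  xs[1] <- m[1, 1]; ys[1] <- m[1, 2]
  xs[K] <- m[n, 1]; ys[K] <- m[n, 2]
  if (K > 2) {
    z <- m[, 3]
    for (j in 2:(K - 1)) {
      zj <- zs[j]
      hit <- which(abs(z - zj) < 1e-12)
      if (length(hit) > 0) {
        i <- hit[1]
        xs[j] <- m[i, 1]; ys[j] <- m[i, 2]
      } else {
        cross <- which((z[-n] - zj) * (z[-1] - zj) < 0)
        if (length(cross) == 0)
          stop("no crossing of station Z = ", zj,
               " after monotone-Z repair", call. = FALSE)
        i <- cross[1] # first crossing along arc length
        f <- (zj - z[i]) / (z[i + 1] - z[i])
        xs[j] <- m[i, 1] + f * (m[i + 1, 1] - m[i, 1])
        ys[j] <- m[i, 2] + f * (m[i + 1, 2] - m[i, 2])
      }
    }
  }
  tibble::tibble(station = seq_len(K) - 1L, z = zs, x = xs, y = ys)
}

#' Build a population curve model
#'
#' The model curve is the component-wise (X and Y independently) sample
#' median of all curves on cross-sections of constant Z, with the sample
#' SD (n - 1) of location recorded per station.
#'
#' @param curves a list of [normalized_curve()] objects (>= 2).
#' @param K number of Z stations.
#' @param label optional population label.
#' @return A tibble of class `population_model` with columns `station`,
#'   `z`, `median_x`, `median_y`, `sd_x`, `sd_y` and attributes `n`,
#'   `label`.
#' @export
build_model <- function(curves, K = 100, label = NULL) {
  if (length(curves) < 2)
    stop("a population model needs at least 2 curves", call. = FALSE)
  if (is.null(label)) label <- attr(curves, "label") %||% "population"
  st <- purrr::map(curves, resample_stations, K = K) |>
    dplyr::bind_rows(.id = "curve_id")
  mod <- st |>
    dplyr::group_by(.data$station, .data$z) |>
    dplyr::summarise(median_x = median(.data$x), median_y = median(.data$y),
                     sd_x = sd(.data$x), sd_y = sd(.data$y),
                     .groups = "drop") |>
    dplyr::arrange(.data$station)
  attr(mod, "n") <- length(curves)
  attr(mod, "label") <- label
  class(mod) <- c("population_model", class(mod))
  mod
}

#' Lordosis peak location of a model curve
#'
#' Z of the station maximizing the median Y (median station index on ties
#' within 1e-9).
#'
#' @param model a [build_model()] result.
#' @return A scalar in `[0, 1]`.
#' @export
model_peak_location <- function(model) {
  ymax <- max(model$median_y)
  peak_set <- which(model$median_y >= ymax - 1e-9)
  model$z[peak_set[ceiling(length(peak_set) / 2)]]
}

#' @export
print.population_model <- function(x, ...) {
  cat("<population_model> '", attr(x, "label"), "', n = ", attr(x, "n"),
      ", K = ", nrow(x), " stations\n", sep = "")
  NextMethod()
}

#' Write/read a population model as JSON
#'
#' @param model a [build_model()] result.
#' @param path JSON path.
#' @return `path` invisibly; `read_model()` returns the model tibble.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(label = attr(model, "label"),
                            n = attr(model, "n"),
                            stations = as.data.frame(model)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  mod <- tibble::as_tibble(j$stations)
  attr(mod, "n") <- j$n
  attr(mod, "label") <- j$label
  class(mod) <- c("population_model", class(mod))
  mod
}
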