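#' Construct a 3-D curve
#'
#' A curve is an ordered polyline of 3-D points in patient coordinates (mm),
#' held as a tibble with columns `x`, `y`, `z`.
#'
#' @param x,y,z numeric coordinate vectors of equal length (mm), or `x` may
#'   be a data frame / matrix with three columns.
#' @return A tibble of class `canal_curve` with columns `x`, `y`, `z`.
#' @export
curve3d <- function(x, y = NULL, z = NULL) {
  if (is.matrix(x) || is.data.frame(x)) {
    m <- as.matrix(x)
    if (ncol(m) != 3L) stop("curve needs exactly 3 coordinate columns",
                            call. = FALSE)
    y <- m[, 2]; z <- m[, 3]; x <- m[, 1]
  }
  x <- as.numeric(x); y <- as.numeric(y); z <- as.numeric(z)
  n <- length(x)
  if (length(y) != n || length(z) != n)
    stop("coordinate vectors must have equal length", call. = FALSE)
  if (n < 2L)
    stop("a curve needs at least 2 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)) || any(!is.finite(z)))
    stop("curve coordinates must be finite", call. = FALSE)
  if (any(diff(x)^2 + diff(y)^2 + diff(z)^2 == 0))
    stop("consecutive curve points must be distinct", call. = FALSE)
  tibble::new_tibble(list(x = x, y = y, z = z), nrow = n,
                     class = "canal_curve")
}

curve_matrix <- function(curve) {
  cbind(x = curve$x, y = curve$y, z = curve$z)
}

arc_lengths <- function(curve) {
  c(0, cumsum(sqrt(diff(curve$x)^2 + diff(curve$y)^2 + diff(curve$z)^2)))
}

#' Write a curve to CSV
#'
#' Writes the points at full float precision with header
#' `x_mm,y_mm,z_mm`; [read_curve()] restores them to within 1e-9 mm.
#'
#' @param curve a curve as produced by [curve3d()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  curve <- curve3d(curve)
  lines <- c("x_mm,y_mm,z_mm",
             sprintf("%.17g,%.17g,%.17g", curve$x, curve$y, curve$z))
  writeLines(lines, path)
  invisible(path)
}

#' Read a curve from CSV
#'
#' @param path CSV with header `x_mm,y_mm,z_mm`.
#' @return A [curve3d()] tibble.
#' @export
read_curve <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) < 3L)
    stop("curve file must contain a header and at least 2 points",
         call. = FALSE)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), c("x_mm", "y_mm", "z_mm")))
    stop("malformed curve CSV header (expected x_mm,y_mm,z_mm)",
         call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(body, ",", fixed = TRUE)
  pts <- matrix(NA_real_, length(parts), 3)
  for (i in seq_along(parts)) {
    cells <- trimws(parts[[i]])
    vals <- suppressWarnings(as.numeric(cells))
    if (length(cells) != 3L || any(is.na(vals)))
      stop("malformed curve CSV row at line ", i + 1L, ": '", body[i], "'",
           call. = FALSE)
    pts[i, ] <- vals
  }
  curve3d(pts)
}
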