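#' Construct a normalized (dimensionless) curve
#'
#' A normalized curve lives in the dimensionless common frame: the caudal
#' endpoint B is at the origin, the cranial endpoint A has Z = 1, Y+ is
#' ventral and X+ the subject's right. `scale_mm` records the projected
#' cranial-caudal extent (Az - Bz, in mm) that was divided out, so mm-valued
#' descriptors can be recovered.
#'
#' @param x,y,z dimensionless coordinates (or `x` a 3-column matrix/data
#'   frame).
#' @param scale_mm the projected Z extent of the original curve in mm.
#' @return A tibble of class `normalized_curve` (and `canal_curve`) with
#'   attribute `scale_mm`.
#' @export
normalized_curve <- function(x, y = NULL, z = NULL, scale_mm) {
  crv <- curve3d(x, y, z)
  if (!is.numeric(scale_mm) || length(scale_mm) != 1L || scale_mm <= 0)
    stop("`scale_mm` must be a positive scalar", call. = FALSE)
  b <- as.numeric(crv[1, ])
  a <- as.numeric(crv[nrow(crv), ])
  if (max(abs(b)) > 1e-6)
    stop("caudal endpoint B must sit at the origin", call. = FALSE)
  if (abs(a[3] - 1) > 1e-6)
    stop("cranial endpoint A must have Z = 1", call. = FALSE)
  attr(crv, "scale_mm") <- scale_mm
  class(crv) <- c("normalized_curve", class(crv))
  crv
}

#' @export
print.normalized_curve <- function(x, ...) {
  cat("<normalized_curve> ", nrow(x), " points, scale_mm = ",
      signif(attr(x, "scale_mm"), 5), "\n", sep = "")
  NextMethod()
}

is_normalized_curve <- function(x) inherits(x, "normalized_curve")
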