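# Cropping to the lumbar segment between endplate planes, and
# normalization into the dimensionless common frame.

#' Landmark planes bounding the lumbar segment
#'
#' The two planes through the T12 inferior endplate (cranial bound) and the
#' S1 superior endplate (caudal bound), each given by a point (mm) and a
#' normal. Normals are rescaled to unit length.
#'
#' @param t12_point,t12_normal point and normal of the T12 inferior plane.
#' @param s1_point,s1_normal point and normal of the S1 superior plane.
#' @return A list of class `landmark_planes`.
#' @export
landmark_planes <- function(t12_point, t12_normal, s1_point, s1_normal) {
  unitize <- function(v, nm) {
    v <- as.numeric(v)
    if (length(v) != 3L || any(!is.finite(v)))
      stop("`", nm, "` must be a finite length-3 vector", call. = FALSE)
    if (grepl("normal", nm)) {
      l <- sqrt(sum(v^2))
      if (l == 0) stop("`", nm, "` must be nonzero", call. = FALSE)
      v <- v / l
    }
    v
  }
  structure(list(t12_inferior = list(point = unitize(t12_point, "t12_point"),
                                     normal = unitize(t12_normal, "t12_normal")),
                 s1_superior = list(point = unitize(s1_point, "s1_point"),
                                    normal = unitize(s1_normal, "s1_normal"))),
            class = "landmark_planes")
}

#' Read/write landmark planes as JSON
#'
#' JSON layout:
#' `{"t12_inferior": {"point_mm": [..], "normal": [..]}, "s1_superior": ...}`.
#'
#' @param path JSON file path.
#' @return [landmark_planes()] for `read_landmarks()`; `path` invisibly for
#'   `write_landmarks()`.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(j$t12_inferior) || is.null(j$s1_superior))
    stop("landmarks JSON must contain t12_inferior and s1_superior",
         call. = FALSE)
  landmark_planes(j$t12_inferior$point_mm, j$t12_inferior$normal,
                  j$s1_superior$point_mm, j$s1_superior$normal)
}

#' @rdname read_landmarks
#' @param planes a [landmark_planes()] object.
#' @export
write_landmarks <- function(planes, path) {
  stopifnot(inherits(planes, "landmark_planes"))
  jsonlite::write_json(
    list(t12_inferior = list(point_mm = planes$t12_inferior$point,
                             normal = planes$t12_inferior$normal),
         s1_superior = list(point_mm = planes$s1_superior$point,
                            normal = planes$s1_superior$normal)),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

# signed distances of curve points to a plane
plane_signed <- function(m, plane) {
  sweep(m, 2, plane$point, "-") %*% plane$normal
}

# exact plane-curve intersection; errors unless the crossing is unique
plane_crossing <- function(m, plane, name) {
  s <- drop(plane_signed(m, plane))
  on_plane <- which(abs(s) < 1e-12)
  crossings <- which(s[-length(s)] * s[-1] < 0)
  hits <- length(on_plane) + length(crossings)
  if (hits != 1L)
    stop("landmark error: plane '", name, "' crossed ", hits,
         " times (expected exactly 1)", call. = FALSE)
  if (length(on_plane) == 1L)
    return(list(idx = on_plane, frac = 0, point = m[on_plane, ]))
  i <- crossings
  f <- s[i] / (s[i] - s[i + 1])
  list(idx = i, frac = f, point = m[i, ] + f * (m[i + 1, ] - m[i, ]))
}

#' Crop a centerline to the lumbar segment
#'
#' Returns the sub-curve between the curve's unique intersections with the
#' T12-inferior and S1-superior endplate planes; the exact (linearly
#' interpolated) intersection points become the new endpoints. The output is
#' ordered caudal (B, the S1 crossing) to cranial (A, the T12 crossing).
#'
#' @param curve a [curve3d()] in mm.
#' @param planes a [landmark_planes()].
#' @return A [curve3d()] running B to A.
#' @export
crop_to_landmarks <- function(curve, planes) {
  stopifnot(inherits(planes, "landmark_planes"))
  curve <- curve3d(curve)
  m <- curve_matrix(curve)
  ct <- plane_crossing(m, planes$t12_inferior, "t12_inferior")
  cs <- plane_crossing(m, planes$s1_superior, "s1_superior")
  lo <- if (ct$idx + ct$frac < cs$idx + cs$frac) ct else cs
  hi <- if (identical(lo, ct)) cs else ct
  inner <- if (lo$idx + 1 <= hi$idx) m[seq(lo$idx + 1, hi$idx), , drop = FALSE]
           else m[0, , drop = FALSE]
  pts <- rbind(lo$point, inner, if (hi$frac > 0) hi$point)
  # drop duplicated points introduced by exact-sample intersections
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 1e-20)
  pts <- pts[keep, , drop = FALSE]
  # order caudal -> cranial: the S1 crossing is the caudal endpoint
  if (ct$point[3] < cs$point[3])
    stop("landmark error: T12 crossing is caudal to the S1 crossing",
         call. = FALSE)
  if (pts[1, 3] > pts[nrow(pts), 3]) pts <- pts[nrow(pts):1, , drop = FALSE]
  curve3d(pts)
}

#' Normalize a cropped lumbar curve into the dimensionless common frame
#'
#' Applies, in order: (1) a rotation about the Z axis taking the subject's
#' ventral direction to +Y (identity for volumes already in the internal
#' orientation); (2) a translation putting the caudal endpoint B at the
#' origin; (3) division of all coordinates by the projected cranial-caudal
#' extent Az - Bz, so the cranial endpoint A lands at Z = 1. Shape (ratios
#' of distances) is unchanged; the divisor is recorded as `scale_mm`.
#'
#' @param curve a cropped [curve3d()] ordered caudal to cranial (mm).
#' @param ventral unit vector (XY plane) of the subject's ventral direction
#'   in the curve's coordinates; default `c(0, 1, 0)` (already internal).
#' @return A [normalized_curve()].
#' @export
normalize_curve <- function(curve, ventral = c(0, 1, 0)) {
  orig_scale <- if (is_normalized_curve(curve)) attr(curve, "scale_mm")
  curve <- curve3d(curve)
  m <- curve_matrix(curve)
  n <- nrow(m)
  if (m[n, 3] <= m[1, 3])
    stop("orientation error: cranial endpoint must have Az > Bz",
         call. = FALSE)
  v <- ventral[1:2]
  if (sqrt(sum(v^2)) == 0)
    stop("`ventral` must have a nonzero XY component", call. = FALSE)
  v <- v / sqrt(sum(v^2))
  theta <- atan2(v[1], v[2]) # rotation about Z taking v to (0, 1)
  rot <- rbind(c(cos(theta), -sin(theta), 0),
               c(sin(theta), cos(theta), 0),
               c(0, 0, 1))
  m <- m %*% t(rot)
  b <- m[1, ]
  m <- sweep(m, 2, b, "-")
  scale_mm <- m[n, 3]
  m <- m / scale_mm
  m[n, 3] <- 1 # exact by construction; guard against roundoff
  normalized_curve(m, scale_mm = orig_scale %||% scale_mm)
}
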