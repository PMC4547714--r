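# Canal centerline extraction: endpoint selection, distance-transform
# speed map, fast-marching minimal path, resampling and smoothing.

#' Path endpoints from a canal mask
#'
#' Centroids (mm) of the most caudal and most cranial occupied slices.
#'
#' @param mask a [binary_mask()] spanning at least 10 slices in Z.
#' @return A list with `start` (caudal, mm) and `end` (cranial, mm).
#' @export
endpoints_from_mask <- function(mask) {
  stopifnot(inherits(mask, "canal_mask"))
  occ <- which(apply(mask$data, 3, any))
  if (length(occ) == 0) stop("mask is empty", call. = FALSE)
  if (diff(range(occ)) + 1 < 10)
    stop("mask must span at least 10 slices in Z", call. = FALSE)
  cen <- function(k) {
    ij <- which(mask$data[, , k], arr.ind = TRUE)
    drop(voxel_to_world(mask, c(colMeans(ij), k)))
  }
  list(start = cen(min(occ)), end = cen(max(occ)))
}

#' Centrality speed map for minimal-path extraction
#'
#' Inside the mask the speed equals the Euclidean distance to the mask
#' boundary normalized to (0, 1], so the fastest routes hug the medial axis;
#' outside it is 1e-6, making off-canal travel prohibitively slow.
#'
#' @inheritParams endpoints_from_mask
#' @return A `canal_volume` of speeds on the same grid.
#' @export
speed_map <- function(mask) {
  stopifnot(inherits(mask, "canal_mask"))
  if (!any(mask$data)) stop("mask is empty", call. = FALSE)
  dims <- dim(mask$data)
  d <- cpp_edt3d(as.logical(mask$data), dims, mask$spacing)
  d <- d / max(d)
  d[d <= 0] <- 1e-6
  image_volume(array(d, dims), mask$spacing, mask$origin)
}

world_to_voxel <- function(vol, p) {
  (as.numeric(p) - vol$origin) / vol$spacing + 1
}

#' Fast-marching minimal path between two points
#'
#' Solves the eikonal arrival-time field from `start` over the speed map by
#' first-order fast marching (6-neighbor upwind stencil), then back-traces
#' from `end` by steepest descent on arrival time with sub-voxel steps
#' (0.25 x the smallest spacing). The arrival time strictly decreases along
#' the back-trace; the path cost is minimal in the eikonal sense.
#'
#' @param speed a speed `canal_volume` (see [speed_map()]).
#' @param start,end points in mm inside the speed support.
#' @return A [curve3d()] in mm ordered `start` to `end`, with attribute
#'   `arrival_time` (the eikonal cost of the path).
#' @export
minimal_path <- function(speed, start, end) {
  stopifnot(inherits(speed, "canal_volume"))
  dims <- dim(speed$data)
  sv <- round(world_to_voxel(speed, start))
  ev <- round(world_to_voxel(speed, end))
  if (any(sv < 1) || any(ev < 1) || any(sv > dims) || any(ev > dims))
    stop("start/end outside the grid", call. = FALSE)
  if (all(sv == ev))
    stop("start and end coincide; a path needs two distinct points",
         call. = FALSE)
  if (speed$data[sv[1], sv[2], sv[3]] <= 1e-6 ||
      speed$data[ev[1], ev[2], ev[3]] <= 1e-6)
    stop("start/end must lie inside the speed support", call. = FALSE)
  sidx <- sv[1] + dims[1] * ((sv[2] - 1) + dims[2] * (sv[3] - 1))
  eidx <- ev[1] + dims[1] * ((ev[2] - 1) + dims[2] * (ev[3] - 1))
  tt <- cpp_fast_march(as.numeric(speed$data), dims, speed$spacing,
                       sidx, eidx)
  t_end <- tt[eidx]
  # a connected in-canal route has average slowness far below the outside
  # epsilon; a cost this large means the front crossed off-support space
  chord <- sqrt(sum((as.numeric(end) - as.numeric(start))^2))
  if (!is.finite(t_end) || t_end > chord * 1e4)
    rlang::abort("end point unreachable from start (disconnected support)",
                 class = "canalcurve_no_path")
  bt <- cpp_backtrace(tt, dims, speed$spacing, sv - 1, ev - 1, 0.25, 100000L)
  path_vox <- bt[, 1:3, drop = FALSE]
  pts <- sweep(sweep(path_vox, 2, speed$spacing, "*"), 2, speed$origin, "+")
  pts <- pts[nrow(pts):1, , drop = FALSE] # order start -> end
  times <- rev(bt[, 4])
  keep <- c(TRUE, rowSums((pts[-1, , drop = FALSE] -
                           pts[-nrow(pts), , drop = FALSE])^2) > 1e-20)
  crv <- curve3d(pts[keep, , drop = FALSE])
  attr(crv, "arrival_time") <- t_end
  attr(crv, "path_times") <- times[keep]
  crv
}

#' Resample a curve at uniform arc length and smooth it
#'
#' Arc-length resampling at a uniform `step`, followed by a centered
#' moving average of odd `window`; the endpoints are kept fixed. A window
#' of 1 resamples without smoothing.
#'
#' @param curve a [curve3d()].
#' @param step resampling step, mm (> 0).
#' @param window odd moving-average window (points).
#' @return A [curve3d()].
#' @export
resample_smooth <- function(curve, step = 1, window = 5) {
  curve <- curve3d(curve)
  if (step <= 0) stop("`step` must be positive", call. = FALSE)
  if (window %% 2 != 1 || window < 1)
    stop("`window` must be odd and >= 1", call. = FALSE)
  s <- arc_lengths(curve)
  total <- s[length(s)]
  if (total < 2 * step)
    stop("curve shorter than 2 x step", call. = FALSE)
  n_out <- max(3, ceiling(total / step) + 1)
  si <- seq(0, total, length.out = n_out)
  m <- vapply(c("x", "y", "z"),
              function(cc) approx(s, curve[[cc]], xout = si)$y,
              numeric(n_out))
  if (window > 1) {
    half <- (window - 1) / 2
    pad <- function(v) c(rep(v[1], half), v, rep(v[length(v)], half))
    sm <- apply(m, 2, function(v)
      stats::filter(pad(v), rep(1 / window, window), sides = 2)[
        (half + 1):(half + length(v))])
    sm[1, ] <- m[1, ]
    sm[nrow(sm), ] <- m[nrow(m), ]
    m <- sm
  }
  keep <- c(TRUE, rowSums((m[-1, , drop = FALSE] -
                           m[-nrow(m), , drop = FALSE])^2) > 1e-20)
  curve3d(m[keep, , drop = FALSE])
}

#' Extract the canal centerline from a mask
#'
#' Convenience composition of [endpoints_from_mask()], [speed_map()],
#' [minimal_path()] and [resample_smooth()].
#'
#' @inheritParams endpoints_from_mask
#' @inheritParams resample_smooth
#' @return A [curve3d()] in mm, caudal to cranial.
#' @export
extract_centerline <- function(mask, step = 1, window = 5) {
  ep <- endpoints_from_mask(mask)
  sp <- speed_map(mask)
  path <- minimal_path(sp, ep$start, ep$end)
  resample_smooth(path, step = step, window = window)
}

#' Mean and maximum distance from one curve to another
#'
#' Distances (mm) from each point of `curve` to the polyline `reference`.
#' Used to score extracted centerlines against a known truth.
#'
#' @param curve,reference [curve3d()] objects in the same coordinates.
#' @return A list with `mean` and `max` distance (mm).
#' @export
curve_distance <- function(curve, reference) {
  a <- curve_matrix(curve3d(curve))
  b <- curve_matrix(curve3d(reference))
  segs <- cbind(b[-nrow(b), , drop = FALSE], b[-1, , drop = FALSE])
  d <- vapply(seq_len(nrow(a)), function(i) {
    p <- a[i, ]
    ap <- sweep(segs[, 1:3, drop = FALSE], 2, p, "-")
    ab <- segs[, 4:6, drop = FALSE] - segs[, 1:3, drop = FALSE]
    tt <- pmin(pmax(-rowSums(ap * ab) / rowSums(ab * ab), 0), 1)
    q <- segs[, 1:3, drop = FALSE] + ab * tt
    min(sqrt(rowSums(sweep(q, 2, p, "-")^2)))
  }, numeric(1))
  list(mean = mean(d), max = max(d))
}
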