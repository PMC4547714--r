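# Seeded phantom generator: analytic lumbar centerlines, CT-like volumes
# with a ground-truth canal tube, and synthetic curve populations.

# run expr under a temporary RNG state derived from `seed`
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Phantom specification
#'
#' Parameters of a synthetic CT-like volume containing a spinal-canal tube
#' with known centerline: the target curve descriptors, tube geometry,
#' HU-like intensities, bone-ring pattern (interrupted by disc-level gaps
#' where the canal has weak or no edges), noise level and grid.
#'
#' @param segment_length lumbar segment length (chord A-B) in mm.
#' @param peak_location lordosis peak Z position, dimensionless in (0, 1).
#' @param cranial_peak_height,caudal_peak_height dimensionless peak heights.
#' @param scoliosis_amplitude dimensionless lateral bow amplitude.
#' @param canal_radius canal tube radius, mm; must exceed twice the largest
#'   voxel spacing.
#' @param ring_thickness_mm radial thickness of the bone ring, mm.
#' @param bone_intensity,canal_intensity,soft_tissue_intensity HU-like
#'   intensities; bone > soft tissue > canal.
#' @param disc_gap_period_mm,gap_width_mm spacing and width (along Z, mm) of
#'   the disc-level interruptions of the bone ring.
#' @param disc_intensity HU-like intensity of the disc-level ring sections
#'   (a weak edge: well below bone, above the canal acceptance band).
#' @param foramen_halfwidth_deg angular half-width (degrees) of the lateral
#'   nerve-root windows cut into the ring at disc levels (no edge at all).
#' @param noise_sd additive Gaussian noise SD (HU-like).
#' @param spacing voxel spacing, mm.
#' @param dim grid size in voxels.
#' @param rng_seed integer seed controlling all randomness.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(segment_length = 179,
                         peak_location = 0.274,
                         cranial_peak_height = 0.092,
                         caudal_peak_height = 0.061,
                         scoliosis_amplitude = 0.005,
                         canal_radius = 8,
                         ring_thickness_mm = 5,
                         bone_intensity = 1200,
                         canal_intensity = 10,
                         soft_tissue_intensity = 40,
                         disc_gap_period_mm = 35,
                         gap_width_mm = 6,
                         disc_intensity = 200,
                         foramen_halfwidth_deg = 25,
                         noise_sd = 20,
                         spacing = c(0.8, 0.8, 1.5),
                         dim = c(256, 256, 300),
                         rng_seed = 1L) {
  if (peak_location <= 0 || peak_location >= 1)
    stop("peak_location must lie strictly inside (0, 1)", call. = FALSE)
  if (cranial_peak_height < 0 || caudal_peak_height < 0)
    stop("peak heights must be nonnegative", call. = FALSE)
  if (canal_radius <= 2 * max(spacing))
    stop("canal_radius must exceed 2 x max(spacing)", call. = FALSE)
  if (!(bone_intensity > soft_tissue_intensity &&
        soft_tissue_intensity > canal_intensity))
    stop("need bone_intensity > soft_tissue_intensity > canal_intensity",
         call. = FALSE)
  structure(as.list(environment()), class = "phantom_spec")
}

#' Analytic lumbar centerline with exactly prescribed descriptors
#'
#' Builds the unique cubic-in-Z sagittal profile `y(z)` on `z` in `[0, 1]`
#' satisfying `y(0) = 0` at the caudal endpoint B, peak value
#' `y(peak_location) = caudal_peak_height` with zero slope, and
#' `y(1) = caudal_peak_height - cranial_peak_height` at the cranial endpoint
#' A, plus a sinusoidal lateral bow `x(z) = scoliosis_amplitude * sin(pi z)`.
#' The sample grid always contains `z = peak_location`, so the six
#' descriptors round-trip exactly through [compute_features()].
#'
#' @inheritParams phantom_spec
#' @param n_points number of samples (>= 50).
#' @return A [normalized_curve()]; `scale_mm` is chosen so the mm chord
#'   length equals `segment_length`.
#' @export
analytic_centerline <- function(peak_location,
                                cranial_peak_height,
                                caudal_peak_height,
                                segment_length = 179,
                                scoliosis_amplitude = 0,
                                n_points = 201) {
  if (n_points < 50) stop("n_points must be >= 50", call. = FALSE)
  if (peak_location <= 0 || peak_location >= 1)
    stop("peak_location must lie strictly inside (0, 1); the peak ",
         "constraint system is singular at the endpoints", call. = FALSE)
  if (cranial_peak_height < 0 || caudal_peak_height < 0)
    stop("peak heights must be nonnegative", call. = FALSE)
  zp <- peak_location
  hc <- caudal_peak_height
  hr <- cranial_peak_height
  # y = a z^3 + b z^2 + c z ; y(zp) = hc, y'(zp) = 0, y(1) = hc - hr
  m <- rbind(c(zp^3, zp^2, zp),
             c(3 * zp^2, 2 * zp, 1),
             c(1, 1, 1))
  coef <- solve(m, c(hc, 0, hc - hr))
  # sample grid: uniform plus the exact peak; uniform points too close to
  # the peak are dropped so the peak sample is never shadowed by a
  # floating-point near-tie in Y
  z <- seq(0, 1, length.out = n_points)
  z <- sort(c(z[abs(z - zp) > 2e-3 | z %in% c(0, 1)], zp))
  y <- coef[1] * z^3 + coef[2] * z^2 + coef[3] * z
  x <- scoliosis_amplitude * sin(pi * z)
  a <- c(x[length(x)], y[length(y)], 1)
  chord <- sqrt(sum(a^2)) # B is the origin
  normalized_curve(x, y, z, scale_mm = segment_length / chord)
}

#' Synthesize a CT-like phantom volume with ground truth
#'
#' Sweeps a tube of `canal_intensity` along the analytic centerline —
#' extended straight beyond the lumbar segment so the canal spans the whole
#' scan, as in a real acquisition — and surrounds it with a
#' `bone_intensity` ring. Every `disc_gap_period_mm` a `gap_width_mm` band
#' emulates a disc level: there the ring drops to `disc_intensity` (a weak
#' edge) and is cut open laterally over `foramen_halfwidth_deg` around the
#' left/right directions (nerve-root windows with no edge at all). The
#' assembly is embedded in soft tissue with seeded Gaussian noise.
#' Identical specs produce bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `volume` (a `canal_volume`), `mask` (the
#'   exact noise-free canal tube as a `canal_mask`), `curve` (the analytic
#'   centerline, including its straight extensions, as a mm [curve3d()]),
#'   `lumbar_curve` (the segment between the landmark planes), and
#'   `landmarks` (the endplate planes bounding the segment, see
#'   [landmark_planes()]).
#' @export
synthesize_volume <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  norm <- analytic_centerline(spec$peak_location, spec$cranial_peak_height,
                              spec$caudal_peak_height, spec$segment_length,
                              spec$scoliosis_amplitude, n_points = 201)
  s <- attr(norm, "scale_mm")
  fov <- spec$spacing * (spec$dim - 1)
  # place the lumbar curve: centered in X/Y, Z centered with equal margins
  ctr <- curve_matrix(norm) * s
  zlen <- s # projected extent in mm
  shift <- c(fov[1] / 2 - mean(range(ctr[, 1])),
             fov[2] / 2 - mean(range(ctr[, 2])),
             (fov[3] - zlen) / 2)
  if (shift[3] < 0)
    stop("tube does not fit in the requested grid", call. = FALSE)
  ctr <- sweep(ctr, 2, shift, "+")
  # straight vertical extensions to the scan borders (thoracic/sacral canal)
  ext <- rbind(c(ctr[1, 1:2], 0), ctr, c(ctr[nrow(ctr), 1:2], fov[3]))
  rtot <- spec$canal_radius + spec$ring_thickness_mm
  if (any(apply(ext[, 1:2], 2, min) - rtot < 0) ||
      any(apply(ext[, 1:2], 2, max) + rtot > fov[1:2]))
    stop("tube does not fit in the requested grid", call. = FALSE)
  dims <- as.integer(spec$dim)
  dist <- cpp_tube_distance(ext, dims, spec$spacing, c(0, 0, 0), rtot + 1)
  mask <- dist <= spec$canal_radius
  ring <- which(dist > spec$canal_radius & dist <= rtot)
  # voxel world coordinates of the ring voxels only
  ijk <- arrayInd(ring, dims)
  w <- sweep(ijk - 1, 2, spec$spacing, "*")
  # disc-level bands of world Z, measured from the caudal lumbar endpoint
  in_disc <- ((w[, 3] - ctr[1, 3]) %% spec$disc_gap_period_mm) <
    spec$gap_width_mm
  # azimuth of each ring voxel around the local canal axis (0 = ventral)
  cx <- approx(ext[, 3], ext[, 1], xout = w[, 3], rule = 2)$y
  cy <- approx(ext[, 3], ext[, 2], xout = w[, 3], rule = 2)$y
  az <- atan2(w[, 1] - cx, w[, 2] - cy)
  half <- spec$foramen_halfwidth_deg * pi / 180
  in_foramen <- abs(abs(az) - pi / 2) < half
  vol <- rep(spec$soft_tissue_intensity, prod(dims))
  vol[ring[!in_disc]] <- spec$bone_intensity
  vol[ring[in_disc & !in_foramen]] <- spec$disc_intensity
  vol[mask] <- spec$canal_intensity
  if (spec$noise_sd > 0)
    vol <- vol + with_local_seed(spec$rng_seed,
                                 rnorm(length(vol), 0, spec$noise_sd))
  dim(vol) <- dims
  lm <- landmark_planes(t12_point = ctr[nrow(ctr), ], t12_normal = c(0, 0, 1),
                        s1_point = ctr[1, ], s1_normal = c(0, 0, 1))
  list(volume = image_volume(vol, spec$spacing),
       mask = binary_mask(array(mask, dims), spec$spacing),
       curve = curve3d(ext),
       lumbar_curve = curve3d(ctr),
       landmarks = lm)
}

#' Per-group curve descriptor distributions
#'
#' Gaussian (mean, SD) parameters for the four generative descriptors plus
#' the lateral bow amplitude, used by [sample_population()].
#'
#' @param label group label.
#' @param peak_location,cranial_peak_height,caudal_peak_height,segment_length
#'   numeric `c(mean, sd)` pairs.
#' @param scoliosis_amplitude `c(mean, sd)` for the lateral bow.
#' @return A list of class `group_params`.
#' @export
group_params <- function(label,
                         peak_location,
                         cranial_peak_height,
                         caudal_peak_height,
                         segment_length,
                         scoliosis_amplitude = c(0.005, 0.02)) {
  pars <- list(label = label,
               peak_location = peak_location,
               cranial_peak_height = cranial_peak_height,
               caudal_peak_height = caudal_peak_height,
               segment_length = segment_length,
               scoliosis_amplitude = scoliosis_amplitude)
  for (f in names(pars)[-1]) {
    v <- pars[[f]]
    if (length(v) != 2L || any(!is.finite(v)) || v[2] < 0)
      stop("`", f, "` must be c(mean, sd) with sd >= 0", call. = FALSE)
  }
  structure(pars, class = "group_params")
}

# truncation bounds keeping sampled descriptors in valid ranges
.feature_bounds <- list(
  peak_location = c(0.05, 0.95),
  cranial_peak_height = c(0, 0.3),
  caudal_peak_height = c(0.001, 0.3),
  segment_length = c(100, 300),
  scoliosis_amplitude = c(-0.1, 0.1)
)

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' Sample a synthetic curve population
#'
#' Draws each subject's descriptors independently from the group's Gaussians
#' (truncated to valid ranges), builds the analytic centerline, and returns
#' the normalized curves. Empirical descriptor means converge to the group
#' parameters as `n` grows.
#'
#' @param params a [group_params()].
#' @param n number of subjects (>= 1).
#' @param rng_seed integer seed.
#' @param n_points samples per curve.
#' @return A list of [normalized_curve()] objects with attribute `label`.
#' @export
sample_population <- function(params, n, rng_seed = 1L, n_points = 101) {
  stopifnot(inherits(params, "group_params"), n >= 1)
  draws <- with_local_seed(rng_seed, {
    feats <- c("peak_location", "cranial_peak_height",
               "caudal_peak_height", "segment_length", "scoliosis_amplitude")
    out <- lapply(feats, function(f) {
      b <- .feature_bounds[[f]]
      rtrunc_norm(n, params[[f]][1], params[[f]][2], b[1], b[2])
    })
    names(out) <- feats
    out
  })
  curves <- purrr::map(seq_len(n), function(i) {
    analytic_centerline(draws$peak_location[i],
                        draws$cranial_peak_height[i],
                        draws$caudal_peak_height[i],
                        draws$segment_length[i],
                        draws$scoliosis_amplitude[i],
                        n_points = n_points)
  })
  attr(curves, "label") <- params$label
  attr(curves, "rng_seed") <- rng_seed
  curves
}
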