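# Two-step coarse-to-fine spinal canal segmentation: seeded morphological
# region growing with per-slice shape screening, then narrow-band surface
# refinement against image edges.

#' Segmentation parameters
#'
#' @param intensity_low,intensity_high HU-like acceptance band for canal
#'   contents (CSF/cord vs. surrounding bone).
#' @param slice_area_min,slice_area_max accepted per-slice component area,
#'   mm^2.
#' @param circularity_min minimal in-plane roundness,
#'   `4 * pi * area / perimeter^2` in (0, 1]; perimeter is estimated from
#'   exposed pixel edges, so a digital disk scores about 0.6.
#' @param drift_mm maximal in-plane drift (mm) of the canal cross-section
#'   between adjacent slices during region growing; candidate voxels
#'   farther than this from the previous slice's accepted region are not
#'   grown into (the guard against escaping through disc-level ring
#'   openings).
#' @param bridge_slices how many consecutive slices failing the shape
#'   screen may be bridged by restricting growth to the previous
#'   cross-section's footprint before propagation stops.
#' @param max_iterations cap on region-growing waves.
#' @param refine_iterations surface refinement steps (0 = skip).
#' @param edge_sigma Gaussian scale (mm) of the gradient used for the edge
#'   stop.
#' @param edge_lambda gradient magnitude (HU/mm) at which the edge
#'   indicator `1 / (1 + (|grad|/lambda)^2)` falls to 0.5.
#' @param edge_stop refinement only advances where the edge indicator
#'   exceeds this value.
#' @param band_voxels half-width (voxels) of the narrow band around the
#'   coarse surface within which refinement may move the boundary.
#' @param expected_radius_mm prior canal radius used for the leak guard.
#' @param leak_factor abort growing if the mask exceeds this multiple of
#'   the expected canal volume.
#' @return A list of class `segmentation_params`.
#' @export
segmentation_params <- function(intensity_low = -100, intensity_high = 150,
                                slice_area_min = 30, slice_area_max = 600,
                                circularity_min = 0.4,
                                drift_mm = 2,
                                bridge_slices = 6L,
                                max_iterations = 1000L,
                                refine_iterations = 50L,
                                edge_sigma = 1.0, edge_lambda = 100,
                                edge_stop = 0.5, band_voxels = 2L,
                                expected_radius_mm = 8,
                                leak_factor = 10) {
  if (intensity_low >= intensity_high)
    stop("intensity_low must be below intensity_high", call. = FALSE)
  if (slice_area_min <= 0 || slice_area_max <= slice_area_min)
    stop("slice area bounds must be positive and ordered", call. = FALSE)
  if (circularity_min <= 0 || circularity_min > 1)
    stop("circularity_min must lie in (0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "segmentation_params")
}

# in-plane candidate regions of one slice: components of the intensity band
# that satisfy the area/circularity criteria and are enclosed by bone
slice_candidates <- function(slice, spacing, params) {
  nx <- nrow(slice); ny <- ncol(slice)
  lb <- cpp_slice_label(as.numeric(slice), nx, ny,
                        params$intensity_low, params$intensity_high)
  pix <- spacing[1] * spacing[2]
  out <- list()
  for (l in seq_along(lb$count)) {
    area <- lb$count[l] * pix
    perim <- lb$edges[l] * mean(spacing[1:2])
    circ <- if (perim > 0) 4 * pi * area / perim^2 else 1
    if (area < params$slice_area_min || area > params$slice_area_max) next
    if (circ < params$circularity_min) next
    member <- which(lb$labels == l, arr.ind = TRUE)
    # enclosure: the shell within Chebyshev distance 2 must be mostly bone
    shell <- unique(do.call(rbind, lapply(-2:2, function(di)
      do.call(rbind, lapply(-2:2, function(dj)
        cbind(member[, 1] + di, member[, 2] + dj))))))
    shell <- shell[shell[, 1] >= 1 & shell[, 2] >= 1 &
                   shell[, 1] <= nx & shell[, 2] <= ny, , drop = FALSE]
    shell <- shell[lb$labels[shell] != l, , drop = FALSE]
    if (nrow(shell) == 0) next
    bone_frac <- mean(slice[shell] > params$intensity_high)
    if (bone_frac < 0.5) next
    cen <- c(lb$cx[l], lb$cy[l])
    d2 <- (member[, 1] - cen[1])^2 + (member[, 2] - cen[2])^2
    out[[length(out) + 1]] <- list(centroid = cen,
                                   seed_ij = member[which.min(d2), ],
                                   area = area, circ = circ,
                                   bone_frac = bone_frac)
  }
  out
}

#' Find a seed voxel inside the spinal canal
#'
#' Scans the mid-Z slice for regions inside the intensity band that satisfy
#' the area/circularity criteria and are enclosed by above-band (bone-like)
#' voxels; among candidates prefers the one nearest the dorsal third of the
#' slice (the canal sits dorsal to the vertebral body). If the mid slice has
#' no candidate (e.g. it falls on a disc level), neighboring slices are
#' scanned outward. Deterministic for fixed input.
#'
#' @param vol a [image_volume()] in the internal orientation.
#' @param params a [segmentation_params()].
#' @return Integer voxel index triple `(i, j, k)` of class `seed_point`.
#' @export
find_seed <- function(vol, params = segmentation_params()) {
  stopifnot(inherits(vol, "canal_volume"))
  nz <- dim(vol$data)[3]
  ny <- dim(vol$data)[2]
  mid <- ceiling(nz / 2)
  reach <- max(1L, ceiling(0.2 * nz))
  offsets <- unique(as.vector(rbind(0:reach, -(0:reach))))
  for (off in offsets) {
    k <- mid + off
    if (k < 1 || k > nz) next
    cands <- slice_candidates(vol$data[, , k], vol$spacing, params)
    if (length(cands) == 0) next
    # distance of the centroid to the dorsal third (j <= ny/3), then the
    # more dorsal candidate wins
    score <- vapply(cands, function(cc)
      max(0, cc$centroid[2] - ny / 3) * 1e6 + cc$centroid[2], numeric(1))
    best <- cands[[which.min(score)]]
    return(structure(as.integer(c(best$seed_ij, k)), class = "seed_point"))
  }
  rlang::abort("no canal-like candidate region found near the mid slice",
               class = "canalcurve_seed_not_found")
}

#' Morphological region growing of the spinal canal
#'
#' Grows the canal iteratively from the seed slice outward: on each slice
#' the candidate cross-section is flooded (8-connected, within the
#' intensity band) from the previous slice's accepted region, restricted to
#' voxels within `drift_mm` of it, and accepted only if its area lies in
#' `[slice_area_min, slice_area_max]` and its circularity reaches
#' `circularity_min` — the shape-and-size screening that keeps the growth
#' from escaping where the canal boundary has weak or no edges. A leak
#' guard aborts if the mask exceeds `leak_factor` times the expected canal
#' volume.
#'
#' @inheritParams find_seed
#' @param seed a `seed_point` (or integer triple) inside the band.
#' @return A [binary_mask()] (one 26-connected component containing the
#'   seed) with attribute `growth_log`.
#' @export
region_grow <- function(vol, seed, params = segmentation_params()) {
  stopifnot(inherits(vol, "canal_volume"))
  seed <- as.integer(seed)
  dims <- dim(vol$data)
  if (any(seed < 1L) || any(seed > dims))
    stop("seed outside grid bounds", call. = FALSE)
  sidx <- seed[1] + dims[1] * ((seed[2] - 1) + dims[2] * (seed[3] - 1))
  cap <- params$leak_factor * pi * params$expected_radius_mm^2 *
    (dims[3] * vol$spacing[3]) / prod(vol$spacing)
  res <- cpp_region_grow(as.numeric(vol$data), dims, vol$spacing, sidx,
                         params$intensity_low, params$intensity_high,
                         params$slice_area_min, params$slice_area_max,
                         params$circularity_min, params$max_iterations, cap,
                         params$drift_mm, params$bridge_slices)
  if (res$status == "seed_invalid")
    rlang::abort("seed voxel intensity outside the acceptance band",
                 class = "canalcurve_seed_invalid")
  if (res$status == "leak")
    rlang::abort("region growing exceeded the leak guard volume cap",
                 class = "canalcurve_leak")
  mask <- binary_mask(array(res$mask, dims), vol$spacing, vol$origin)
  attr(mask, "growth_log") <- list(iterations = res$iterations,
                                   added_per_iter = res$added_per_iter)
  mask
}

#' Refine a coarse canal mask against image edges
#'
#' Narrow-band refinement of the coarse surface: the boundary balloons
#' outward into voxels whose intensity matches the coarse region (gate =
#' region mean +/- max(3 SD, 20)) and where the Gaussian-gradient edge
#' indicator shows no strong edge, retreats from voxels failing the gate,
#' and is regularized by a neighbor-support requirement against one-voxel
#' tendrils. Movement is confined to `band_voxels` around the coarse
#' surface. With `refine_iterations = 0` the input is returned unchanged.
#'
#' @inheritParams find_seed
#' @param coarse the coarse [binary_mask()].
#' @return A refined [binary_mask()], one 26-connected component.
#' @export
refine_active_surface <- function(vol, coarse, params = segmentation_params()) {
  stopifnot(inherits(vol, "canal_volume"), inherits(coarse, "canal_mask"))
  stopifnot_same_grid(vol, coarse)
  if (!any(coarse$data))
    stop("coarse mask is empty", call. = FALSE)
  if (params$refine_iterations <= 0) return(coarse)
  dims <- dim(vol$data)
  inten <- vol$data[coarse$data]
  half <- max(3 * sd(inten), 20)
  gate <- mean(inten) + c(-1, 1) * half
  tight <- mean(inten) + c(-1, 1) * half / 2
  g <- cpp_gradmag(as.numeric(vol$data), dims, vol$spacing, params$edge_sigma)
  g <- 1 / (1 + (g / params$edge_lambda)^2)
  refined <- cpp_refine(as.numeric(vol$data), as.logical(coarse$data), dims,
                        g, params$edge_stop, gate[1], gate[2],
                        tight[1], tight[2],
                        as.integer(params$refine_iterations),
                        as.integer(params$band_voxels))
  refined <- cpp_keep_component(refined, dims, 0L, FALSE)
  binary_mask(array(refined, dims), vol$spacing, vol$origin)
}

#' Segment the spinal canal (coarse to fine)
#'
#' Composition of [find_seed()], [region_grow()] and
#' [refine_active_surface()]. Per-step voxel counts are recorded in the
#' `segmentation_log` attribute.
#'
#' @inheritParams find_seed
#' @param seed optional manual seed (integer voxel triple); found
#'   automatically when `NULL`.
#' @return A [binary_mask()] of the canal.
#' @export
segment_canal <- function(vol, seed = NULL, params = segmentation_params()) {
  if (is.null(seed)) seed <- find_seed(vol, params)
  coarse <- region_grow(vol, seed, params)
  refined <- refine_active_surface(vol, coarse, params)
  attr(refined, "segmentation_log") <-
    list(seed = as.integer(seed),
         coarse_voxels = sum(coarse$data),
         refined_voxels = sum(refined$data),
         growth = attr(coarse, "growth_log"))
  refined
}

#' Dice overlap between two masks
#'
#' `2 |A & B| / (|A| + |B|)`; 1 for identical masks.
#'
#' @param a,b [binary_mask()] objects on the same grid.
#' @return A scalar in `[0, 1]`.
#' @export
dice_overlap <- function(a, b) {
  stopifnot_same_grid(a, b)
  2 * sum(a$data & b$data) / (sum(a$data) + sum(b$data))
}
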