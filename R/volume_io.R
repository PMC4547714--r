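#' Construct an image volume
#'
#' A `canal_volume` is a 3-D scalar grid (CT-like intensities) together with
#' its voxel spacing and world origin, expressed in the package's internal
#' anatomical frame: array axis 1 = X+ (subject's right), axis 2 = Y+
#' (ventral), axis 3 = Z+ (cranial), world coordinates in mm.
#'
#' @param data 3-D numeric array, each dimension at least 2 voxels.
#' @param spacing numeric length-3, mm per voxel along (x, y, z); all
#'   strictly positive.
#' @param origin numeric length-3, world position (mm) of voxel (1, 1, 1).
#' @return An object of class `canal_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  if (any(dim(data) < 2L))
    stop("each dimension must have at least 2 voxels", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 strictly positive numbers (mm)", call. = FALSE)
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "canal_volume"
  )
}

#' Construct a binary mask on a volume grid
#'
#' @param data 3-D logical array.
#' @inheritParams image_volume
#' @return An object of class `canal_mask`.
#' @export
binary_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array", call. = FALSE)
  storage.mode(data) <- "logical"
  v <- image_volume(array(0, dim(data)), spacing, origin) # reuse validation
  structure(list(data = data, spacing = v$spacing, origin = v$origin),
            class = "canal_mask")
}

#' @export
print.canal_volume <- function(x, ...) {
  cat("<canal_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.canal_mask <- function(x, ...) {
  cat("<canal_mask> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", sum(x$data), " set\n", sep = "")
  invisible(x)
}

# grid compatibility check used across modules
stopifnot_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data)) ||
      max(abs(a$spacing - b$spacing)) > 1e-9)
    stop("volume and mask are not grid-compatible", call. = FALSE)
  invisible(TRUE)
}

# world coordinates (mm) of a voxel index triple (1-based)
voxel_to_world <- function(vol, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(sweep(ijk - 1, 2, vol$spacing, "*"), 2, vol$origin, "+")
}

#' Read a NIfTI volume in the internal anatomical frame
#'
#' Reads a 3-D NIfTI file and reorients the array so that axis 1 increases
#' to the subject's right, axis 2 ventrally and axis 3 cranially (the RAS
#' frame for a supine subject). Voxel spacing and origin are taken from the
#' file's affine.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return A [image_volume()] object.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3-D volume, got ", length(dim(img)), " dimensions",
         call. = FALSE)
  RNifti::orientation(img) <- "RAS"
  m <- RNifti::xform(img)
  spacing <- abs(c(m[1, 1], m[2, 2], m[3, 3]))
  if (any(spacing <= 0) || any(!is.finite(spacing)))
    spacing <- RNifti::pixdim(img)[1:3]
  image_volume(as.array(img), spacing = spacing, origin = m[1:3, 4])
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a `canal_volume` or `canal_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  dat <- vol$data
  if (is.logical(dat)) storage.mode(dat) <- "integer"
  aff <- diag(4)
  aff[1, 1] <- vol$spacing[1]
  aff[2, 2] <- vol$spacing[2]
  aff[3, 3] <- vol$spacing[3]
  aff[1:3, 4] <- vol$origin
  img <- RNifti::asNifti(dat)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI mask
#'
#' @inheritParams read_volume
#' @return A [binary_mask()] object (voxels > 0.5 are set).
#' @export
read_mask <- function(path) {
  v <- read_volume(path)
  binary_mask(v$data > 0.5, v$spacing, v$origin)
}
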