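#' Volumetric image containers
#'
#' `voxel_image()` wraps a 3D intensity array together with a 4x4 affine that
#' maps 0-based voxel indices (i, j, k) to world coordinates in mm (RAS,
#' NIfTI convention). `binary_mask()` and `prob_atlas()` are the analogous
#' containers for region masks and probabilistic atlases; all three share the
#' grid/affine geometry so they can annotate the same image.
#'
#' @param data 3D numeric array (logical for masks; values in \[0,1\] for
#'   atlases).
#' @param affine 4x4 numeric matrix, voxel-index -> world mm. Last row must
#'   be (0, 0, 0, 1).
#' @return An object of class `voxel_image`, `binary_mask` or `prob_atlas`:
#'   a list with elements `data` and `affine`.
#' @examples
#' img <- voxel_image(array(0, dim = c(4, 4, 4)), affine_scaling(c(1, 1, 1)))
#' voxel_dims(img)
#' @export
voxel_image <- function(data, affine) {
  check_grid(data, affine)
  structure(list(data = data, affine = affine), class = "voxel_image")
}

#' @rdname voxel_image
#' @export
binary_mask <- function(data, affine) {
  check_grid(data, affine)
  vals <- unique(as.vector(data))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    stop("mask values must be strictly in {0, 1}")
  structure(list(data = array(as.logical(data), dim = dim(data)),
                 affine = affine),
            class = "binary_mask")
}

#' @rdname voxel_image
#' @export
prob_atlas <- function(data, affine) {
  check_grid(data, affine)
  if (min(data) < 0 || max(data) > 1)
    stop("atlas probabilities must lie in [0, 1]")
  structure(list(data = data, affine = affine), class = "prob_atlas")
}

check_grid <- function(data, affine) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3D array (a 4D series must be read via read_series)")
  if (any(dim(data) < 1L)) stop("all grid dimensions must be >= 1")
  if (!is.matrix(affine) || any(dim(affine) != c(4L, 4L)))
    stop("affine must be a 4x4 matrix")
  if (max(abs(affine[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("last affine row must be (0, 0, 0, 1)")
  vd <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vd <= 0)) stop("voxel dimensions must be strictly positive")
  invisible(TRUE)
}

#' Voxel dimensions of an image
#'
#' Column norms of the affine's linear part, in mm.
#' @param img a `voxel_image`, `binary_mask` or `prob_atlas`
#' @return numeric length-3 vector (dx, dy, dz) in mm
#' @export
voxel_dims <- function(img) {
  sqrt(colSums(img$affine[1:3, 1:3]^2))
}

#' Diagonal scaling affine with a centered origin
#'
#' Convenience constructor used throughout the phantom generator: voxel
#' dimensions on the diagonal and, optionally, a translation placing the
#' world origin at the grid center.
#' @param vdims voxel dimensions (mm)
#' @param shape grid shape; when given, the origin is moved to the grid
#'   center so world coordinates are symmetric about 0
#' @return 4x4 affine matrix
#' @export
affine_scaling <- function(vdims, shape = NULL) {
  a <- diag(c(vdims, 1))
  if (!is.null(shape)) a[1:3, 4] <- -(shape - 1) / 2 * vdims
  a
}

#' Volume of a binary mask
#'
#' Number of true voxels times the voxel volume dx*dy*dz.
#' @param mask a `binary_mask`
#' @param vdims optional voxel dimensions; defaults to the mask's own
#' @return volume in mm^3
#' @examples
#' aff <- affine_scaling(c(0.39, 0.39, 3))
#' m <- array(FALSE, dim = c(4, 4, 4)); m[1, 1, 1] <- TRUE
#' mask_volume(binary_mask(m, aff))  # 0.4563
#' @export
mask_volume <- function(mask, vdims = NULL) {
  if (is.null(vdims)) vdims <- voxel_dims(mask)
  sum(mask$data) * prod(vdims)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Read a 3D NIfTI-1 volume
#'
#' @param path a .nii or .nii.gz file
#' @param as one of "image", "mask", "atlas" — the container to return
#' @return `voxel_image` (or `binary_mask`/`prob_atlas`)
#' @export
read_image <- function(path, as = c("image", "mask", "atlas")) {
  as <- match.arg(as)
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d),
         "D (use read_series for a 4D measurement series)")
  aff <- unclass(RNifti::xform(nii, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  dat <- array(as.vector(nii), dim = d)
  switch(as,
         image = voxel_image(dat, aff),
         mask  = binary_mask(dat != 0, aff),
         atlas = prob_atlas(dat, aff))
}

#' Read a 4D NIfTI-1 measurement series
#'
#' Splits the 4th dimension (repeated measurements) into a list of 3D
#' `voxel_image`s sharing the spatial affine.
#' @param path a 4D .nii/.nii.gz file
#' @return list of `voxel_image`
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nii <- RNifti::readNifti(path)
  d <- dim(nii)
  if (length(d) != 4L) stop("expected a 4D series, got ", length(d), "D")
  aff <- unclass(RNifti::xform(nii, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- array(as.vector(nii), dim = d)
  lapply(seq_len(d[4]), function(t) voxel_image(arr[, , , t], aff))
}

#' Write a volume or mask as NIfTI-1
#'
#' Data are stored as float32 (uint8 for masks); the affine goes into both
#' the sform and qform (code 2). Round-trips are bit-exact for float32 data.
#' @param img `voxel_image`, `binary_mask` or `prob_atlas`
#' @param path output .nii or .nii.gz path
#' @return `path`, invisibly
#' @export
write_image <- function(img, path) {
  is_mask <- inherits(img, "binary_mask")
  dat <- if (is_mask) array(as.integer(img$data), dim = dim(img$data))
         else img$data
  nii <- RNifti::asNifti(dat, datatype = if (is_mask) "uint8" else "float")
  nii <- set_xforms(nii, img$affine)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Write a list of measurements as one 4D NIfTI-1 series
#' @param imgs list of `voxel_image` on a common grid
#' @param path output path
#' @return `path`, invisibly
#' @export
write_series <- function(imgs, path) {
  stopifnot(length(imgs) >= 1)
  d <- dim(imgs[[1]]$data)
  arr <- array(0, dim = c(d, length(imgs)))
  for (t in seq_along(imgs)) {
    if (!same_grid(imgs[[t]], imgs[[1]]))
      stop("all measurements must share one grid")
    arr[, , , t] <- imgs[[t]]$data
  }
  nii <- RNifti::asNifti(arr, datatype = "float")
  nii <- set_xforms(nii, imgs[[1]]$affine)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

# Stamp an affine into both sform and qform (code 2). RNifti's quaternion
# form cannot carry shears and can drop non-unit scales, so readers go
# through the sform (read_image uses useQuaternionFirst = FALSE).
set_xforms <- function(nii, affine) {
  aff <- structure(affine, code = 2L)
  nii <- RNifti::`sform<-`(nii, aff)
  RNifti::`qform<-`(nii, aff)
}
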