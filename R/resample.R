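# Resampling of volumes between grids and through world-space transforms.
# All sampling is pull-based: for each output voxel the world position is
# mapped back into the source volume and sampled there; positions outside
# the source field of view contribute 0.

resample_core <- function(values, src_grid, world_map, target,
                          interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  # output voxel -> output world -> (inverse world map) -> source world
  # -> source voxel, as one 4x4 matrix
  M <- solve(src_grid$affine) %*% solve(world_map) %*% target$affine
  out <- cpp_resample(as.double(values), src_grid$dims, M, target$dims,
                      as.integer(interpolation == "trilinear"))
  array(out, dim = target$dims)
}

#' Reslice an image onto a target grid
#'
#' Samples the source image at the world positions of the target grid's
#' voxel centers.  Voxels falling outside the source field of view are set
#' to 0.  Use `"nearest"` for label data.
#'
#' @param image an [image_volume].
#' @param target a [volume_grid].
#' @param interpolation `"trilinear"` (default) or `"nearest"`.
#' @return an [image_volume] on `target`.
#' @export
reslice_to_grid <- function(image, target,
                            interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(image, "image_volume"), inherits(target, "volume_grid"))
  if (!grids_overlap(image$grid, target))
    stop("source and target grids have disjoint fields of view")
  vals <- resample_core(image$values, image$grid, diag(4), target,
                        interpolation)
  image_volume(vals, target, image$modality)
}

# Axis-aligned world bounding boxes must intersect.
grids_overlap <- function(a, b) {
  box <- function(g) {
    corners <- as.matrix(expand.grid(c(0, g$dims[1] - 1),
                                     c(0, g$dims[2] - 1),
                                     c(0, g$dims[3] - 1)))
    w <- vox_to_world(g, corners)
    rbind(apply(w, 2, min), apply(w, 2, max))
  }
  ba <- box(a); bb <- box(b)
  all(ba[1, ] <= bb[2, ] & bb[1, ] <= ba[2, ])
}

#' Apply a world-space affine transform to an image
#'
#' The content of the image is moved by `t`: a feature at world position
#' `p` ends up at `t(p)`.  Equivalently, each target voxel at world `v` is
#' filled with the source value at `t^{-1}(v)`.
#'
#' @param image an [image_volume].
#' @param t an `affine_transform` (world mm).
#' @param target target [volume_grid] (defaults to the image's own grid).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return an [image_volume] on `target`.
#' @export
apply_transform <- function(image, t, target = image$grid,
                            interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(image, "image_volume"),
            inherits(t, "affine_transform"))
  vals <- resample_core(image$values, image$grid, t$matrix, target,
                        interpolation)
  image_volume(vals, target, image$modality)
}

#' Mirror an image about the mid-sagittal plane
#'
#' Reflects the volume about the world plane x = 0 mm (the inter-hemispheric
#' plane through bregma), not the array midplane.  On grids whose voxel
#' centers are symmetric about x = 0 this is an exact permutation of voxels;
#' otherwise the mirrored positions are interpolated.
#'
#' @param image an [image_volume].
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return an [image_volume] on the same grid.
#' @export
flip_lr <- function(image, interpolation = c("trilinear", "nearest")) {
  Fm <- diag(c(-1, 1, 1, 1))
  vals <- resample_core(image$values, image$grid, Fm, image$grid,
                        interpolation)
  image_volume(vals, image$grid, image$modality)
}

#' Gaussian smoothing of a volume
#'
#' Separable Gaussian filter with the full width at half maximum given in
#' millimeters; per axis, `sigma = fwhm / (2 sqrt(2 log 2))` converted to
#' voxels through the grid's voxel size.  Boundaries are handled by mirror
#' reflection, so a fully interior kernel conserves total intensity.
#' `fwhm = 0` returns the image unchanged.
#'
#' @param image an [image_volume].
#' @param fwhm kernel FWHM in mm, scalar (isotropic) or length 3; must
#'   be nonnegative.
#' @param boundary `"reflect"` (mirror, intensity-conserving, default) or
#'   `"zero"` (truncated kernel, scanner-like dark field edge).
#' @return an [image_volume].
#' @export
smooth_gaussian <- function(image, fwhm, boundary = c("reflect", "zero")) {
  stopifnot(inherits(image, "image_volume"))
  boundary <- match.arg(boundary)
  fwhm <- rep_len(as.numeric(fwhm), 3L)
  if (any(fwhm < 0)) stop("fwhm must be >= 0")
  if (all(fwhm == 0)) return(image)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  sigma_vox <- sigma_mm / grid_voxel_size(image$grid)
  vals <- cpp_gauss_smooth(as.double(image$values), image$grid$dims,
                           sigma_vox, as.integer(boundary == "zero"))
  image_volume(array(vals, dim = image$grid$dims), image$grid,
               image$modality)
}
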