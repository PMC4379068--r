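#' @useDynLib bregma, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Sampling geometry of a volume in bregma-centered Paxinos space
#'
#' A `volume_grid` couples array dimensions with an invertible affine map
#' from 0-based voxel indices (voxel centers) to world coordinates in
#' millimeters.  The world frame is the stereotaxic Paxinos convention:
#' origin at bregma, +x toward the animal's right, +y anterior, +z dorsal.
#'
#' @param dims integer vector of length 3, voxels per axis (all >= 1).
#' @param voxel_size numeric scalar or length-3 vector, voxel edge length in
#'   mm (all > 0).  Ignored when `affine` is given.
#' @param origin world coordinate (mm) of voxel index (0,0,0).  Ignored when
#'   `affine` is given.
#' @param affine optional full 4x4 voxel-to-world matrix; overrides
#'   `voxel_size`/`origin`.
#' @return An object of class `volume_grid` with fields `dims` and `affine`.
#' @examples
#' g <- volume_grid(c(96, 120, 96), 0.2, origin = c(-9.6, -16.8, -12))
#' vox_to_world(g, c(48, 84, 60))   # bregma
#' @export
volume_grid <- function(dims, voxel_size = 1, origin = c(0, 0, 0),
                        affine = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L))
    stop("dims must be 3 integers >= 1")
  if (is.null(affine)) {
    voxel_size <- rep_len(as.numeric(voxel_size), 3L)
    if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
    affine <- diag(4)
    diag(affine)[1:3] <- voxel_size
    affine[1:3, 4] <- as.numeric(origin)
  } else {
    affine <- as.matrix(affine)
    if (!all(dim(affine) == c(4, 4))) stop("affine must be 4x4")
    if (abs(det(affine[1:3, 1:3])) < 1e-12)
      stop("grid affine is not invertible")
  }
  structure(list(dims = dims, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$dims, collapse = " x "),
      "voxels,", paste(signif(grid_voxel_size(x), 4), collapse = " x "),
      "mm\n  origin (mm):", paste(signif(x$affine[1:3, 4], 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Voxel size of a grid
#'
#' Column norms of the linear part of the voxel-to-world affine, in mm.
#' @param grid a [volume_grid].
#' @return numeric length-3 vector.
#' @export
grid_voxel_size <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Map voxel indices to world coordinates
#'
#' @param grid a [volume_grid].
#' @param ijk numeric vector of length 3 or an n x 3 matrix of 0-based voxel
#'   indices (may be fractional).
#' @return world coordinates in mm, same shape as the input.
#' @export
vox_to_world <- function(grid, ijk) {
  ijk <- rbind(t(matrix(ijk, ncol = 3)), 1)
  w <- grid$affine %*% ijk
  out <- t(w[1:3, , drop = FALSE])
  if (nrow(out) == 1L) drop(out) else out
}

#' Map world coordinates to voxel indices
#'
#' Inverse of [vox_to_world()]; returns continuous 0-based voxel indices.
#' @inheritParams vox_to_world
#' @param xyz world coordinates (mm), length 3 or n x 3.
#' @export
world_to_vox <- function(grid, xyz) {
  xyz <- rbind(t(matrix(xyz, ncol = 3)), 1)
  v <- solve(grid$affine) %*% xyz
  out <- t(v[1:3, , drop = FALSE])
  if (nrow(out) == 1L) drop(out) else out
}

#' Canonical acquisition grids
#'
#' Pre-defined 0.2 mm isotropic grids used throughout the pipeline: `"small"`
#' (96 x 120 x 96, cropped to the skull) and `"large"` (150 x 150 x 150,
#' broader field of view including extracranial structures), plus the
#' 180 x 180 x 180 `"prep"` grid accepted as an input geometry.  Bregma sits
#' at voxel (48, 84, 60) on the small grid, (75, 105, 75) on the large one
#' and (90, 120, 90) on the preparation grid, so that the brain (which
#' extends mostly posterior and ventral to bregma) is fully in field.
#'
#' @param size one of `"small"`, `"large"`, `"prep"`.
#' @return a [volume_grid].
#' @export
default_grid <- function(size = c("small", "large", "prep")) {
  size <- match.arg(size)
  switch(size,
    small = volume_grid(c(96L, 120L, 96L), 0.2,
                        origin = -0.2 * c(48, 84, 60)),
    large = volume_grid(c(150L, 150L, 150L), 0.2,
                        origin = -0.2 * c(75, 105, 75)),
    prep  = volume_grid(c(180L, 180L, 180L), 0.2,
                        origin = -0.2 * c(90, 120, 90)))
}

#' A scalar image volume on a grid
#'
#' @param values 3D numeric array whose dimensions equal `grid$dims`.  All
#'   values must be finite.
#' @param grid a [volume_grid].
#' @param modality free-text modality tag (e.g. `"PET"`, `"SPECT"`).
#' @return object of class `image_volume`.
#' @export
image_volume <- function(values, grid, modality = "PET") {
  values <- as.array(values)
  if (!identical(dim(values), NULL) && length(dim(values)) != 3L)
    stop("values must be a 3D array")
  if (!all(dim(values) == grid$dims))
    stop("values dimensions do not match grid dims")
  if (!all(is.finite(values)))
    stop("image values must all be finite")
  structure(list(values = values, grid = grid, modality = modality),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("image_volume [", x$modality, "] ",
      paste(dim(x$values), collapse = " x "),
      ", range ", paste(signif(range(x$values), 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' A boolean brain mask on a grid
#'
#' @param mask logical 3D array congruent with `grid$dims`; must contain at
#'   least one `TRUE` voxel.
#' @param grid a [volume_grid].
#' @export
brain_mask <- function(mask, grid) {
  mask <- array(as.logical(mask), dim = dim(as.array(mask)))
  if (!all(dim(mask) == grid$dims)) stop("mask dimensions do not match grid")
  if (!any(mask)) stop("brain mask is empty")
  structure(list(mask = mask, grid = grid), class = "brain_mask")
}

#' An integer-labeled region atlas on a grid
#'
#' @param labels integer 3D array (0 = background) congruent with the grid.
#' @param grid a [volume_grid].
#' @param names data.frame with columns `label` (integer), `region`
#'   (character) and `hemisphere` (`"left"`/`"right"`).  Every nonzero label
#'   in `labels` must appear, and every region must have both hemisphere
#'   labels.
#' @export
label_atlas <- function(labels, grid, names) {
  labels <- array(as.integer(labels), dim = dim(as.array(labels)))
  if (!all(dim(labels) == grid$dims)) stop("labels do not match grid dims")
  stopifnot(is.data.frame(names),
            all(c("label", "region", "hemisphere") %in% colnames(names)))
  present <- setdiff(unique(as.vector(labels)), 0L)
  if (!all(present %in% names$label))
    stop("labels present in the volume are missing from the name table")
  if (!all(names$hemisphere %in% c("left", "right")))
    stop("hemisphere must be 'left' or 'right'")
  sides <- table(names$region)
  if (any(sides != 2L))
    stop("every region must have exactly a left and a right label")
  structure(list(labels = labels, grid = grid, names = names),
            class = "label_atlas")
}

# Internal: grids must describe the same sampling to combine volumes voxelwise.
same_grid <- function(a, b, tol = 1e-6) {
  all(a$dims == b$dims) && max(abs(a$affine - b$affine)) < tol
}
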