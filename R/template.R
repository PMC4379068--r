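# Three-step tracer-specific template construction:
#   1. affine SSD normalization of every subject to a representative scan,
#   2. symmetric voxelwise averaging (flip - register - average),
#   3. rigid NMI coregistration of the symmetric average to a reference
#      volume already in Paxinos space, with the resulting map propagated
#      to every subject.

#' Align a cohort of images to a representative scan
#'
#' Every image is affinely registered (SSD) to the cohort member at
#' `representative_index` and resampled onto its grid.  The representative's
#' own transform is the identity.  The default control smooths both images
#' by 4 mm inside the data term only (the aligned outputs are resampled
#' from the originals); without it, SSD between two noisy images is biased
#' toward sub-voxel offsets whose interpolation averages away noise.
#'
#' @param images list of [image_volume]s.
#' @param representative_index 1-based index of the reference scan.
#' @param control a [reg_control] for the SSD registrations.
#' @return list with `aligned` (list of [image_volume]s on the
#'   representative grid), `transforms` (list of `affine_transform`s,
#'   subject world -> representative world) and `results` (the raw
#'   registration results).
#' @export
align_cohort <- function(images, representative_index = 1L,
                         control = reg_control("ssd", dof = 12L,
                                               smoothing_fwhm = 4)) {
  stopifnot(length(images) >= 1L)
  if (representative_index < 1L || representative_index > length(images))
    stop("representative_index out of range")
  ref <- images[[representative_index]]
  aligned <- vector("list", length(images))
  transforms <- vector("list", length(images))
  results <- vector("list", length(images))
  for (i in seq_along(images)) {
    if (i == representative_index) {
      aligned[[i]] <- reslice_to_grid(images[[i]], ref$grid)
      transforms[[i]] <- identity_affine()
      results[[i]] <- NULL
    } else {
      res <- register_affine_ssd(images[[i]], ref, control)
      transforms[[i]] <- res$transform
      aligned[[i]] <- apply_transform(images[[i]], res$transform, ref$grid)
      results[[i]] <- res
    }
  }
  list(aligned = aligned, transforms = transforms, results = results)
}

#' Suggest a representative scan
#'
#' Helper for choosing the cohort member used as registration target: the
#' image with the median total squared difference to all other images
#' (computed on whole volumes, which therefore must share a grid).
#'
#' @param images list of [image_volume]s on a common grid.
#' @return 1-based index.
#' @export
suggest_representative <- function(images) {
  stopifnot(length(images) >= 1L)
  if (length(images) == 1L) return(1L)
  n <- length(images)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (!same_grid(images[[i]]$grid, images[[j]]$grid))
      stop("images must share a grid")
    d[i, j] <- d[j, i] <- sum((images[[i]]$values - images[[j]]$values)^2)
  }
  tot <- rowSums(d)
  which.min(abs(tot - stats::median(tot)))[1]
}

#' Voxelwise average of images on a common grid
#'
#' @param images nonempty list of [image_volume]s with identical grids.
#' @return an [image_volume]: the arithmetic per-voxel mean.
#' @export
voxelwise_average <- function(images) {
  stopifnot(length(images) >= 1L)
  g <- images[[1]]$grid
  acc <- array(0, dim = g$dims)
  for (im in images) {
    if (!same_grid(im$grid, g)) stop("grid mismatch in voxelwise_average")
    acc <- acc + im$values
  }
  image_volume(acc / length(images), g, images[[1]]$modality)
}

#' Symmetrize an average image about the mid-sagittal plane
#'
#' A left-right mirrored duplicate of the average is created ([flip_lr()]),
#' affinely registered (SSD) back onto the original, and the two are
#' averaged voxelwise.  For a perfectly mirror-symmetric input the
#' registration sits at the identity and the image is a fixed point.
#'
#' @param average an [image_volume].
#' @param control a [reg_control] for the flip registration.
#' @return list with `volume` (the symmetrized [image_volume]),
#'   `transform` (the flip-registration map) and `converged`.
#' @export
symmetrize <- function(average, control = reg_control("ssd", dof = 12L,
                                                      smoothing_fwhm = 4)) {
  flipped <- flip_lr(average)
  res <- register_affine_ssd(flipped, average, control)
  reg_flip <- apply_transform(flipped, res$transform, average$grid)
  out <- image_volume((average$values + reg_flip$values) / 2,
                      average$grid, average$modality)
  list(volume = out, transform = res$transform, converged = res$converged)
}

#' Mean relative left-right asymmetry of a volume
#'
#' `mean |T - flip(T)| / mean T`, evaluated over a brain mask when given.
#' @param image an [image_volume].
#' @param mask optional [brain_mask] on the same grid.
#' @return nonnegative scalar.
#' @export
flip_residual <- function(image, mask = NULL) {
  d <- abs(image$values - flip_lr(image)$values)
  m <- image$values
  if (!is.null(mask)) {
    d <- d[mask$mask]
    m <- m[mask$mask]
  }
  mean(d) / mean(m)
}

#' Coregister a symmetric average to a reference volume in Paxinos space
#'
#' Rigid-body (6 dof) registration driven by normalized mutual information,
#' appropriate across modalities (e.g. a PET average onto a structural MRI
#' template).
#'
#' @param symmetric_avg an [image_volume].
#' @param reference an [image_volume] already in Paxinos space.
#' @param control a [reg_control] with `cost = "nmi"`, `dof = 6`.
#' @return an `affine_transform` mapping template space into reference
#'   world coordinates.
#' @export
coregister_to_reference <- function(symmetric_avg, reference,
                                    control = reg_control("nmi", dof = 6L)) {
  register_rigid_nmi(symmetric_avg, reference, control)$transform
}

#' Build a tracer-specific symmetric template
#'
#' Runs the three construction steps in order: cohort alignment to the
#' representative scan, symmetric voxelwise averaging, and (when a
#' reference is supplied) rigid NMI coregistration into the reference
#' space, with the coregistration map propagated to every subject.  Each
#' subject transform is the composition coregistration o intra-modal, so
#' applying it to the raw input reproduces that subject's contribution in
#' template space.
#'
#' @param images list of [image_volume]s (raw cohort).
#' @param representative_index 1-based index of the representative scan.
#' @param reference optional [image_volume] in Paxinos space; when `NULL`
#'   the template stays in the representative's space.
#' @param control [reg_control] for the SSD steps.
#' @param nmi_control [reg_control] for the reference coregistration.
#' @param tracer,strain provenance labels stored on the template.
#' @return list with `template` (class `brain_template`: fields `volume`,
#'   `tracer`, `strain`, `n_subjects`, `subject_transforms`, `symmetric`)
#'   and `report` (per-subject costs and convergence flags).
#' @export
build_template <- function(images, representative_index = 1L,
                           reference = NULL,
                           control = reg_control("ssd", dof = 12L,
                                                 smoothing_fwhm = 4),
                           nmi_control = reg_control("nmi", dof = 6L),
                           tracer = "unknown", strain = "unknown") {
  ali <- align_cohort(images, representative_index, control)
  avg <- voxelwise_average(ali$aligned)
  sym <- symmetrize(avg, control)
  if (!is.null(reference)) {
    coreg <- coregister_to_reference(sym$volume, reference, nmi_control)
    final <- apply_transform(sym$volume, coreg, reference$grid)
  } else {
    coreg <- identity_affine()
    final <- sym$volume
  }
  subject_transforms <- lapply(ali$transforms,
                               function(t) compose_affine(coreg, t))
  template <- structure(
    list(volume = final, tracer = tracer, strain = strain,
         n_subjects = length(images),
         subject_transforms = subject_transforms,
         symmetric = TRUE),
    class = "brain_template")
  report <- list(
    subject_cost = vapply(ali$results, function(r)
      if (is.null(r)) 0 else r$final_cost, numeric(1)),
    subject_converged = vapply(ali$results, function(r)
      if (is.null(r)) TRUE else r$converged, logical(1)),
    symmetrization_transform = sym$transform,
    symmetrization_converged = sym$converged,
    coregistration_transform = coreg)
  list(template = template, report = report)
}

#' @export
print.brain_template <- function(x, ...) {
  cat("brain_template: tracer ", x$tracer, ", strain ", x$strain,
      ", n = ", x$n_subjects, "\n", sep = "")
  print(x$volume)
  invisible(x)
}
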