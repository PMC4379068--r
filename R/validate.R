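# Randomized-misalignment validation of spatial normalization: each
# already-normalized image is perturbed by known random transforms, heavily
# smoothed, re-registered to the template, and the residual per-voxel
# displacement between original and recovered positions is averaged over
# the brain mask.

#' Specification of the random misalignment protocol
#'
#' Defaults follow the standard protocol: per image, `n_per_kind`
#' misalignments of each kind with parameters drawn uniformly from
#' translation within +/- 0.5 mm, rotation within +/- 20 degrees, linear
#' stretching within +/- 10 percent, and, for the combined misalignment,
#' rotation reduced to +/- 10 degrees.  Transforms act about bregma.
#'
#' @param translation_range half-width of the uniform translation range, mm.
#' @param rotation_range half-width of the rotation range, degrees.
#' @param scale_range half-width of the scale range, as a fraction.
#' @param combined_rotation_range rotation half-width used by the combined
#'   kind, degrees.
#' @param n_per_kind misalignments per kind per image.
#' @param seed integer seed; draws are deterministic in
#'   (seed, image id, kind, replicate).
#' @param quantize when `TRUE`, drawn parameters are rounded to 0.1 mm,
#'   1 degree and 1 percent, mimicking integer pseudorandom draws.
#' @return a `misalignment_spec` list.
#' @export
misalignment_spec <- function(translation_range = 0.5, rotation_range = 20,
                              scale_range = 0.1,
                              combined_rotation_range = 10,
                              n_per_kind = 10L, seed = 1L,
                              quantize = FALSE) {
  stopifnot(translation_range >= 0, rotation_range >= 0, scale_range >= 0,
            combined_rotation_range >= 0, n_per_kind >= 1L)
  structure(list(translation_range = translation_range,
                 rotation_range = rotation_range,
                 scale_range = scale_range,
                 combined_rotation_range = combined_rotation_range,
                 n_per_kind = as.integer(n_per_kind),
                 seed = as.integer(seed), quantize = quantize),
            class = "misalignment_spec")
}

MISALIGN_KINDS <- c("translate", "rotate", "scale", "combined")

# Deterministic sub-seed from (seed, image id, kind, replicate), kept well
# below 2^31.
misalign_seed <- function(seed, image_id, kind, replicate) {
  if (is.character(image_id))
    image_id <- sum(utf8ToInt(image_id) * seq_len(nchar(image_id)))
  ki <- match(kind, MISALIGN_KINDS)
  mix <- (as.double(seed) * 48271 + as.double(image_id) * 2246822519 +
          ki * 3266489917 + as.double(replicate) * 668265263)
  as.integer(mix %% 2147483629)
}

with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Draw one random misalignment transform
#'
#' Parameters are uniform over the ranges of the requested kind:
#' `"translate"` draws 3 translations (rotations 0, scales 1); `"rotate"`
#' draws 3 angles; `"scale"` draws 3 scale factors in `[1 - r, 1 + r]`;
#' `"combined"` draws all of them with the reduced rotation range.  The
#' draw is deterministic for fixed (spec seed, image id, kind, replicate)
#' and leaves the global RNG state untouched.
#'
#' @param spec a [misalignment_spec].
#' @param kind one of `"translate"`, `"rotate"`, `"scale"`, `"combined"`.
#' @param image_id integer identifier of the image.
#' @param replicate replicate index (1-based).
#' @return an `affine_transform`.
#' @export
sample_misalignment <- function(spec, kind, image_id = 1L, replicate = 1L) {
  if (!kind %in% MISALIGN_KINDS) stop("unknown misalignment kind: ", kind)
  q <- function(x, step) if (spec$quantize) round(x / step) * step else x
  with_local_seed(misalign_seed(spec$seed, image_id, kind, replicate), {
    tr <- c(0, 0, 0); ro <- c(0, 0, 0); sc <- c(1, 1, 1)
    if (kind %in% c("translate", "combined"))
      tr <- q(stats::runif(3, -spec$translation_range,
                           spec$translation_range), 0.1)
    if (kind == "rotate")
      ro <- q(stats::runif(3, -spec$rotation_range, spec$rotation_range), 1)
    if (kind == "combined")
      ro <- q(stats::runif(3, -spec$combined_rotation_range,
                           spec$combined_rotation_range), 1)
    if (kind %in% c("scale", "combined"))
      sc <- 1 + q(stats::runif(3, -spec$scale_range, spec$scale_range), 0.01)
    make_affine(tx = tr[1], ty = tr[2], tz = tr[3],
                rx = ro[1], ry = ro[2], rz = ro[3],
                sx = sc[1], sy = sc[2], sz = sc[3])
  })
}

#' Mean voxel displacement between applied and recovered positions
#'
#' For every brain-mask voxel with world position `p`, the position after
#' misalignment and subsequent re-registration is
#' `p' = recovered(applied(p))`; the error is the mean Euclidean norm
#' `||p' - p||` in mm.  Zero iff the recovery undoes the misalignment on
#' the mask's point set; for pure translations it equals the uncompensated
#' translation norm independent of the mask.
#'
#' @param applied `affine_transform` of the misalignment.
#' @param recovered `affine_transform` returned by re-registration.
#' @param mask a nonempty [brain_mask].
#' @return mean displacement in mm.
#' @export
mean_displacement_error <- function(applied, recovered, mask) {
  stopifnot(inherits(mask, "brain_mask"))
  idx <- which(mask$mask, arr.ind = TRUE) - 1  # 0-based voxel indices
  if (nrow(idx) == 0L) stop("empty mask")
  P <- vox_to_world(mask$grid, idx)
  if (is.null(dim(P))) P <- matrix(P, ncol = 3)
  M <- recovered$matrix %*% applied$matrix
  Pp <- cbind(P, 1) %*% t(M[1:3, , drop = FALSE])
  mean(sqrt(rowSums((Pp - P)^2)))
}

#' Heavy smoothing on a padded coarse grid (protocol preprocessing)
#'
#' Smoothing with a kernel comparable to the field-of-view margins must pad
#' the field, or boundary truncation creates halos that bias the subsequent
#' registration.  This helper applies the full kernel exactly (zero
#' padding) and cheaply: an anti-alias Gaussian at native resolution, then
#' resampling onto a grid coarsened to about half the kernel sigma and
#' padded by two sigma, then the remainder of the kernel there.  The
#' returned image carries the padded coarse grid.
#'
#' @param image an [image_volume].
#' @param fwhm total kernel FWHM in mm.
#' @return an [image_volume] on the padded coarse grid.
#' @export
smooth_padded <- function(image, fwhm) {
  if (fwhm <= 0) return(image)
  vs <- grid_voxel_size(image$grid)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  factor <- max(1L, floor(sigma / (8 * max(vs))))
  st1 <- image
  fw1 <- 0
  if (factor > 1L) {                   # anti-alias before coarsening
    fw1 <- 2 * max(vs) * factor
    st1 <- smooth_gaussian(image, fw1, boundary = "zero")
  }
  cvs <- vs * factor
  pad_mm <- ceiling(2 * sigma / cvs) * cvs  # whole output voxels
  dims_c <- as.integer(ceiling((image$grid$dims * vs + 2 * pad_mm) / cvs))
  origin <- image$grid$affine[1:3, 4] - pad_mm
  coarse <- volume_grid(dims_c, cvs, origin = origin)
  st1c <- reslice_to_grid(st1, coarse)
  fw2 <- sqrt(max(fwhm^2 - fw1^2, 0))
  smooth_gaussian(st1c, fw2, boundary = "zero")
}

#' Run the randomized-misalignment registration-error protocol
#'
#' For each image and each of the `4 * n_per_kind` misalignments: apply the
#' transform and resample, smooth (8 mm by default), re-register to the
#' template with SSD affine least squares, and record the mean voxel
#' displacement between original and recovered positions.  Images are
#' expected to be already normalized to the template's space, as the
#' construction pipeline leaves them.
#'
#' @param images list of [image_volume]s in template space.
#' @param template an [image_volume] (the registration target).
#' @param mask a [brain_mask] on the template grid; when `NULL` one is
#'   derived from the template by Otsu thresholding.
#' @param spec a [misalignment_spec].
#' @param control a [reg_control] for the SSD re-registration.
#' @param smoothing_fwhm Gaussian FWHM in mm applied identically to the
#'   misaligned image and the template before re-registration.
#' @param cost_mask_dilate_mm the re-registration data term is restricted
#'   to the brain mask dilated by this many mm (making the cost robust to
#'   field-of-view truncation of the smoothing); set `NULL` to use the
#'   whole volume.
#' @param image_ids optional identifiers for the rows (default 1..n).
#' @param recover set `FALSE` to skip re-registration (identity recovery),
#'   giving the no-recovery baseline error.
#' @return an `error_report`: `rows` data.frame (image, kind, replicate,
#'   error_mm) with the applied/recovered transforms as attributes, and
#'   `summary` per kind (mean, SD, min, max in mm).
#' @export
evaluate_registration_error <- function(images, template, mask = NULL,
                                        spec = misalignment_spec(),
                                        control = reg_control("ssd",
                                                              dof = 12L,
                                                              pyramid_levels = 2L,
                                                              sampling = 1L),
                                        smoothing_fwhm = 8,
                                        cost_mask_dilate_mm = 4,
                                        image_ids = NULL,
                                        recover = TRUE) {
  stopifnot(inherits(template, "image_volume"))
  if (is.null(mask)) mask <- otsu_mask(template)
  if (is.null(image_ids)) image_ids <- seq_along(images)
  cost_mask <- if (is.null(cost_mask_dilate_mm)) NULL
               else dilate_mask(mask, cost_mask_dilate_mm)
  fixed <- if (smoothing_fwhm > 0) smooth_padded(template, smoothing_fwhm)
           else template
  if (!is.null(cost_mask) && !same_grid(cost_mask$grid, fixed$grid)) {
    cm <- image_volume(array(as.numeric(cost_mask$mask),
                             dim = cost_mask$grid$dims), cost_mask$grid)
    cost_mask <- brain_mask(
      reslice_to_grid(cm, fixed$grid, "nearest")$values > 0.5, fixed$grid)
  }
  rows <- list()
  applied_list <- list(); recovered_list <- list()
  r <- 0L
  for (ii in seq_along(images)) {
    img <- images[[ii]]
    for (kind in MISALIGN_KINDS) {
      for (rep_i in seq_len(spec$n_per_kind)) {
        t_applied <- sample_misalignment(spec, kind, image_ids[[ii]], rep_i)
        moved <- apply_transform(img, t_applied, template$grid)
        if (smoothing_fwhm > 0) moved <- smooth_padded(moved, smoothing_fwhm)
        if (recover) {
          res <- register_affine_ssd(moved, fixed, control,
                                     mask = cost_mask)
          t_rec <- res$transform
          conv <- res$converged
        } else {
          t_rec <- identity_affine()
          conv <- TRUE
        }
        err <- mean_displacement_error(t_applied, t_rec, mask)
        r <- r + 1L
        rows[[r]] <- data.frame(image = image_ids[[ii]], kind = kind,
                                replicate = rep_i, error_mm = err,
                                converged = conv,
                                stringsAsFactors = FALSE)
        applied_list[[r]] <- t_applied
        recovered_list[[r]] <- t_rec
      }
    }
  }
  rows <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(rows$error_mm, rows$kind), function(e)
    data.frame(mean = mean(e), sd = stats::sd(e), min = min(e), max = max(e))))
  summary <- summary[MISALIGN_KINDS, ]
  summary$kind <- MISALIGN_KINDS
  rownames(summary) <- NULL
  structure(list(rows = rows, summary = summary[, c("kind", "mean", "sd",
                                                    "min", "max")],
                 applied = applied_list, recovered = recovered_list),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat("error_report:", nrow(x$rows), "misalignments,",
      length(unique(x$rows$image)), "image(s)\n")
  print(x$summary, digits = 3)
  cat("overall mean:", signif(mean(x$rows$error_mm), 4), "mm\n")
  invisible(x)
}

#' Dilate a brain mask by a distance in mm
#'
#' Morphological dilation implemented by Gaussian smoothing of the mask
#' indicator and low thresholding; the effective radius is about `mm`.
#'
#' @param mask a [brain_mask].
#' @param mm dilation distance in mm.
#' @return a [brain_mask].
#' @export
dilate_mask <- function(mask, mm) {
  if (mm <= 0) return(mask)
  m <- image_volume(array(as.numeric(mask$mask), dim = mask$grid$dims),
                    mask$grid)
  sm <- smooth_gaussian(m, fwhm = 2 * mm, boundary = "zero")
  # half-maximum of the kernel sits at ~ fwhm/2 = mm from the boundary
  brain_mask(sm$values > 0.05 | mask$mask, mask$grid)
}

#' Derive a brain mask from an image by Otsu thresholding
#'
#' Standard Otsu threshold on a 256-bin intensity histogram; voxels above
#' the threshold are brain.
#'
#' @param image an [image_volume].
#' @return a [brain_mask].
#' @export
otsu_mask <- function(image) {
  v <- as.vector(image$values)
  rng <- range(v)
  if (diff(rng) <= 0) stop("constant image: cannot derive a mask")
  h <- tabulate(pmin(256L, pmax(1L, 1L + floor((v - rng[1]) /
                                               diff(rng) * 256))), 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(256L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  thr <- rng[1] + k / 256 * diff(rng)
  brain_mask(image$values > thr, image$grid)
}
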