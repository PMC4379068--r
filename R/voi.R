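# VOI-level quantification: whole-brain normalization, per-region mean
# uptake, and right-to-left asymmetry ratios.

#' Normalize an image by its whole-brain mean uptake
#'
#' Divides every voxel by the mean value over the brain mask, so the output
#' brain mean is exactly 1.  Applied to tracers whose absolute scale is not
#' comparable across animals (e.g. perfusion and glucose-metabolism scans).
#'
#' @param image an [image_volume].
#' @param mask a [brain_mask] on the same grid.
#' @return an [image_volume].
#' @export
whole_brain_normalize <- function(image, mask) {
  stopifnot(inherits(image, "image_volume"), inherits(mask, "brain_mask"))
  if (!same_grid(image$grid, mask$grid)) stop("image and mask grid mismatch")
  m <- mean(image$values[mask$mask])
  if (!is.finite(m) || m <= 0) stop("whole-brain mean must be > 0")
  image_volume(image$values / m, image$grid, image$modality)
}

#' Per-region uptake statistics and right-to-left ratios
#'
#' Computes, for every bilateral region in the atlas, the mean image value
#' over the left and right labels, the volume-weighted bilateral mean, and
#' the right-to-left ratio.  Regions with no labeled voxels on the grid are
#' flagged absent (`NA` statistics).
#'
#' @param image an [image_volume].
#' @param atlas a [label_atlas] on the same grid (reslice first otherwise).
#' @return a `voi_report` data.frame: `region`, `n_vox_left`, `n_vox_right`,
#'   `suv_left`, `suv_right`, `mean_suv`, `rl_ratio`.
#' @export
region_stats <- function(image, atlas) {
  stopifnot(inherits(image, "image_volume"), inherits(atlas, "label_atlas"))
  if (!same_grid(image$grid, atlas$grid))
    stop("image and atlas grid mismatch: reslice the atlas first")
  lab <- as.vector(atlas$labels)
  if (!any(lab != 0L)) stop("atlas has no labeled voxels")
  vals <- as.vector(image$values)
  sums <- rowsum(vals[lab != 0L], lab[lab != 0L])
  cnts <- table(lab[lab != 0L])
  stat <- data.frame(label = as.integer(rownames(sums)),
                     sum = sums[, 1],
                     n = as.integer(cnts[rownames(sums)]))
  regions <- unique(atlas$names$region)
  out <- do.call(rbind, lapply(regions, function(rg) {
    lab_l <- atlas$names$label[atlas$names$region == rg &
                               atlas$names$hemisphere == "left"]
    lab_r <- atlas$names$label[atlas$names$region == rg &
                               atlas$names$hemisphere == "right"]
    sl <- stat[match(lab_l, stat$label), ]
    sr <- stat[match(lab_r, stat$label), ]
    nl <- if (is.na(sl$n)) 0L else sl$n
    nr <- if (is.na(sr$n)) 0L else sr$n
    ml <- if (nl > 0L) sl$sum / nl else NA_real_
    mr <- if (nr > 0L) sr$sum / nr else NA_real_
    bil <- if (nl + nr > 0L)
      (ifelse(nl > 0, sl$sum, 0) + ifelse(nr > 0, sr$sum, 0)) / (nl + nr)
    else NA_real_
    data.frame(region = rg, n_vox_left = nl, n_vox_right = nr,
               suv_left = ml, suv_right = mr, mean_suv = bil,
               rl_ratio = if (!is.na(ml) && !is.na(mr) && ml > 0) mr / ml
                          else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("voi_report", "data.frame")
  out
}

#' Cohort-level VOI table
#'
#' Per-region mean and standard deviation, across subjects, of the
#' bilateral mean uptake and of the right-to-left ratio — the summary
#' printed for the images entering a template.
#'
#' @param images list of [image_volume]s.
#' @param atlas a [label_atlas] shared by all images.
#' @return a data.frame: `region`, `mean_suv`, `sd_suv`, `mean_rl`,
#'   `sd_rl`, `n`.  With a single subject the SDs are `NA`.
#' @export
cohort_voi_table <- function(images, atlas) {
  stopifnot(length(images) >= 1L)
  per <- lapply(images, region_stats, atlas = atlas)
  regions <- per[[1]]$region
  n <- length(images)
  suv <- sapply(per, `[[`, "mean_suv")
  rl <- sapply(per, `[[`, "rl_ratio")
  if (is.null(dim(suv))) { suv <- matrix(suv, ncol = 1); rl <- matrix(rl, ncol = 1) }
  data.frame(region = regions,
             mean_suv = rowMeans(suv),
             sd_suv = if (n > 1L) apply(suv, 1, stats::sd) else NA_real_,
             mean_rl = rowMeans(rl),
             sd_rl = if (n > 1L) apply(rl, 1, stats::sd) else NA_real_,
             n = n, stringsAsFactors = FALSE)
}
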