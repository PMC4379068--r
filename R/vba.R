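# Voxel-based group comparison: smoothing, pooled-variance two-sample
# t-maps, one-sided thresholding with cluster extent, permutation-based
# family-wise-error control at cluster level, stereotaxic peak reporting
# and glass-brain maximum-intensity projections.

# Pooled-variance two-sample t of (mean B - mean A) per row of X.
# Rows with zero pooled variance get t = 0.
tstat_rows <- function(X, idxA, idxB) {
  n1 <- length(idxA); n2 <- length(idxB)
  A <- X[, idxA, drop = FALSE]; B <- X[, idxB, drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  vA <- (rowSums(A^2) - n1 * mA^2) / (n1 - 1)
  vB <- (rowSums(B^2) - n2 * mB^2) / (n2 - 1)
  sp2 <- ((n1 - 1) * vA + (n2 - 1) * vB) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mB - mA) / se
  t[!is.finite(t)] <- 0
  t
}

#' Two-sample t-map of group B versus group A
#'
#' Images are smoothed (1.2 mm isotropic by default), stacked over the mask
#' voxels, and a pooled-variance two-sample t statistic of B minus A
#' (intervention > control positive) is computed per voxel.  No global
#' normalization is applied.  Voxels with zero pooled variance are removed
#' from the analysis mask.
#'
#' @param groupA,groupB lists of [image_volume]s (>= 2 each) on a common
#'   grid; A is the control group, B the intervention group.
#' @param mask a [brain_mask] on the same grid.
#' @param smoothing_fwhm isotropic Gaussian FWHM in mm (default 1.2).
#' @return a `t_map`: `t_values` (3D array, 0 outside the mask), `df`,
#'   `n_per_group`, `mask`, plus the smoothed data matrix needed by
#'   [cluster_fwe()].
#' @export
two_sample_tmap <- function(groupA, groupB, mask, smoothing_fwhm = 1.2) {
  if (length(groupA) < 2L || length(groupB) < 2L)
    stop("each group needs at least 2 images")
  stopifnot(inherits(mask, "brain_mask"))
  g <- mask$grid
  sm <- function(im) {
    if (!same_grid(im$grid, g)) stop("image grid does not match mask grid")
    if (smoothing_fwhm > 0) smooth_gaussian(im, smoothing_fwhm) else im
  }
  all_im <- c(lapply(groupA, sm), lapply(groupB, sm))
  midx <- which(mask$mask)
  X <- vapply(all_im, function(im) im$values[midx],
              numeric(length(midx)))
  n1 <- length(groupA); n2 <- length(groupB)
  t <- tstat_rows(X, seq_len(n1), n1 + seq_len(n2))
  # drop voxels that are exactly constant across all subjects
  const <- rowSums(abs(X - X[, 1])) < 1e-12
  t[const] <- 0
  keep <- !const
  tv <- array(0, dim = g$dims)
  tv[midx] <- t
  mk <- array(FALSE, dim = g$dims)
  mk[midx[keep]] <- TRUE
  structure(list(t_values = tv, df = n1 + n2 - 2L,
                 n_per_group = c(n1, n2),
                 mask = brain_mask(mk, g), grid = g,
                 data = X, mask_index = midx,
                 smoothing_fwhm = smoothing_fwhm),
            class = "t_map")
}

#' @export
print.t_map <- function(x, ...) {
  cat("t_map: df =", x$df, ", groups", paste(x$n_per_group, collapse = " vs "),
      ", max |t| =", signif(max(abs(x$t_values)), 4), "\n")
  invisible(x)
}

#' Threshold a t-map and form clusters
#'
#' One-sided thresholding at the critical t for `voxel_p` with the map's
#' degrees of freedom; suprathreshold voxels are grouped into connected
#' components (18-connectivity by default) and components smaller than
#' `extent_k` voxels are discarded.
#'
#' @param tmap a `t_map`.
#' @param voxel_p uncorrected one-sided voxel threshold (default 0.001).
#' @param extent_k minimum cluster extent in voxels (default 200).
#' @param connectivity 6, 18 or 26.
#' @return a `cluster_set`: `clusters` data.frame (`cluster`, `extent`,
#'   `peak_t`, `peak_x/y/z` in mm), the labeled array, and the thresholds
#'   used.
#' @export
threshold_and_cluster <- function(tmap, voxel_p = 0.001, extent_k = 200L,
                                  connectivity = 18L) {
  stopifnot(inherits(tmap, "t_map"), voxel_p > 0, voxel_p < 1, extent_k >= 0)
  crit <- stats::qt(1 - voxel_p, df = tmap$df)
  supra <- tmap$t_values > crit & tmap$mask$mask
  lab <- cluster_label(supra, tmap$grid$dims, connectivity)
  tab <- cluster_table_from_labels(lab, tmap, extent_k)
  structure(list(clusters = tab, labels = lab$labels,
                 voxel_p = voxel_p, crit_t = crit,
                 extent_k = as.integer(extent_k),
                 connectivity = as.integer(connectivity),
                 tmap = tmap),
            class = "cluster_set")
}

cluster_label <- function(supra, dims, connectivity) {
  lab <- cpp_label_components(as.logical(supra), dims, connectivity)
  n <- attr(lab, "n_components")
  list(labels = array(lab, dim = dims), n = n)
}

cluster_table_from_labels <- function(lab, tmap, extent_k) {
  if (lab$n == 0L)
    return(data.frame(cluster = integer(), extent = integer(),
                      peak_t = numeric(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric()))
  ext <- tabulate(lab$labels[lab$labels > 0L], lab$n)
  keep <- which(ext >= extent_k)
  if (length(keep) == 0L)
    return(data.frame(cluster = integer(), extent = integer(),
                      peak_t = numeric(), peak_x = numeric(),
                      peak_y = numeric(), peak_z = numeric()))
  out <- do.call(rbind, lapply(seq_along(keep), function(i) {
    cl <- keep[i]
    vox <- which(lab$labels == cl)
    pk <- vox[which.max(tmap$t_values[vox])]
    ijk <- arrayInd(pk, tmap$grid$dims) - 1
    w <- vox_to_world(tmap$grid, as.numeric(ijk))
    data.frame(cluster = i, extent = ext[cl],
               peak_t = tmap$t_values[pk],
               peak_x = w[1], peak_y = w[2], peak_z = w[3])
  }))
  # largest first, matching standard reporting order
  out <- out[order(-out$extent), ]
  out$cluster <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Permutation-based cluster-level family-wise-error control
#'
#' Group labels are randomly permuted `n_permutations` times; for each
#' permutation the t-map is recomputed on the same smoothed data,
#' thresholded identically, and the maximal suprathreshold cluster extent
#' recorded.  A cluster's FWE-corrected p is the proportion of permutations
#' whose maximal extent reaches its extent (with add-one smoothing in
#' numerator and denominator).  Cluster-level uncorrected p uses the pooled
#' null distribution of all cluster extents; peak-level FWE p uses the null
#' distribution of the maximal t.  Deterministic for a fixed seed.
#'
#' @param clusters a `cluster_set` from [threshold_and_cluster()].
#' @param n_permutations number of random permutations (>= 100).
#' @param seed integer seed.
#' @return a `cluster_table` data.frame: `cluster`, `extent`,
#'   `cluster_fwe_p`, `cluster_unc_p`, `peak_t`, `peak_fwe_p`,
#'   `peak_x/y/z`; thresholds carried as attributes.
#' @export
cluster_fwe <- function(clusters, n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  tmap <- clusters$tmap
  n1 <- tmap$n_per_group[1]; n2 <- tmap$n_per_group[2]
  n <- n1 + n2
  if (choose(n, n1) < 10 * n_permutations)
    warning("few distinct permutations (", choose(n, n1),
            ") for the requested resolution")
  X <- tmap$data
  dims <- tmap$grid$dims
  midx <- tmap$mask_index
  crit <- clusters$crit_t
  max_ext <- integer(n_permutations)
  max_t <- numeric(n_permutations)
  null_ext <- vector("list", n_permutations)
  with_local_seed(as.integer(seed), {
    for (p in seq_len(n_permutations)) {
      idxB <- sample.int(n, n2)
      idxA <- setdiff(seq_len(n), idxB)
      t <- tstat_rows(X, idxA, idxB)
      supra_v <- t > crit
      mt <- suppressWarnings(max(t))
      max_t[p] <- if (is.finite(mt)) mt else 0
      if (!any(supra_v)) { max_ext[p] <- 0L; null_ext[[p]] <- integer(); next }
      supra <- array(FALSE, dim = dims)
      supra[midx[supra_v]] <- TRUE
      lab <- cluster_label(supra, dims, clusters$connectivity)
      ext <- tabulate(lab$labels[lab$labels > 0L], lab$n)
      max_ext[p] <- max(ext)
      null_ext[[p]] <- ext
    }
  })
  all_null <- unlist(null_ext)
  tab <- clusters$clusters
  if (nrow(tab) > 0L) {
    tab$cluster_fwe_p <- vapply(tab$extent, function(e)
      (1 + sum(max_ext >= e)) / (n_permutations + 1), numeric(1))
    tab$cluster_unc_p <- vapply(tab$extent, function(e)
      (1 + sum(all_null >= e)) / (length(all_null) + 1), numeric(1))
    tab$peak_fwe_p <- vapply(tab$peak_t, function(tt)
      (1 + sum(max_t >= tt)) / (n_permutations + 1), numeric(1))
    tab <- tab[, c("cluster", "extent", "cluster_fwe_p", "cluster_unc_p",
                   "peak_t", "peak_fwe_p", "peak_x", "peak_y", "peak_z")]
  } else {
    tab$cluster_fwe_p <- numeric(); tab$cluster_unc_p <- numeric()
    tab$peak_fwe_p <- numeric()
  }
  structure(tab,
            class = c("cluster_table", "data.frame"),
            voxel_p = clusters$voxel_p, extent_k = clusters$extent_k,
            crit_t = crit, n_permutations = as.integer(n_permutations),
            seed = as.integer(seed),
            null_max_extent = max_ext, null_max_t = max_t,
            cluster_set = clusters)
}

#' Report cluster peaks in Paxinos coordinates
#'
#' One row per local peak: within each cluster, suprathreshold local maxima
#' at least `min_separation` mm apart (greedy, by descending t), at most
#' `max_peaks` per cluster.  Coordinates are rounded to 0.1 mm.
#'
#' @param cluster_table a `cluster_table` from [cluster_fwe()].
#' @param min_separation minimum peak separation in mm (default 8).
#' @param max_peaks maximal peaks per cluster (default 3).
#' @return data.frame: `cluster`, `cluster_fwe_p`, `cluster_unc_p`,
#'   `extent`, `peak_t`, `peak_fwe_p`, `x`, `y`, `z` (mm).
#' @export
report_peaks_paxinos <- function(cluster_table, min_separation = 8,
                                 max_peaks = 3L) {
  stopifnot(inherits(cluster_table, "cluster_table"))
  cs <- attr(cluster_table, "cluster_set")
  empty <- data.frame(cluster = integer(), cluster_fwe_p = numeric(),
                      cluster_unc_p = numeric(), extent = integer(),
                      peak_t = numeric(), peak_fwe_p = numeric(),
                      x = numeric(), y = numeric(), z = numeric())
  if (nrow(cluster_table) == 0L) return(empty)
  tmap <- cs$tmap
  out <- list()
  # map reported clusters back to label ids via their peak voxel
  for (r in seq_len(nrow(cluster_table))) {
    row <- cluster_table[r, ]
    pk_vox <- round(world_to_vox(tmap$grid,
                                 c(row$peak_x, row$peak_y, row$peak_z)))
    lab_id <- cs$labels[matrix(pk_vox + 1, ncol = 3)]
    vox <- which(cs$labels == lab_id)
    ord <- vox[order(-tmap$t_values[vox])]
    ijk <- arrayInd(ord, tmap$grid$dims) - 1
    W <- vox_to_world(tmap$grid, ijk)
    if (is.null(dim(W))) W <- matrix(W, ncol = 3)
    sel <- integer()
    for (i in seq_len(nrow(W))) {
      if (length(sel) >= max_peaks) break
      if (length(sel) == 0L ||
          all(sqrt(colSums((t(W[sel, , drop = FALSE]) - W[i, ])^2)) >=
              min_separation))
        sel <- c(sel, i)
    }
    out[[r]] <- data.frame(cluster = row$cluster,
                           cluster_fwe_p = row$cluster_fwe_p,
                           cluster_unc_p = row$cluster_unc_p,
                           extent = row$extent,
                           peak_t = tmap$t_values[ord[sel]],
                           peak_fwe_p = c(row$peak_fwe_p,
                                          rep(NA_real_,
                                              length(sel) - 1L)),
                           x = round(W[sel, 1], 1), y = round(W[sel, 2], 1),
                           z = round(W[sel, 3], 1))
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Glass-brain maximum-intensity projections of a thresholded t-map
#'
#' Projects the suprathreshold t field of the surviving clusters onto the
#' sagittal (y,z), coronal (x,z) and axial (x,y) planes by maximum
#' intensity, together with the projected brain-mask outline.
#'
#' @param tmap a `t_map`.
#' @param cluster_table a `cluster_table`; only voxels in its clusters are
#'   projected (an empty table gives outline-only projections).
#' @return a `glass_brain` object (three projection matrices with mm axis
#'   coordinates plus mask outlines); has a `plot()` method.
#' @export
mip_glass_brain <- function(tmap, cluster_table) {
  stopifnot(inherits(tmap, "t_map"))
  cs <- attr(cluster_table, "cluster_set")
  field <- array(0, dim = tmap$grid$dims)
  if (!is.null(cs) && nrow(cluster_table) > 0L) {
    keep <- cs$labels > 0L
    # restrict to labels that survived extent thresholding
    surviving <- unique(unlist(lapply(seq_len(nrow(cluster_table)),
      function(r) {
        pk <- round(world_to_vox(tmap$grid,
                                 unlist(cluster_table[r, c("peak_x", "peak_y",
                                                           "peak_z")])))
        cs$labels[matrix(pk + 1, ncol = 3)]
      })))
    keep <- array(cs$labels %in% surviving & cs$labels > 0L,
                  dim = tmap$grid$dims)
    field[keep] <- tmap$t_values[keep]
  }
  axes <- lapply(1:3, function(ax) {
    idx <- seq_len(tmap$grid$dims[ax]) - 1
    ijk <- matrix(0, length(idx), 3)
    ijk[, ax] <- idx
    w <- vox_to_world(tmap$grid, ijk)
    if (is.null(dim(w))) w <- matrix(w, ncol = 3)
    w[, ax]
  })
  proj <- function(a, margin) apply(a, margin, max)
  mask_num <- array(as.numeric(tmap$mask$mask), dim = tmap$grid$dims)
  structure(list(
    sagittal = list(values = proj(field, c(2, 3)),
                    outline = proj(mask_num, c(2, 3)) > 0,
                    h = axes[[2]], v = axes[[3]],
                    hlab = "y (mm)", vlab = "z (mm)"),
    coronal = list(values = proj(field, c(1, 3)),
                   outline = proj(mask_num, c(1, 3)) > 0,
                   h = axes[[1]], v = axes[[3]],
                   hlab = "x (mm)", vlab = "z (mm)"),
    axial = list(values = proj(field, c(1, 2)),
                 outline = proj(mask_num, c(1, 2)) > 0,
                 h = axes[[1]], v = axes[[2]],
                 hlab = "x (mm)", vlab = "y (mm)")),
    class = "glass_brain")
}

#' @export
plot.glass_brain <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (nm in names(x)) {
    p <- x[[nm]]
    graphics::image(p$h, p$v, ifelse(p$outline, 0.5, NA),
                    col = grDevices::grey(0.85), zlim = c(0, 1),
                    xlab = p$hlab, ylab = p$vlab, main = nm, useRaster = TRUE)
    if (any(p$values > 0)) {
      v <- p$values
      v[v <= 0] <- NA
      graphics::image(p$h, p$v, v, add = TRUE, useRaster = TRUE,
                      col = grDevices::hcl.colors(64, "Reds", rev = TRUE))
    }
  }
  invisible(x)
}
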