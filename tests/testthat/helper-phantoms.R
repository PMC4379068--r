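# Shared fixtures and independent oracles.  All fixtures are built in code;
# unit tests use coarse grids (0.4-1 mm voxels) so the suite stays fast,
# while the acceptance tests use the canonical 0.2 mm grids.

# Coarse analogue of the canonical small grid: same world extent, 0.4 mm.
coarse_grid <- function() {
  volume_grid(c(48L, 60L, 48L), 0.4, origin = -0.4 * c(24, 42, 30))
}

coarse_spec <- function(...) {
  phantom_spec(grid = coarse_grid(), ...)
}

# Analytic multi-blob image: sum of Gaussians evaluated at (possibly
# transformed) world coordinates -- misaligned copies built this way carry
# no interpolation error, so recovery targets are exact.
blob_field <- function(x, y, z) {
  0.5 * exp(-((x - 2)^2 + (y + 4)^2 + (z + 4)^2) / (2 * 1.5^2)) +
    0.8 * exp(-((x + 3)^2 + (y + 8)^2 + (z + 3)^2) / (2 * 2^2)) +
    0.6 * exp(-(x^2 + (y - 1)^2 + (z + 6)^2) / (2 * 1.2^2)) +
    0.7 * exp(-((x - 1)^2 + (y + 11)^2 + (z + 6)^2) / (2 * 1.8^2))
}

# Evaluate blob_field moved by the world transform t (content at t(p)
# equals the field at p) on a grid.
blob_image <- function(grid = coarse_grid(), t = identity_affine()) {
  co <- bregma:::grid_coord_arrays(grid)
  ti <- solve(t$matrix)
  x <- ti[1, 1] * co$x + ti[1, 2] * co$y + ti[1, 3] * co$z + ti[1, 4]
  y <- ti[2, 1] * co$x + ti[2, 2] * co$y + ti[2, 3] * co$z + ti[2, 4]
  z <- ti[3, 1] * co$x + ti[3, 2] * co$y + ti[3, 3] * co$z + ti[3, 4]
  image_volume(blob_field(x, y, z), grid)
}

# A delta image: single nonzero voxel.
delta_image <- function(grid, ijk, value = 1) {
  v <- array(0, dim = grid$dims)
  v[matrix(ijk + 1, ncol = 3)] <- value
  image_volume(v, grid)
}

# --- independent oracles -------------------------------------------------

# Brute-force trilinear sampling at a single continuous 0-based voxel
# coordinate; out-of-field corners contribute 0.
oracle_trilinear <- function(arr, x, y, z) {
  d <- dim(arr)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  out <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    xi <- x0 + dx; yi <- y0 + dy; zi <- z0 + dz
    w <- (if (dx) x - x0 else 1 - (x - x0)) *
      (if (dy) y - y0 else 1 - (y - y0)) *
      (if (dz) z - z0 else 1 - (z - z0))
    if (xi >= 0 && xi < d[1] && yi >= 0 && yi < d[2] && zi >= 0 && zi < d[3])
      out <- out + w * arr[xi + 1, yi + 1, zi + 1]
  }
  out
}

# Brute-force per-voxel resampling of an image through a world transform.
oracle_resample <- function(image, t, target,
                            interpolation = "trilinear") {
  tm <- if (is.matrix(t)) t else t$matrix
  M <- solve(image$grid$affine) %*% solve(tm) %*% target$affine
  out <- array(0, dim = target$dims)
  for (k in seq_len(target$dims[3]) - 1L)
    for (j in seq_len(target$dims[2]) - 1L)
      for (i in seq_len(target$dims[1]) - 1L) {
        p <- M %*% c(i, j, k, 1)
        out[i + 1, j + 1, k + 1] <-
          if (interpolation == "trilinear")
            oracle_trilinear(image$values, p[1], p[2], p[3])
          else {
            q <- round(p[1:3])
            if (all(q >= 0) && all(q < image$grid$dims))
              image$values[q[1] + 1, q[2] + 1, q[3] + 1] else 0
          }
      }
  out
}

# Brute-force flood-fill connected-component labeling (6/18/26).
oracle_label <- function(mask, connectivity = 18L) {
  d <- dim(mask)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  m <- rowSums(abs(offs))
  offs <- offs[m > 0 & m <= switch(as.character(connectivity),
                                   "6" = 1, "18" = 2, "26" = 3), ,
               drop = FALSE]
  lab <- array(0L, dim = d)
  cur <- 0L
  for (idx in which(mask)) {
    if (lab[idx] != 0L) next
    cur <- cur + 1L
    queue <- idx
    lab[idx] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (r in seq_len(nrow(offs))) {
        q <- ijk + offs[r, ]
        if (any(q < 1) || any(q > d)) next
        qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
        if (mask[qi] && lab[qi] == 0L) {
          lab[qi] <- cur
          queue <- c(queue, qi)
        }
      }
    }
  }
  lab
}

# Relabel components in a canonical order so two labelings can be compared.
canonical_labels <- function(lab) {
  first <- tapply(seq_along(lab), as.vector(lab), min)
  first <- first[names(first) != "0"]
  map <- integer(max(as.integer(names(first))))
  map[as.integer(names(first))] <- rank(first)
  out <- array(0L, dim = dim(lab))
  nz <- lab > 0
  out[nz] <- map[lab[nz]]
  out
}

# Brute-force per-voxel accumulation of region statistics.
oracle_region_means <- function(image, atlas) {
  labs <- sort(setdiff(unique(as.vector(atlas$labels)), 0L))
  sums <- setNames(numeric(length(labs)), labs)
  cnts <- setNames(integer(length(labs)), labs)
  for (idx in which(atlas$labels != 0L)) {
    l <- as.character(atlas$labels[idx])
    sums[l] <- sums[l] + image$values[idx]
    cnts[l] <- cnts[l] + 1L
  }
  sums / cnts
}
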