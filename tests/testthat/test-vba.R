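# Voxel-based analysis: t-maps, clustering, permutation FWE, peak
# reporting and glass-brain projections.

make_groups <- function(n1 = 4, n2 = 4, lesion = NULL, seed = 100,
                        noise = 0.1) {
  spec <- coarse_spec(noise_sd = noise, subject_variability_sd = 0.05)
  geo <- make_label_phantom(spec)
  a <- lapply(seq_len(n1), function(i)
    simulate_subject(spec, subject_seed = seed + i, geometry = geo))
  b <- lapply(seq_len(n2), function(i)
    simulate_subject(spec, lesion = lesion, subject_seed = seed + 100 + i,
                     geometry = geo))
  list(a = a, b = b, mask = geo$mask, geo = geo)
}

test_that("t-map basics: same groups give 0, swapping negates", {
  gr <- make_groups()
  tm0 <- two_sample_tmap(gr$a, gr$a, gr$mask)
  expect_lt(max(abs(tm0$t_values)), 1e-8)
  tm1 <- two_sample_tmap(gr$a, gr$b, gr$mask)
  tm2 <- two_sample_tmap(gr$b, gr$a, gr$mask)
  expect_equal(tm1$t_values, -tm2$t_values, tolerance = 1e-9)
  expect_identical(tm1$df, 6L)
  expect_error(two_sample_tmap(gr$a[1], gr$b, gr$mask), "at least 2")
})

test_that("the pooled t statistic matches the textbook formula", {
  # 2 x 1 x 1 volume, values {1,2,3} vs {4,5,6} at one voxel
  g <- volume_grid(c(2, 1, 1), 1)
  mk <- function(v) image_volume(array(c(v, 0), dim = c(2, 1, 1)), g)
  mask <- brain_mask(array(c(TRUE, TRUE), dim = c(2, 1, 1)), g)
  tm <- two_sample_tmap(list(mk(1), mk(2), mk(3)),
                        list(mk(4), mk(5), mk(6)), mask,
                        smoothing_fwhm = 0)
  # pooled sd = 1, se = sqrt(1/3 + 1/3), t = 3 / se
  expect_equal(tm$t_values[1, 1, 1], 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_identical(tm$df, 4L)
  # the all-zero voxel is dropped from the analysis mask
  expect_false(tm$mask$mask[2, 1, 1])
})

test_that("cluster labeling agrees with the flood-fill oracle", {
  set.seed(55)
  for (conn in c(6L, 18L, 26L)) {
    for (rep_i in 1:3) {
      d <- c(16L, 16L, 16L)
      m <- array(runif(prod(d)) < 0.25, dim = d)
      ours <- bregma:::cluster_label(m, d, conn)$labels
      oracle <- oracle_label(m, conn)
      expect_identical(canonical_labels(ours), canonical_labels(oracle))
    }
  }
  # one larger instance
  d <- c(32L, 32L, 32L)
  m <- array(runif(prod(d)) < 0.2, dim = d)
  ours <- bregma:::cluster_label(m, d, 18L)$labels
  expect_identical(canonical_labels(ours), canonical_labels(oracle_label(m)))
})

test_that("thresholding and extent filtering follow the stated semantics", {
  g <- coarse_grid()
  tv <- array(0, dim = g$dims)
  mask <- array(TRUE, dim = g$dims)
  # blob A: 250 voxels above threshold; blob B: 150 voxels; k = 200
  tv[5:14, 5:9, 5:9] <- 10       # 10*5*5 = 250
  tv[30:35, 30:34, 30:34] <- 10  # 6*5*5 = 150
  tm <- structure(list(t_values = tv, df = 19L, n_per_group = c(10L, 11L),
                       mask = brain_mask(mask, g), grid = g,
                       data = NULL, mask_index = which(mask),
                       smoothing_fwhm = 0), class = "t_map")
  cs <- threshold_and_cluster(tm, voxel_p = 0.001, extent_k = 200L)
  expect_identical(nrow(cs$clusters), 1L)
  expect_identical(cs$clusters$extent, 250L)
  # both survive at k = 100; none at k = 300
  expect_identical(nrow(threshold_and_cluster(tm, 0.001, 100L)$clusters), 2L)
  expect_identical(nrow(threshold_and_cluster(tm, 0.001, 300L)$clusters), 0L)
  # all-zero map -> empty table
  tm$t_values[] <- 0
  expect_identical(nrow(threshold_and_cluster(tm, 0.001, 0L)$clusters), 0L)
})

test_that("extent-threshold monotonicity: larger k never yields more clusters", {
  set.seed(77)
  gr <- make_groups(n1 = 3, n2 = 3)
  tm <- two_sample_tmap(gr$a, gr$b, gr$mask)
  ks <- c(0L, 5L, 20L, 100L)
  ns <- vapply(ks, function(k)
    nrow(threshold_and_cluster(tm, voxel_p = 0.05, extent_k = k)$clusters),
    1L)
  expect_true(all(diff(ns) <= 0))
})

test_that("permutation FWE is deterministic and flags an injected lesion", {
  les <- lesion_spec(center = c(3.3, 0, -3.4), radius = 1, multiplier = 2)
  gr <- make_groups(n1 = 5, n2 = 5, lesion = les, noise = 0.05)
  tm <- two_sample_tmap(gr$a, gr$b, gr$mask)
  # volume-equivalent of the 200-voxel extent at 0.4 mm voxels: 25
  cs <- threshold_and_cluster(tm, voxel_p = 0.001, extent_k = 25L)
  expect_gt(nrow(cs$clusters), 0L)
  tab1 <- suppressWarnings(cluster_fwe(cs, n_permutations = 120L, seed = 5))
  tab2 <- suppressWarnings(cluster_fwe(cs, n_permutations = 120L, seed = 5))
  expect_identical(tab1$cluster_fwe_p, tab2$cluster_fwe_p)
  expect_lt(tab1$cluster_fwe_p[1], 0.05)
  # peak near the injected center
  expect_lt(sqrt((tab1$peak_x[1] - 3.3)^2 + tab1$peak_y[1]^2 +
                   (tab1$peak_z[1] + 3.4)^2), 1.5)
  expect_error(cluster_fwe(cs, n_permutations = 10L), "100")
})

test_that("peak reporting rounds to 0.1 mm and respects separation", {
  les <- lesion_spec(center = c(3.3, 0, -3.4), radius = 1, multiplier = 2)
  gr <- make_groups(n1 = 5, n2 = 5, lesion = les, noise = 0.05)
  tm <- two_sample_tmap(gr$a, gr$b, gr$mask)
  cs <- threshold_and_cluster(tm, voxel_p = 0.001, extent_k = 25L)
  tab <- suppressWarnings(cluster_fwe(cs, n_permutations = 120L, seed = 5))
  peaks <- report_peaks_paxinos(tab)
  expect_true(all(c("cluster", "cluster_fwe_p", "extent", "peak_t",
                    "x", "y", "z") %in% colnames(peaks)))
  expect_equal(peaks$x, round(peaks$x, 1))
  # at most 3 peaks per cluster, >= 8 mm apart within a cluster
  for (cl in unique(peaks$cluster)) {
    pk <- peaks[peaks$cluster == cl, ]
    expect_lte(nrow(pk), 3L)
    if (nrow(pk) > 1) {
      dmin <- min(dist(pk[, c("x", "y", "z")]))
      expect_gte(dmin, 8)
    }
  }
  # empty input -> header-only
  empty <- tab[0, ]
  attr(empty, "cluster_set") <- attr(tab, "cluster_set")
  class(empty) <- class(tab)
  expect_identical(nrow(report_peaks_paxinos(empty)), 0L)
})

test_that("glass-brain projections place single points correctly", {
  g <- coarse_grid()
  tv <- array(0, dim = g$dims)
  mask <- array(TRUE, dim = g$dims)
  tv[13:17, 21:25, 29:31] <- 8   # 5*5*3 = 75 suprathreshold voxels
  tm <- structure(list(t_values = tv, df = 10L, n_per_group = c(6L, 6L),
                       mask = brain_mask(mask, g), grid = g,
                       data = NULL, mask_index = which(mask),
                       smoothing_fwhm = 0), class = "t_map")
  cs <- threshold_and_cluster(tm, voxel_p = 0.001, extent_k = 10L)
  tab <- structure(cs$clusters,
                   class = c("cluster_table", "data.frame"),
                   cluster_set = cs)
  tab$cluster_fwe_p <- 0.01; tab$cluster_unc_p <- 0.01; tab$peak_fwe_p <- 0.01
  gb <- mip_glass_brain(tm, tab)
  expect_named(gb, c("sagittal", "coronal", "axial"))
  # projected maxima are the cluster value, at the right mm positions
  expect_equal(max(gb$axial$values), 8)
  hit <- which(gb$axial$values == 8, arr.ind = TRUE)
  expect_true(all(gb$axial$h[hit[, 1]] >= vox_to_world(g, c(12, 0, 0))[1]))
  # two voxels along a ray project to their maximum
  tv2 <- tv; tv2[15, 23, 5] <- 3
  tm$t_values <- tv2
  gb2 <- mip_glass_brain(tm, tab)
  expect_equal(max(gb2$axial$values), 8)
  # empty table: outline-only projections
  empty <- tab[0, ]
  attr(empty, "cluster_set") <- cs
  class(empty) <- class(tab)
  gb3 <- mip_glass_brain(tm, empty)
  expect_equal(max(gb3$sagittal$values), 0)
  expect_true(any(gb3$sagittal$outline))
})

test_that("null-group FWE p-values are well-behaved", {
  # no effect: smallest FWE p should rarely be small; here we just check
  # validity of the machinery at reduced scale (full calibration runs in
  # the acceptance suite)
  gr <- make_groups(n1 = 4, n2 = 4, noise = 0.1)
  tm <- two_sample_tmap(gr$a, gr$b, gr$mask)
  cs <- threshold_and_cluster(tm, voxel_p = 0.01, extent_k = 5L)
  if (nrow(cs$clusters) > 0) {
    tab <- cluster_fwe(cs, n_permutations = 100L, seed = 3)
    expect_true(all(tab$cluster_fwe_p > 0 & tab$cluster_fwe_p <= 1))
    expect_true(all(tab$cluster_unc_p > 0 & tab$cluster_unc_p <= 1))
    # p-values decrease with extent
    ord <- order(tab$extent)
    expect_true(all(diff(tab$cluster_fwe_p[ord]) <= 1e-12))
  } else {
    succeed()
  }
})
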