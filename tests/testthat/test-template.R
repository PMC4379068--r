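# Template construction: cohort alignment, averaging, symmetrization,
# reference coregistration, and the assembled pipeline.

test_that("a single-image cohort passes through unchanged", {
  img <- blob_image()
  out <- align_cohort(list(img), 1L)
  expect_lt(max(abs(out$aligned[[1]]$values - img$values)), 1e-6)
  expect_equal(out$transforms[[1]]$matrix, diag(4))
  expect_error(align_cohort(list(img), 5L), "out of range")
})

test_that("known-misaligned copies align back onto the representative", {
  set.seed(17)
  spec <- coarse_spec(noise_sd = 0.02)
  geo <- make_label_phantom(spec)
  rep_img <- simulate_subject(spec, subject_seed = 1, geometry = geo)
  images <- list(rep_img)
  for (i in 2:5) {
    t <- make_affine(tx = runif(1, -0.5, 0.5), ty = runif(1, -0.5, 0.5),
                     rz = runif(1, -8, 8), sy = runif(1, 0.95, 1.05))
    images[[i]] <- apply_transform(
      simulate_subject(spec, subject_seed = i, geometry = geo), t)
  }
  out <- align_cohort(images, 1L)
  for (i in 2:5) {
    expect_gt(cor(as.vector(out$aligned[[i]]$values),
                  as.vector(rep_img$values)), 0.99)
  }
})

test_that("voxelwise averaging is exact", {
  g <- volume_grid(c(6, 5, 4), 1)
  set.seed(3)
  imgs <- lapply(1:4, function(i)
    image_volume(array(runif(120), dim = g$dims), g))
  avg <- voxelwise_average(imgs)
  # brute-force per-voxel loop oracle
  oracle <- array(0, dim = g$dims)
  for (idx in seq_len(120))
    oracle[idx] <- mean(vapply(imgs, function(im) im$values[idx], 1))
  expect_equal(avg$values, oracle, tolerance = 1e-12)
  # average of one image is itself; average of v and 3 - v is 1.5
  expect_identical(voxelwise_average(imgs[1])$values, imgs[[1]]$values)
  v3 <- image_volume(3 - imgs[[1]]$values, g)
  expect_equal(as.vector(voxelwise_average(list(imgs[[1]], v3))$values),
               rep(1.5, 120), tolerance = 1e-12)
  g2 <- volume_grid(c(6, 5, 4), 2)
  expect_error(voxelwise_average(list(imgs[[1]],
                                      image_volume(imgs[[2]]$values, g2))),
               "mismatch")
})

test_that("symmetrizing a symmetric input is a fixed point", {
  spec <- coarse_spec(noise_sd = 0)
  img <- simulate_subject(spec, subject_seed = 1)
  out <- symmetrize(img)
  expect_lt(max(abs(out$volume$values - img$values)), 1e-3)
  p <- affine_params(out$transform)
  expect_lt(max(abs(p[1:3])), 0.05)
  expect_lt(max(abs(p[4:6])), 0.5)
})

test_that("symmetrization reduces the flip residual of asymmetric input", {
  spec <- coarse_spec(noise_sd = 0)
  geo <- make_label_phantom(spec)
  base <- simulate_subject(spec, subject_seed = 1, geometry = geo)
  co <- bregma:::grid_coord_arrays(base$grid)
  bump <- 0.3 * exp(-((co$x - 3)^2 + (co$y + 4)^2 + (co$z + 4)^2) / 2)
  asym <- image_volume(base$values + bump, base$grid)
  out <- symmetrize(asym)
  expect_lt(flip_residual(out$volume, geo$mask),
            flip_residual(asym, geo$mask))
})

test_that("one-sided extra mass symmetrizes to equal mass at +/- x", {
  # a symmetric base anchors the flip registration at the identity; the
  # one-sided bump at x = +2 must end up split equally between +/- 2 mm
  g <- volume_grid(c(41, 21, 21), 0.5, origin = c(-10, -5, -5))
  co <- bregma:::grid_coord_arrays(g)
  # structured, mirror-symmetric base so affine distortions are costly
  base <- exp(-(co$x^2 + co$y^2 + co$z^2) / (2 * 1.5^2)) +
    0.8 * exp(-((co$x - 4)^2 + co$y^2 + co$z^2) / (2 * 1.0^2)) +
    0.8 * exp(-((co$x + 4)^2 + co$y^2 + co$z^2) / (2 * 1.0^2)) +
    0.6 * exp(-(co$x^2 + (co$y - 3)^2 + (co$z + 2)^2) / (2 * 0.9^2)) +
    0.6 * exp(-(co$x^2 + (co$y + 3)^2 + (co$z + 2)^2) / (2 * 0.9^2))
  bump <- 0.3 * exp(-((co$x - 2)^2 + co$y^2 + co$z^2) / (2 * 0.6^2))
  img <- image_volume(base + bump, g)
  out <- symmetrize(img)
  # half the bump at +2 mm, half at -2 mm (voxels i = 24 and 16, 0-based)
  expect_equal(out$volume$values[25, 11, 11], out$volume$values[17, 11, 11],
               tolerance = 0.1)
  expect_equal(out$volume$values[25, 11, 11],
               base[25, 11, 11] + 0.15, tolerance = 0.05)
  expect_equal(sum(out$volume$values), sum(img$values),
               tolerance = 0.01 * sum(img$values))
})

test_that("reference coregistration recovers contrast and shift", {
  spec <- coarse_spec(noise_sd = 0)
  img <- simulate_subject(spec, subject_seed = 1)
  ref <- image_volume(sqrt(img$values + 0.05), img$grid, "MRI")
  t <- coregister_to_reference(img, ref)
  p <- affine_params(t)
  expect_lt(max(abs(p[1:3])), 0.1)
  expect_lt(max(abs(p[4:6])), 0.5)
  ref_shift <- apply_transform(ref, make_affine(ty = -1))
  t2 <- coregister_to_reference(img, ref_shift)
  expect_equal(unname(affine_params(t2)["ty"]), -1, tolerance = 0.1)
  flat <- image_volume(array(1, dim = img$grid$dims), img$grid)
  expect_error(coregister_to_reference(img, flat), "degenerate")
})

test_that("build_template recovers the phantom from a noisy cohort", {
  spec <- coarse_spec(noise_sd = 0.05, subject_variability_sd = 0.1)
  coh <- simulate_cohort(spec, n = 6, cohort_seed = 42)
  bt <- build_template(coh$images, representative_index = 1,
                       tracer = "pk11195", strain = "wistar")
  tpl <- bt$template
  clean <- simulate_subject(coarse_spec(noise_sd = 0), subject_seed = 1)
  expect_gt(cor(as.vector(tpl$volume$values), as.vector(clean$values)), 0.99)
  expect_true(tpl$symmetric)
  expect_lt(flip_residual(tpl$volume, coh$mask), 1e-3)
  expect_length(tpl$subject_transforms, 6L)
  expect_length(bt$report$subject_converged, 6L)
  expect_true(all(bt$report$subject_converged))
  expect_identical(tpl$n_subjects, 6L)
  expect_identical(tpl$tracer, "pk11195")
})

test_that("template building is insensitive to input order", {
  spec <- coarse_spec(noise_sd = 0.05)
  coh <- simulate_cohort(spec, n = 4, cohort_seed = 9)
  b1 <- build_template(coh$images, representative_index = 1)
  b2 <- build_template(coh$images[c(1, 4, 3, 2)], representative_index = 1)
  expect_lt(max(abs(b1$template$volume$values - b2$template$volume$values)),
            1e-6)
})

test_that("rebuilding from copies of a symmetric template is idempotent", {
  spec <- coarse_spec(noise_sd = 0.03)
  coh <- simulate_cohort(spec, n = 4, cohort_seed = 5)
  b1 <- build_template(coh$images)
  tpl <- b1$template$volume
  b2 <- build_template(list(tpl, tpl, tpl))
  expect_gt(cor(as.vector(b2$template$volume$values),
                as.vector(tpl$values)), 0.999)
})

test_that("propagated subject transforms reproduce construction alignment", {
  spec <- coarse_spec(noise_sd = 0.05)
  coh <- simulate_cohort(spec, n = 3, cohort_seed = 31,
                         misalign = misalignment_spec(seed = 4))
  bt <- build_template(coh$images, representative_index = 1)
  tpl <- bt$template
  # placing each raw input with its subject transform should land close to
  # the template (same cost regime as during construction)
  for (i in seq_along(coh$images)) {
    placed <- apply_transform(coh$images[[i]], tpl$subject_transforms[[i]],
                              tpl$volume$grid)
    expect_gt(cor(as.vector(placed$values), as.vector(tpl$volume$values)),
              0.95)
  }
})

test_that("suggest_representative picks a median-distance member", {
  spec <- coarse_spec(noise_sd = 0.05)
  coh <- simulate_cohort(spec, n = 5, cohort_seed = 2)
  idx <- suggest_representative(coh$images)
  expect_true(idx %in% 1:5)
  expect_identical(suggest_representative(coh$images[1]), 1L)
})
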