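# Digital phantom: geometry, uptake profiles, lesions, cohorts.

test_that("uptake profiles carry all 13 regions for every tracer", {
  for (tr in c("fdg", "flumazenil", "medas", "pk11195", "raclopride",
               "hmpao")) {
    p <- uptake_profile(tr)
    expect_identical(nrow(p), 13L)
    expect_true(all(p$mean > 0))
    expect_true(all(p$sd > 0))
  }
  expect_identical(attr(uptake_profile("hmpao"), "modality"), "SPECT")
  expect_identical(attr(uptake_profile("fdg"), "modality"), "PET")
  expect_error(uptake_profile("nonesuch"), "unknown tracer")
  # spot values from the cohort tables
  fl <- uptake_profile("flumazenil")
  expect_equal(fl$mean[fl$region == "cortex"], 0.87)
  expect_equal(fl$mean[fl$region == "medulla"], 0.29)
  ra <- uptake_profile("raclopride")
  expect_equal(ra$mean[ra$region == "caudate_putamen"], 2.37)
  pk <- uptake_profile("pk11195")
  expect_equal(pk$mean[pk$region == "cerebellum"], 0.58)
})

test_that("label phantom: 26 labels, symmetric, disjoint, inside the shell", {
  spec <- coarse_spec()
  geo <- make_label_phantom(spec)
  lab <- geo$atlas$labels
  present <- sort(setdiff(unique(as.vector(lab)), 0L))
  expect_identical(present, 1:26)          # every region, both hemispheres
  expect_true(all(geo$mask$mask[lab != 0L]))
  # mirroring the label volume swaps left and right labels exactly
  img <- image_volume(array(as.numeric(lab), dim = dim(lab)), spec$grid)
  flipped <- flip_lr(img, "nearest")$values
  swapped <- array(0, dim = dim(lab))
  odd <- lab %% 2L == 1L & lab > 0L
  even <- lab %% 2L == 0L & lab > 0L
  swapped[odd] <- lab[odd] + 1L
  swapped[even] <- lab[even] - 1L
  expect_identical(as.integer(flipped), as.integer(swapped))
})

test_that("labels match a point-in-ellipsoid oracle voxel-for-voxel", {
  spec <- coarse_spec()
  geo <- make_label_phantom(spec)
  co <- bregma:::grid_coord_arrays(spec$grid)
  reg <- spec$regions
  oracle <- array(0L, dim = spec$grid$dims)
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    ins <- ((co$x - r$cx) / r$rx)^2 + ((co$y - r$cy) / r$ry)^2 +
      ((co$z - r$cz) / r$rz)^2 <= 1
    if (r$cx > 0)
      ins <- ins | (((co$x + r$cx) / r$rx)^2 + ((co$y - r$cy) / r$ry)^2 +
                      ((co$z - r$cz) / r$rz)^2 <= 1)
    oracle[ins & co$x > 0] <- 2L * i
    oracle[ins & co$x < 0] <- 2L * i - 1L
  }
  expect_identical(as.integer(geo$atlas$labels), as.integer(oracle))
})

test_that("overlapping geometry is rejected", {
  bad <- bregma:::PHANTOM_REGIONS
  bad$cx[2] <- bad$cx[3]; bad$cy[2] <- bad$cy[3]; bad$cz[2] <- bad$cz[3]
  spec <- coarse_spec(regions = bad)
  expect_error(make_label_phantom(spec), "overlapping")
})

test_that("noise-free, blur-free subjects reproduce the profile exactly", {
  spec <- coarse_spec(profile = uptake_profile("flumazenil"),
                      psf_fwhm = 0, noise_sd = 0)
  geo <- make_label_phantom(spec)
  img <- simulate_subject(spec, subject_seed = 1, geometry = geo)
  rs <- region_stats(img, geo$atlas)
  expect_equal(rs$mean_suv, spec$profile$mean, tolerance = 1e-12)
  expect_equal(rs$mean_suv[rs$region == "cortex"], 0.87)
  expect_equal(rs$mean_suv[rs$region == "medulla"], 0.29)
  expect_equal(rs$rl_ratio, rep(1, 13), tolerance = 1e-12)
})

test_that("a focal lesion raises the right side by the geometric overlap", {
  spec <- coarse_spec(psf_fwhm = 0, noise_sd = 0)
  geo <- make_label_phantom(spec)
  les <- lesion_spec(center = c(3.3, 0, -3.4), radius = 1, multiplier = 2)
  img <- simulate_subject(spec, lesion = les, subject_seed = 1,
                          geometry = geo)
  rs <- region_stats(img, geo$atlas)
  cp <- rs[rs$region == "caudate_putamen", ]
  # analytic overlap: lesion voxels inside the right caudate-putamen
  co <- bregma:::grid_coord_arrays(spec$grid)
  r <- spec$regions[spec$regions$region == "caudate_putamen", ]
  in_cp_right <- (((co$x - r$cx) / r$rx)^2 + ((co$y - r$cy) / r$ry)^2 +
                    ((co$z - r$cz) / r$rz)^2 <= 1) & co$x > 0
  in_les <- ((co$x - 3.3)^2 + co$y^2 + (co$z + 3.4)^2) <= 1
  frac <- sum(in_cp_right & in_les) / sum(in_cp_right)
  base <- spec$profile$mean[spec$profile$region == "caudate_putamen"]
  expect_equal(cp$suv_right, base * (1 + frac), tolerance = 1e-9)
  expect_equal(cp$suv_left, base, tolerance = 1e-12)
  expect_equal(cp$rl_ratio, 1 + frac, tolerance = 1e-9)
  expect_gt(frac, 0)
})

test_that("diffuse lesions scale whole regions bilaterally", {
  spec <- coarse_spec(psf_fwhm = 0, noise_sd = 0)
  geo <- make_label_phantom(spec)
  les <- lesion_spec(regions = c("medulla", "pons"), multiplier = 1.5)
  img <- simulate_subject(spec, lesion = les, subject_seed = 1,
                          geometry = geo)
  rs <- region_stats(img, geo$atlas)
  prof <- spec$profile
  for (rg in c("medulla", "pons"))
    expect_equal(rs$mean_suv[rs$region == rg],
                 1.5 * prof$mean[prof$region == rg], tolerance = 1e-12)
  expect_equal(rs$mean_suv[rs$region == "cortex"],
               prof$mean[prof$region == "cortex"], tolerance = 1e-12)
  expect_error(lesion_spec(multiplier = 0), "multiplier")
  expect_error(simulate_subject(spec, lesion_spec(regions = "nope"),
                                1, geo), "unknown lesion region")
})

test_that("cohorts are reproducible and independent across subjects", {
  spec <- coarse_spec(noise_sd = 0.05, subject_variability_sd = 0.1)
  c1 <- simulate_cohort(spec, n = 3, cohort_seed = 11)
  c2 <- simulate_cohort(spec, n = 3, cohort_seed = 11)
  for (i in 1:3)
    expect_identical(c1$images[[i]]$values, c2$images[[i]]$values)
  expect_gt(max(abs(c1$images[[1]]$values - c1$images[[2]]$values)), 0)
  c3 <- simulate_cohort(spec, n = 3, cohort_seed = 12)
  expect_gt(max(abs(c1$images[[1]]$values - c3$images[[1]]$values)), 0)
  expect_length(simulate_cohort(spec, n = 19, cohort_seed = 1)$images, 19L)
})

test_that("cohort means converge to profile means (law of large numbers)", {
  spec <- coarse_spec(psf_fwhm = 0, noise_sd = 0.05,
                      subject_variability_sd = 0.1)
  coh <- simulate_cohort(spec, n = 25, cohort_seed = 123)
  tab <- cohort_voi_table(coh$images, coh$atlas)
  sem <- tab$sd_suv / sqrt(25)
  prof <- spec$profile
  # lognormal(0, 0.1) has mean exp(0.005): allow that bias plus 2 SEM
  expect_true(all(abs(tab$mean_suv - prof$mean * exp(0.1^2 / 2)) <
                    2.5 * sem + 0.01))
})

test_that("cohort SD scales linearly with the variability parameter", {
  rel_sd <- vapply(c(0.05, 0.1, 0.2), function(sv) {
    spec <- coarse_spec(psf_fwhm = 0, noise_sd = 0,
                        subject_variability_sd = sv)
    coh <- simulate_cohort(spec, n = 12, cohort_seed = 500)
    tab <- cohort_voi_table(coh$images, coh$atlas)
    median(tab$sd_suv / tab$mean_suv)
  }, 1)
  expect_equal(rel_sd[2] / rel_sd[1], 2, tolerance = 0.5)
  expect_equal(rel_sd[3] / rel_sd[2], 2, tolerance = 0.5)
  expect_true(all(diff(rel_sd) > 0))
})

test_that("misaligned cohorts return their applied transforms", {
  spec <- coarse_spec(noise_sd = 0.02)
  ms <- misalignment_spec(seed = 6)
  coh <- simulate_cohort(spec, n = 2, cohort_seed = 3, misalign = ms)
  expect_length(coh$misalignments, 2L)
  expect_s3_class(coh$misalignments[[1]], "affine_transform")
  # undoing the stored transform restores the unmisaligned subject
  plain <- simulate_cohort(spec, n = 2, cohort_seed = 3)
  undone <- apply_transform(coh$images[[1]],
                            invert_affine(coh$misalignments[[1]]))
  msk <- plain$mask$mask
  expect_gt(cor(undone$values[msk], plain$images[[1]]$values[msk]), 0.98)
})
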