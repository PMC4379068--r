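# Digital rat-brain phantom: stylized ellipsoidal geometry for the 13
# bilateral composite regions inside a brain shell, region-wise tracer
# uptake with inter-subject variability, camera-like PSF blur, additive
# noise, and focal/diffuse lesion injection.  Geometry is mirror-symmetric
# about the mid-sagittal plane x = 0 and placed at approximate stereotaxic
# centroids; the fidelity target is the statistical structure of real
# cohorts (regional means and variability), not anatomical shape.

# Right-hemisphere ellipsoid centers/radii (mm, Paxinos).  Lateral regions
# (cx > 0) get a mirrored left copy; midline regions (cx = 0) are a single
# ellipsoid split at x = 0 into hemispheric labels.
PHANTOM_REGIONS <- data.frame(
  region = c("accumbens", "amygdala", "caudate_putamen", "cerebellum",
             "cortex", "globus_pallidus", "hippocampus", "hypothalamus",
             "medulla", "midbrain", "pons", "septum", "thalamus"),
  cx = c(1.6, 4.3, 2.6, 2.2, 4.5, 3.0, 2.6, 0.9, 1.0, 1.4, 1.1, 0.7, 1.5),
  cy = c(1.6, -2.6, 0.0, -12.0, -3.7, -1.2, -4.6, -2.6, -12.2, -6.8, -9.8,
         0.4, -3.4),
  cz = c(-7.2, -7.6, -3.8, -4.5, -1.8, -6.4, -3.2, -8.6, -7.2, -5.2, -7.8,
         -5.6, -5.6),
  rx = c(0.9, 1.0, 1.4, 1.9, 1.2, 0.9, 1.1, 0.8, 0.8, 1.2, 1.0, 0.6, 1.3),
  ry = c(1.1, 1.4, 2.0, 1.7, 5.2, 1.0, 1.7, 1.6, 1.1, 1.6, 1.25, 1.3, 1.4),
  rz = c(0.9, 1.0, 1.6, 1.9, 1.5, 0.9, 1.0, 0.9, 0.9, 1.3, 1.1, 1.1, 1.1),
  stringsAsFactors = FALSE)

# Brain shell ellipsoid: center / radii in mm (a rat brain is roughly
# 14 x 21 x 12 mm), leaving field-of-view margins on the canonical grids.
PHANTOM_BRAIN <- list(center = c(0, -4.8, -4.2), radii = c(7.2, 10.4, 6.2))

# Regional mean SUV and between-subject SD per tracer, for the 13 bilateral
# composites (VOI analysis of the template cohorts).  FDG and HMPAO values
# are relative to the whole-brain mean.
UPTAKE_TABLE <- local({
  reg <- PHANTOM_REGIONS$region
  mk <- function(mean, sd) data.frame(region = reg, mean = mean, sd = sd,
                                      stringsAsFactors = FALSE)
  list(
    fdg = mk(c(1.06, 0.78, 1.28, 0.94, 1.09, 1.10, 1.05, 0.77, 0.90, 1.08,
               0.85, 1.05, 1.17),
             c(0.05, 0.04, 0.06, 0.07, 0.04, 0.08, 0.03, 0.06, 0.07, 0.03,
               0.10, 0.04, 0.06)),
    flumazenil = mk(c(0.63, 0.66, 0.71, 0.50, 0.87, 0.63, 0.86, 0.55, 0.29,
                      0.72, 0.34, 0.68, 0.62),
                    c(0.15, 0.13, 0.14, 0.11, 0.16, 0.14, 0.16, 0.12, 0.08,
                      0.17, 0.09, 0.14, 0.16)),
    medas = mk(c(1.00, 0.82, 1.20, 0.85, 0.87, 1.28, 0.96, 1.06, 1.20, 1.31,
                 1.40, 1.07, 1.21),
               c(0.04, 0.05, 0.03, 0.05, 0.02, 0.05, 0.01, 0.06, 0.04, 0.05,
                 0.05, 0.05, 0.04)),
    pk11195 = mk(c(0.38, 0.40, 0.33, 0.58, 0.51, 0.32, 0.36, 0.39, 0.51,
                   0.38, 0.42, 0.38, 0.36),
                 c(0.07, 0.07, 0.06, 0.14, 0.09, 0.07, 0.06, 0.07, 0.09,
                   0.08, 0.08, 0.07, 0.07)),
    raclopride = mk(c(1.50, 0.94, 2.37, 0.69, 1.02, 2.10, 0.86, 0.86, 0.80,
                      0.92, 0.82, 1.26, 1.10),
                    c(0.53, 0.35, 0.83, 0.20, 0.32, 0.84, 0.26, 0.29, 0.26,
                      0.28, 0.26, 0.46, 0.37)),
    hmpao = mk(c(0.96, 0.86, 0.94, 1.05, 1.04, 0.87, 1.13, 1.01, 0.89, 1.10,
                 0.91, 1.01, 1.07),
               c(0.08, 0.07, 0.05, 0.07, 0.03, 0.09, 0.03, 0.04, 0.07, 0.04,
                 0.05, 0.09, 0.03)))
})

#' Regional uptake profile of a tracer
#'
#' Mean SUV and between-subject SD for each of the 13 bilateral composite
#' regions, as measured on real template cohorts.  Available tracers:
#' `fdg`, `flumazenil`, `medas`, `pk11195`, `raclopride` (PET) and `hmpao`
#' (SPECT).
#'
#' @param tracer tracer name (see above).
#' @return an `uptake_profile`: data.frame `region`, `mean`, `sd` with the
#'   tracer name and modality as attributes.
#' @export
uptake_profile <- function(tracer = "pk11195") {
  tracer <- tolower(tracer)
  if (!tracer %in% names(UPTAKE_TABLE))
    stop("unknown tracer: ", tracer, " (available: ",
         paste(names(UPTAKE_TABLE), collapse = ", "), ")")
  tab <- UPTAKE_TABLE[[tracer]]
  if (any(tab$mean <= 0)) stop("uptake means must be positive")
  structure(tab, tracer = tracer,
            modality = if (tracer == "hmpao") "SPECT" else "PET",
            class = c("uptake_profile", "data.frame"))
}

#' Phantom specification
#'
#' Bundles the grid, region geometry, uptake profile and acquisition-like
#' corruption parameters of the digital phantom.
#'
#' @param grid a [volume_grid] (default the canonical small grid).
#' @param profile an [uptake_profile()].
#' @param psf_fwhm scanner point-spread FWHM in mm; `NULL` picks 1.2 mm for
#'   PET and 0.8 mm for SPECT profiles.
#' @param noise_sd additive Gaussian noise SD as a fraction of the
#'   whole-brain mean uptake (default 0.05).
#' @param subject_variability_sd region-level multiplicative lognormal
#'   variability (SD of the log), default 0.
#' @param background_uptake uptake of brain tissue outside the 13 labeled
#'   regions, as a fraction of the mean regional uptake (default 0.8).
#' @param seed base seed for subject simulation.
#' @param regions,brain geometry overrides (see `PHANTOM_REGIONS` format).
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(grid = default_grid("small"),
                         profile = uptake_profile("pk11195"),
                         psf_fwhm = NULL, noise_sd = 0.05,
                         subject_variability_sd = 0,
                         background_uptake = 0.8,
                         seed = 1L,
                         regions = PHANTOM_REGIONS,
                         brain = PHANTOM_BRAIN) {
  if (is.null(psf_fwhm))
    psf_fwhm <- if (attr(profile, "modality") == "SPECT") 0.8 else 1.2
  stopifnot(psf_fwhm >= 0, noise_sd >= 0, subject_variability_sd >= 0,
            nrow(regions) == nrow(profile))
  structure(list(grid = grid, profile = profile, psf_fwhm = psf_fwhm,
                 noise_sd = noise_sd,
                 subject_variability_sd = subject_variability_sd,
                 background_uptake = background_uptake,
                 seed = as.integer(seed),
                 regions = regions, brain = brain),
            class = "phantom_spec")
}

#' Focal or diffuse lesion specification
#'
#' A focal lesion multiplies the uptake inside a sphere at a stereotaxic
#' coordinate; a diffuse lesion multiplies the uptake of whole regions
#' (both hemispheres).
#'
#' @param center Paxinos mm coordinate of a focal lesion.
#' @param radius focal lesion radius in mm.
#' @param regions character vector of region names for a diffuse lesion.
#' @param multiplier uptake multiplier (> 0).
#' @return a `lesion_spec`.
#' @export
lesion_spec <- function(center = NULL, radius = NULL, regions = NULL,
                        multiplier = 2) {
  if (multiplier <= 0) stop("lesion multiplier must be > 0")
  focal <- !is.null(center)
  if (focal && (is.null(radius) || radius <= 0))
    stop("focal lesion needs a positive radius")
  if (!focal && is.null(regions))
    stop("specify either a focal center/radius or a region list")
  structure(list(center = center, radius = radius, regions = regions,
                 multiplier = multiplier, focal = focal),
            class = "lesion_spec")
}

# World-coordinate arrays of every voxel center of a grid.
grid_coord_arrays <- function(grid) {
  d <- grid$dims; A <- grid$affine
  i <- array(rep.int(seq_len(d[1]) - 1L, d[2] * d[3]), d)
  j <- array(rep.int(rep(seq_len(d[2]) - 1L, each = d[1]), d[3]), d)
  k <- array(rep(seq_len(d[3]) - 1L, each = d[1] * d[2]), d)
  list(x = A[1, 1] * i + A[1, 2] * j + A[1, 3] * k + A[1, 4],
       y = A[2, 1] * i + A[2, 2] * j + A[2, 3] * k + A[2, 4],
       z = A[3, 1] * i + A[3, 2] * j + A[3, 3] * k + A[3, 4])
}

inside_ellipsoid <- function(co, center, radii) {
  ((co$x - center[1]) / radii[1])^2 +
    ((co$y - center[2]) / radii[2])^2 +
    ((co$z - center[3]) / radii[3])^2 <= 1
}

#' Rasterize the phantom's label atlas and brain mask
#'
#' Deterministic: 26 labels (13 regions x 2 hemispheres; left label
#' `2i - 1`, right label `2i`), mirror-symmetric about x = 0, plus the
#' brain-shell mask.  Voxels exactly on the mid-sagittal plane stay
#' background so that mirroring is an exact left-right label swap.
#' Overlapping region geometry is an error.
#'
#' @param spec a [phantom_spec].
#' @return list with `atlas` (a [label_atlas]) and `mask` (a [brain_mask]).
#' @export
make_label_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  co <- grid_coord_arrays(spec$grid)
  lab <- array(0L, dim = spec$grid$dims)
  reg <- spec$regions
  for (i in seq_len(nrow(reg))) {
    r <- reg[i, ]
    if (r$cx > 0) {
      right <- inside_ellipsoid(co, c(r$cx, r$cy, r$cz), c(r$rx, r$ry, r$rz))
      left <- inside_ellipsoid(co, c(-r$cx, r$cy, r$cz), c(r$rx, r$ry, r$rz))
    } else {
      inside <- inside_ellipsoid(co, c(0, r$cy, r$cz), c(r$rx, r$ry, r$rz))
      right <- inside & co$x > 0
      left <- inside & co$x < 0
    }
    right <- right & co$x > 0
    left <- left & co$x < 0
    if (any(lab[right | left] != 0L))
      stop("overlapping region geometry at '", r$region, "'")
    lab[left] <- 2L * i - 1L
    lab[right] <- 2L * i
  }
  mask <- inside_ellipsoid(co, spec$brain$center, spec$brain$radii)
  if (any(lab != 0L & !mask))
    stop("region geometry extends outside the brain shell")
  names_df <- data.frame(
    label = as.integer(t(cbind(2L * seq_len(nrow(reg)) - 1L,
                               2L * seq_len(nrow(reg))))),
    region = rep(reg$region, each = 2L),
    hemisphere = rep(c("left", "right"), nrow(reg)),
    stringsAsFactors = FALSE)
  list(atlas = label_atlas(lab, spec$grid, names_df),
       mask = brain_mask(mask, spec$grid))
}

#' Simulate one subject's tracer-uptake volume
#'
#' Piecewise-constant uptake (profile mean per region, a background level
#' elsewhere in the brain) times a per-region lognormal subject effect and
#' an optional lesion multiplier, convolved with the Gaussian PSF, plus
#' voxelwise Gaussian noise with SD `noise_sd * whole-brain mean`.
#' Deterministic for a fixed `subject_seed`; the global RNG state is left
#' untouched.
#'
#' @param spec a [phantom_spec].
#' @param lesion optional [lesion_spec].
#' @param subject_seed integer seed for this subject.
#' @param geometry optional precomputed [make_label_phantom()] output
#'   (computed on the fly otherwise).
#' @return an [image_volume].
#' @export
simulate_subject <- function(spec, lesion = NULL, subject_seed = spec$seed,
                             geometry = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(geometry)) geometry <- make_label_phantom(spec)
  lab <- geometry$atlas$labels
  mask <- geometry$mask$mask
  nreg <- nrow(spec$regions)
  base_means <- spec$profile$mean
  bg <- spec$background_uptake * mean(base_means)
  with_local_seed(as.integer(subject_seed %% 2147483629), {
    mult <- if (spec$subject_variability_sd > 0)
      stats::rlnorm(nreg + 1L, 0, spec$subject_variability_sd)
    else rep(1, nreg + 1L)
    # per-voxel uptake: lookup by label (left/right share the region effect)
    lut <- c(bg * mult[nreg + 1L], rep(base_means * mult[seq_len(nreg)],
                                       each = 2L))
    vals <- array(0, dim = spec$grid$dims)
    vals[mask] <- lut[lab[mask] + 1L]
    if (!is.null(lesion)) {
      if (lesion$focal) {
        co <- grid_coord_arrays(spec$grid)
        inside <- ((co$x - lesion$center[1])^2 +
                   (co$y - lesion$center[2])^2 +
                   (co$z - lesion$center[3])^2) <= lesion$radius^2
        vals[inside] <- vals[inside] * lesion$multiplier
      } else {
        ridx <- match(lesion$regions, spec$regions$region)
        if (anyNA(ridx)) stop("unknown lesion region(s)")
        sel <- lab %in% c(2L * ridx - 1L, 2L * ridx)
        vals[sel] <- vals[sel] * lesion$multiplier
      }
    }
    img <- image_volume(vals, spec$grid,
                        modality = attr(spec$profile, "modality"))
    if (spec$psf_fwhm > 0) img <- smooth_gaussian(img, spec$psf_fwhm)
    if (spec$noise_sd > 0) {
      sd_abs <- spec$noise_sd * mean(img$values[mask])
      img <- image_volume(img$values +
                            array(stats::rnorm(length(img$values), 0, sd_abs),
                                  dim = spec$grid$dims),
                          spec$grid, img$modality)
    }
    img
  })
}

#' Simulate a cohort of subjects
#'
#' `n` independent subjects from the same phantom specification, with
#' subject seeds derived deterministically from `cohort_seed`.  Optionally
#' each subject is additionally misaligned by a random transform drawn from
#' a [misalignment_spec] (emulating un-normalized raw data); the applied
#' transforms are returned alongside.
#'
#' @param spec a [phantom_spec].
#' @param n number of subjects (>= 1).
#' @param lesion optional [lesion_spec] applied to every subject.
#' @param cohort_seed integer seed.
#' @param misalign optional [misalignment_spec]; draws one `"combined"`
#'   misalignment per subject.
#' @return list with `images` (list of [image_volume]s), `atlas`, `mask`,
#'   and `misalignments` (list of `affine_transform` or `NULL`).
#' @export
simulate_cohort <- function(spec, n, lesion = NULL, cohort_seed = spec$seed,
                            misalign = NULL) {
  stopifnot(n >= 1L)
  geometry <- make_label_phantom(spec)
  images <- vector("list", n)
  mis <- vector("list", n)
  for (i in seq_len(n)) {
    s_i <- misalign_seed(cohort_seed, i, "translate", 1L) %% 2147483629
    images[[i]] <- simulate_subject(spec, lesion, s_i, geometry)
    if (!is.null(misalign)) {
      t_i <- sample_misalignment(misalign, "combined", image_id = i,
                                 replicate = 1L)
      images[[i]] <- apply_transform(images[[i]], t_i)
      mis[[i]] <- t_i
    }
  }
  list(images = images, atlas = geometry$atlas, mask = geometry$mask,
       misalignments = mis)
}
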