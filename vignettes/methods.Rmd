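---
title: "Tracer-specific rat brain templates: models, validation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracer-specific rat brain templates: models, validation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bregma)
```

## The problem

Small-animal PET and SPECT brain studies rarely come with a same-session
structural scan, so individual functional volumes must be normalized
directly into a common stereotaxic space before any group analysis.
Cross-modality normalization of a functional image onto an MRI template is
fragile for tracers whose uptake carries little anatomy (a microglia
ligand in a healthy brain is almost featureless).  The remedy implemented
here is the *tracer-specific template*: a symmetric average of healthy
scans of the same tracer, itself anchored once in stereotaxic (Paxinos)
space, so that every future scan needs only an easy intra-modal
registration.

All coordinates in the package are bregma-centered Paxinos millimeters:
+x toward the animal's right, +y anterior, +z dorsal.  Voxel indices are
0-based, voxel *centers* map to world points, and the canonical
acquisition grids are 96x120x96 ("small", cropped to the skull) and
150x150x150 ("large") at 0.2 mm isotropic, with the 180-cube preparation
grid accepted as input.

## Template construction

`build_template()` runs the three construction steps in order:

1. **Intra-modal alignment** (`align_cohort`): every cohort image is
   affinely registered to one representative scan by minimizing the mean
   squared intensity difference (SSD) and resampled onto its grid.  The
   representative is an explicit argument (default the first image;
   `suggest_representative()` proposes the scan with median squared
   distance to the others).
2. **Symmetric averaging** (`voxelwise_average` + `symmetrize`): the
   voxelwise mean is mirrored about the mid-sagittal plane x = 0, the
   mirrored copy is affinely registered back onto the original, and the
   two are averaged.  Averaging the original with its registered mirror is
   the standard symmetrization; the combination rule (arithmetic mean) is
   recorded provenance.
3. **Reference anchoring** (`coregister_to_reference`): a rigid-body
   (6 dof) registration driven by normalized mutual information,
   NMI = (H(A)+H(B))/H(A,B), maps the symmetric average onto a reference
   volume already in Paxinos space (typically a T2 MRI template).  NMI
   tolerates arbitrary monotone contrast differences, which is exactly
   what a PET-to-MRI match needs.  The resulting transform is composed
   into every subject's transform, so each raw scan can be placed in
   template space in a single resampling.

When no reference is supplied the template stays in the representative's
space; mid-sagittal symmetry of the result is then only meaningful if the
cohort was already stereotaxically aligned.

### Registration machinery

Both costs run on a coarse-to-fine resolution pyramid (factor 2 per
level).  The SSD cost is minimized by damped Gauss-Newton
(Levenberg-Marquardt) on the per-voxel residuals with finite-difference
Jacobians; the NMI cost, whose histogram construction is not a smooth sum
of residuals, uses Nelder-Mead.  The initial plan was derivative-free
minimization for both; it was abandoned for SSD after measuring an order
of magnitude more cost evaluations for visibly worse optima on the 12-dof
problem.  Transforms are parameterized as `T . Rz . Ry . Rx . Shear .
Scale` about bregma, with Euler angles in degrees; 6/9/12-dof subsets are
selected by `reg_control(dof = )`.  Monotone improvement is guaranteed:
if the optimizer ends above the initial cost the initial transform is
returned with `converged = FALSE`.

Two numerical effects discovered on the digital phantoms are worth
knowing about, because they afflict any SSD pipeline:

- **Noise-blur bias.**  The SSD between two *noisy* images is lowered by
  any sub-voxel offset, because trilinear interpolation averages the
  moving image's noise.  Left alone this produced a spurious ~0.8 degree
  tilt in the symmetrization step.  The construction registrations
  therefore smooth both images by 4 mm *inside the data term only* (the
  aligned outputs are always resampled from the originals), as SPM's
  affine normalization has always done.
- **Boundary halos.**  Smoothing with a kernel comparable to the
  field-of-view margin does not commute with a misalignment unless the
  field is padded: both mirror-reflection and zero-truncation create
  image-specific halos that moved the SSD optimum several degrees away
  from the truth.  The validation protocol smooths on a zero-padded grid
  (exact full-kernel smoothing), computed multirate for speed
  (`smooth_padded`): anti-alias at native resolution, then the remainder
  of the kernel on a grid coarsened to about sigma/8 and padded by two
  sigma.  Re-registration runs on that grid.

## Registration-error validation

`evaluate_registration_error()` quantifies how well spatial normalization
recovers a known perturbation.  Each already-normalized image undergoes
40 random misalignments — 10 translations (uniform within +/-0.5 mm per
axis), 10 rotations (+/-20 degrees), 10 anisotropic scalings (+/-10%),
and 10 combined misalignments with rotation reduced to +/-10 degrees —
applied about bregma.  Each misaligned volume is smoothed with an 8 mm
Gaussian and re-registered to the template by 12-dof SSD affine least
squares.  The error of one trial is the mean over brain-mask voxels of
the Euclidean displacement between a voxel's original world position and
its position after misalignment-plus-recovery (in mm; the norm is the
natural reading of the summed squared coordinate differences).  For pure
translations this reduces to the uncompensated translation norm and is
mask-independent; for rotations and scalings it grows with the mask
radius.

Choices the protocol fixes (all configurable):

- misalignments are drawn as continuous uniforms with a deterministic
  per-(seed, image, kind, replicate) sub-seed; `quantize = TRUE` rounds to
  0.1 mm / 1 degree / 1% to mimic integer pseudo-random draws;
- rotations and scalings act about bregma (the source protocol is silent
  on the center);
- the 8 mm kernel is taken at face value in rat-brain millimeters;
- the re-registration data term is restricted to the brain mask dilated
  by 4 mm (`cost_mask_dilate_mm = NULL` restores whole-volume SSD); the
  mask defaults to Otsu thresholding of the template when not supplied.

On the stock phantom world (PET-like cohort of 6, 5% noise, 10% regional
variability, matched-size template) the protocol's mean error is about
0.36 mm, with per-kind means 0.29-0.43 mm — below the 1.4 mm PET
resolution bound, and in the same regime as published per-tracer errors
on real cohorts.  After heavy smoothing the brain is close to an
ellipsoidal blob, so sagittal-plane tilt and other near-degenerate affine
directions dominate the residual error; that, not optimizer failure, is
the error floor (continuing the optimization from the true transform
walks to the same few-tenths-of-a-millimeter solutions).

## VOI statistics

`region_stats()` aggregates an image over an integer label atlas of 13
bilateral composite regions (accumbens, amygdala, caudate-putamen,
cerebellum, cortex, globus pallidus, hippocampus, hypothalamus, medulla,
midbrain, pons, septum, thalamus; independent left/right labels).  The
bilateral mean is volume-weighted (the unweighted alternative is not
distinguishable from published tables; weighted was chosen as the one
consistent with whole-brain decomposition, which is tested exactly).
Right-to-left asymmetry is right/left.  `whole_brain_normalize()` divides
by the brain-mask mean — applied to tracers reported relative to global
uptake (FDG, HMPAO).

## Voxel-based analysis

`two_sample_tmap()` smooths with a 1.2 mm isotropic Gaussian (no global
normalization), then computes a pooled-variance two-sample t statistic of
intervention minus control per voxel.  `threshold_and_cluster()` keeps the
one-sided suprathreshold voxels at p = 0.001 (uncorrected) and forms
18-connected components (SPM's convention; 6/26 available), discarding
those under 200 voxels.  `cluster_fwe()` controls the family-wise error by
permutation: group labels are reshuffled, the t-map is rethresholded
identically, and the maximal cluster extent is recorded; a cluster's
FWE p is the add-one-smoothed proportion of permutations whose maximum
reaches its extent.  Random-field theory (the source of the published
p-values) is deliberately out of scope — the permutation test is exact
under exchangeability and needs no smoothness estimate — so only the
alpha = 0.05 significance *decisions* are comparable.  Peak coordinates
are reported in Paxinos mm to one decimal, at most three local peaks at
least 8 mm apart per cluster; `mip_glass_brain()` draws the standard
three-view maximum-intensity projection with the mask outline.

## The digital phantom

`phantom_spec()`/`simulate_subject()` generate the synthetic world every
other module is tested against.  The 13 bilateral regions are stylized
ellipsoids at approximate stereotaxic centroids inside a 14 x 21 x 12 mm
brain shell; geometry is exactly mirror-symmetric about x = 0 and was
chosen once so that regions are disjoint, inside the shell, and leave
realistic field-of-view margins on the canonical grids.  A subject is

1. piecewise-constant uptake: the tracer profile mean per region
   (published cohort means for fdg, flumazenil, medas, pk11195,
   raclopride, hmpao), a background at 0.8 of the mean regional uptake
   elsewhere in the brain;
2. times a per-region lognormal subject effect (sigma on the log scale =
   `subject_variability_sd`, shared by the two hemispheres);
3. times an optional lesion multiplier (focal sphere at a stereotaxic
   coordinate, or whole regions for a diffuse model);
4. convolved with a Gaussian PSF (1.2 mm PET-like, 0.8 mm SPECT-like);
5. plus voxelwise Gaussian noise with SD = `noise_sd` x whole-brain mean
   (post-reconstruction noise is approximately Gaussian; projection-domain
   simulation is out of scope).

Defaults are 5% noise and 10% regional variability — the regime of the
published cohort tables, whose relative SDs average ~18%.  What the
phantom does *not* emulate: anatomical shape, partial-volume structure at
region boundaries, attenuation/scatter artifacts, inter-subject anatomical
(as opposed to intensity) variability.  A green registration test on the
phantom therefore establishes the correctness and stability of the
machinery under realistic intensity statistics, not performance on real
anatomy; conversely the phantom's post-smoothing blobbiness makes some
affine directions *harder* than real data, since real brains carry more
orientation-anchoring texture.

Degenerate-input behavior worth knowing: symmetrization registers the
mirrored average back onto the original, which is only meaningful for
near-symmetric images — for a strongly one-sided image the SSD optimum
may legitimately translate the mirror onto the original rather than keep
it mirrored.  Constant images are rejected by NMI (degenerate histogram)
and produce `converged = FALSE` from SSD.

## Reproducibility

Every stochastic element (phantom subjects, misalignment draws,
permutations) derives from explicit integer seeds through local RNG
scopes that never disturb the session's generator; identical seeds give
bit-identical volumes and CSV outputs.  The command-line interface
(`bregma_main()`; subcommands simulate, build-template, validate,
voi-report, vba) writes a manifest JSON with the resolved configuration,
input MD5 hashes and package version for every run.
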