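# bregma

Tracer-specific brain templates, registration validation and voxel-based
group analysis for small-animal PET/SPECT, in bregma-centered stereotaxic
(Paxinos) coordinates.

## Who this is for

Preclinical imaging groups analyzing rat brain PET or SPECT volumes
without an accompanying structural scan.  Cross-modality normalization of
a functional image onto an MRI template fails for tracers with little
anatomical contrast; the robust alternative is an intra-modal
registration to a *tracer-specific template* — a symmetric average of
healthy scans of the same tracer, anchored once in Paxinos space.  This
package builds such templates, quantifies how accurately images register
to them, and runs the downstream region-of-interest and voxelwise group
statistics, all exercisable end-to-end on a built-in digital phantom (no
scanner data required).

## What it computes

- **Template construction** (`build_template`): (1) every cohort image is
  affinely registered to a representative scan by sum-of-squared-
  differences (SSD) minimization; (2) the voxelwise average is mirrored
  about the mid-sagittal plane, the mirror registered back and averaged,
  giving a symmetric template; (3) a rigid-body registration maximizing
  normalized mutual information, NMI = (H(A)+H(B))/H(A,B), anchors the
  template to a reference volume in Paxinos space and is propagated to
  every subject.
- **Registration-error validation** (`evaluate_registration_error`): each
  normalized image undergoes 40 random misalignments about bregma — 10
  translations (±0.5 mm), 10 rotations (±20°), 10 anisotropic scalings
  (±10%), 10 combined (rotation ±10°) — is smoothed at 8 mm and
  re-registered by 12-dof SSD affine least squares.  The reported error is
  the brain-mask average of ‖p′ − p‖, where p′ is a voxel's position
  after misalignment plus recovery (mm).
- **VOI statistics** (`region_stats`, `cohort_voi_table`): mean uptake and
  right/left asymmetry ratios over 13 bilateral composite regions, with
  optional whole-brain normalization.
- **Voxel-based analysis** (`two_sample_tmap`, `threshold_and_cluster`,
  `cluster_fwe`): 1.2 mm smoothing, pooled-variance two-sample t-maps,
  one-sided p = 0.001 thresholding with a 200-voxel extent,
  permutation-based cluster-level family-wise-error control, Paxinos peak
  tables and glass-brain maximum-intensity projections.
- **Digital phantom** (`simulate_cohort`): ellipsoidal 13-region rat brain
  with published per-tracer regional uptake profiles, lognormal
  between-subject variability, Gaussian PSF blur, additive noise, and
  focal/diffuse lesion injection.

I/O is NIfTI-1 (`read_volume`/`write_volume`, `.nii`/`.nii.gz`); the
file affine is the voxel-to-Paxinos-mm map.

## Worked example

Simulate a PET-like cohort, build its template, and validate registration
accuracy (this is exactly what `scripts/acceptance.R` runs):

```r
library(bregma)

spec <- phantom_spec(profile = uptake_profile("pk11195"),
                     grid = default_grid("small"), psf_fwhm = 1.2,
                     noise_sd = 0.05, subject_variability_sd = 0.1)
cohort <- simulate_cohort(spec, n = 6, cohort_seed = 1)
built  <- build_template(cohort$images, representative_index = 1,
                         tracer = "pk11195")
report <- evaluate_registration_error(cohort$images, built$template$volume,
                                      mask = cohort$mask,
                                      spec = misalignment_spec(seed = 1))
print(report)
```

```
       kind  mean    sd    min   max
1 translate 0.329 0.158 0.0256 0.679
2    rotate 0.291 0.155 0.1153 0.827
3     scale 0.386 0.225 0.1319 1.430
4  combined 0.425 0.345 0.0719 1.737
overall mean: 0.3577 mm
```

Every misalignment is recovered to a mean residual displacement of a few
tenths of a millimeter — well below the ~1.4 mm spatial resolution of a
small-animal PET camera, i.e. normalization error is not the limiting
factor of the analysis.  Regional quantification on a noise-free,
blur-free flumazenil phantom reproduces its uptake profile exactly:

```r
spec0 <- phantom_spec(profile = uptake_profile("flumazenil"),
                      psf_fwhm = 0, noise_sd = 0)
geo <- make_label_phantom(spec0)
rs <- region_stats(simulate_subject(spec0, geometry = geo), geo$atlas)
rs[rs$region %in% c("cortex", "medulla"), c("region", "mean_suv", "rl_ratio")]
#>    region mean_suv rl_ratio
#>    cortex     0.87        1
#>   medulla     0.29        1
```

## Command line

```sh
inst/cli/bregma simulate --tracer pk11195 --n 6 --grid small --seed 1 --out-dir sim/
inst/cli/bregma build-template --images sim/subject_*.nii.gz --out-dir tpl/
inst/cli/bregma validate --images sim/subject_*.nii.gz \
    --template tpl/template.nii.gz --mask sim/mask.nii.gz --seed 1 --out-dir val/
inst/cli/bregma voi-report --images sim/subject_*.nii.gz \
    --atlas sim/atlas.nii.gz --names sim/atlas_names.tsv --out-dir voi/
inst/cli/bregma vba --group-a ctrl/*.nii.gz --group-b lesion/*.nii.gz \
    --mask sim/mask.nii.gz --perms 1000 --seed 7 --out-dir vba/
```

Every run writes a `manifest.json` with the resolved configuration, seeds
and input hashes; identical seeds give bit-identical outputs.

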