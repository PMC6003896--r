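---
title: "Quantifying the lung shunt fraction for Y-90 radioembolization planning"
author: "shuntQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the lung shunt fraction for Y-90 radioembolization planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shuntQuant)
```

## The problem

Before transarterial radioembolization (TARE) of hepatic tumors with Y-90
microspheres, the fraction of injected particles that shunts from the liver
to the lungs must be estimated from a surrogate Tc-99m-MAA scan, because the
lungs tolerate only a limited absorbed dose (the conventional eligibility
limit is 30 Gy). The lung shunt fraction (LSF) is defined on image counts,

$$\mathrm{LSF} = 100 \times
  \frac{C_\mathrm{lung}}{C_\mathrm{lung} + C_\mathrm{liver}},$$

and the predicted lung absorbed dose follows the MIRD formalism for Y-90,

$$D_\mathrm{lung}\,[\mathrm{Gy}] = 49.38 \times
  \frac{A\,[\mathrm{GBq}]}{m_\mathrm{lung}\,[\mathrm{kg}]} \times
  \mathrm{LSF}_\mathrm{fraction}.$$

Planar scintigraphy, the standard of care, measures the counts without
attenuation or scatter correction and therefore overestimates the LSF:
liver counts are suppressed by roughly 10 cm of overlying soft tissue while
lung counts pass through low-density (0.3 kg/L) lung. Quantitative SPECT/CT
with CT-based attenuation correction (AC) and energy-window scatter
correction (SC) removes most of this bias and supplies the patient's lung
volume (hence mass) for dosimetry. This package implements the complete
chain needed to study that comparison in silico: a digital torso phantom
with known shunt, a planar/SPECT simulator with OSEM reconstruction and
independently toggleable AC and SC, the CT/SPECT auto-contouring workflow,
MIRD dosimetry, and the paired statistics for a packaged 40-patient cohort
table of planar, SPECT/CT and post-therapy PET/CT shunt estimates.

## The digital phantom

The physical reference object is a fillable liver/lung torso phantom whose
published filling data are activity *concentrations* (lungs 3 kBq/mL,
normal liver 140 or 65 kBq/mL depending on the configured shunt level,
lesions 390 kBq/mL), the three true shunt levels (0, 3.6 and 6.9%), and the
total activity (195 MBq at the 3.6% configuration). Compartment volumes are
not published, but they are fully determined by those constraints: the two
shunt equations share the lung and lesion terms and differ only in the
normal-liver concentration, leaving a 2x2 linear system once the lung
volume is fixed by the total-activity constraint.

```{r solver}
specs <- solvePhantomVolumes()
specs$lsf3.6
```

`buildPhantom()` voxelizes a specification with parametric geometry: an
elliptic-cylinder soft-tissue body (half-axes 175 x 115 mm), a cylindrical
bone spine, two ellipsoidal lungs, and a liver ellipsoid carrying a
spherical and an ellipsoid lesion. Only volumes and concentrations are
constrained by the published data; shapes are design choices. Each
compartment is scaled until its voxelized volume matches the target
(typically well under 0.5%), so the ground-truth shunt of the grid matches
the specification. Density is mapped to a synthetic CT through
HU = 1000 (rho - 1), giving about -700 HU in lung, -999 in air and +500 in
bone, which is what the segmentation stage consumes. The default grid is
128 x 128 x 110 at 4 mm; the simulation studies in the tests use
64 x 64 x 64 at 6.4 mm, which covers the same 41-cm field of view at a
desk-scale runtime (a full three-level, three-realization experiment with
all reconstructions runs in about two and a half minutes on one CPU).

Respiratory motion is modeled by `applyBreathingBlur()`, a Gaussian smear
of the activity along the superior-inferior axis only, with a
column-normalized kernel so activity is conserved exactly. The sigma of
this blur is the *time-averaged* positional spread, not the diaphragm
excursion: for quiet tidal breathing with 1.5-2.5 cm peak-to-peak liver
travel, the RMS of a sinusoidal trajectory is roughly 4-9 mm, which is the
default range sampled by `CohortSpec` for synthetic patients.

## The scanner simulator

`projectSpect()` and `projectPlanar()` implement a rotation-based
parallel-beam model. Per view, the volume is resampled into the gantry
frame with a sparse bilinear *splat* operator (the transpose of gather
resampling, chosen so each view conserves total activity exactly), each
voxel is weighted by its attenuation factor toward the detector
(trapezoidal line integral of mu, with mu = 0.154 cm^-1 per unit density,
clipped at 0.25 cm^-1 for bone), and depth planes are accumulated through a
depth-dependent Gaussian collimator response with FWHM = 4 mm + 0.05 x
depth, evaluated in bins of four depth planes for tractable runtime. The
backprojector is the exact transpose of every factor, so the adjoint
identity holds to numerical precision — this is what makes the OSEM
fixed-point argument valid, and it is tested to 1e-6.

Scatter is modeled in projection space: the photopeak acquires an additive
component equal to the primary convolved with a broad Gaussian (sigma
40 mm) times a scatter fraction of 0.3, and the adjacent low-energy window
records the same blurred primary scaled by scatter fraction / k with
k = 0.5, the conventional dual-energy-window weighting. The window
magnitude is calibrated so that k times the window is an unbiased estimate
of the photopeak scatter; an uncalibrated window (as would arise from a
mismatched k) simply shifts part of the scatter bias between the AC-only
and AC+SC reconstructions, and both parameters are config-exposed.
Photopeak counts are scaled to the protocol targets (500k anterior planar
counts, 6M total SPECT counts) before Poisson sampling; a noise-free mode
returns the expectations. The clinic's non-circular orbit is simplified to
circular, which does not affect the corrections under study.

`osemReconstruct()` runs ordered-subsets EM (8 iterations x 4 subsets, as
in the clinic protocol) with collimator modeling always on. AC toggles the
attenuation factors inside the system model; SC adds k times the measured
scatter window to the forward projection — additive rather than
pre-subtracted, which preserves the multiplicative update's
non-negativity. An 8.4-mm FWHM Gaussian post-filter is applied last. With
no attenuation and no blur, total reconstructed counts match the per-view
sinogram counts within 1%.

## The auto-contouring workflow

The segmentation chain mirrors a clinical semi-automatic workflow:

* **Whole-body VOI** — threshold above -500 HU, morphological closing per
  axial slice with a 2-voxel disc brush (slices are zero-padded so the
  image border stays background), 3-D hole filling (which recovers the
  lungs as interior cavities), largest connected component.
* **Lung VOI** — voxels at or below a -150 HU lock inside the body;
  connected components smaller than 50 mL are discarded (the published
  workflow removes mediastinal fragments with unspecified "volume
  thresholds"; 50 mL is this package's config-exposed default); remaining
  components are assigned left/right by centroid about the body's
  mid-sagittal plane.
* **2-cm exclusion** — per lung, all voxels within 2 cm of that lung's own
  most inferior voxel are removed, rounded to whole slices (the distance
  actually removed is recorded). Per-lung measurement was chosen over a
  global plane because the two lungs' bases differ in height.
* **Liver VOI** — largest component above a preset percentage of the
  maximum counts in the emission volume, presets {0.5, 1, 2, 5, 10}%. The
  default is 2%, the modal clinical choice; when a CT-derived liver volume
  is available, auto-selection picks the preset whose volume matches best.
  On simulated reconstructions the low presets overgrow the liver,
  because the post-filtered liver edge stays above a threshold tied to the
  (much hotter) lesion maximum for several millimetres beyond the true
  boundary; the volume-matched preset lands within 10% of truth, and the
  shunt itself is insensitive to this rim because rim voxels carry little
  activity.
* **Lung count extrapolation** — total lung counts are estimated as the
  mean count density over the (excluded, in-FOV) lung VOI times the full
  CT lung volume. The same estimator serves the exclusion margin and the
  partial-field-of-view situation of post-therapy PET centered on the
  liver.

Lung *volume* (and hence mass, at 0.3 kg/L) is always taken from the full
pre-exclusion CT lung VOI; the exclusion affects counts only.

## Dosimetry

`lungDose()` evaluates the MIRD expression with the 49.38 Gy kg/GBq Y-90
constant. Because the constant absorbs the unit conversions, the shunt
must enter as a fraction; the function requires an explicit
`"percent"`/`"fraction"` tag rather than guessing from magnitude. Planar
dosimetry conventionally assumes a 1-kg standard lung; volumetric
dosimetry uses the patient's CT lung mass — the two are never silently
mixed. Multiple administrations sum.

```{r dose}
lungDose(4.377, 1, 13.6, "percent")
```

## The cohort table and statistics

`patientLSFTable()` ships the 40-patient table of per-method shunt values
(planar; SPECT/CT with no corrections, AC, AC+SC, each with and without
the exclusion; post-therapy PET/CT for the 20 patients who had it),
guarded by a value checksum against accidental edits. One AC entry
(patient 23, 0.3%) is transcribed as published but looks like a
typographical inversion with that patient's AC+SC value; no statistic in
the package depends on it. The statistics layer provides mean/range
summaries, a paired t test implemented from its definition (mean
difference over its standard error, n-1 degrees of freedom; the test suite
cross-checks it against `stats::t.test` and a sign-flip permutation test),
squared Pearson correlation, the mean of per-patient ratios (reported
separately from the ratio of means, which is substantially smaller on this
skewed distribution), and paired difference statistics.

```{r cohort}
recs <- patientLSFTable()
summarizeLSF(recs, "planar")
pairedT(recs, "spect_acsc", "pet_acsc", "pet_only")
```

Because the table prints one decimal, statistics recomputed from it can
differ in the last digit from values computed on full-precision clinic
data: the squared correlation between planar and SPECT AC+SC comes out
0.42 from the printed table (0.46 on the original data), and the
SPECT-vs-PET paired p-value 0.95 (0.968 originally). The tests assert
at tolerances that accommodate exactly this rounding provenance, and the
decisions (significant / not significant) are unaffected.

## What the simulation does and does not show

The phantom experiment (`runPhantomExperiment()`) reproduces the
qualitative structure of the physical study: planar geometric-mean
estimates exceed anterior-liver/posterior-lung estimates, both exceed
truth; uncorrected SPECT overestimates most, AC removes most of the bias,
and AC+SC lands within 15% of truth (slightly low, as energy-window SC
tends to be in the lung region); at a true shunt of zero the AC+SC
residual stays below half a point; and repeat noise realizations scatter
by far less than 10% of the mean. These are *property* reproductions: the
absolute values depend on collimator, scatter and orbit details of a
physical camera that a kernel-based simulator does not capture, so the
published phantom numbers are matched in ordering and rough magnitude, not
digit by digit.

Two honest limitations of the method itself show up in the synthetic
cohorts and are worth knowing about:

* With realistic breathing blur, the axial-slab exclusion cannot remove
  liver spill that enters the lung VOI *laterally* around the liver dome
  (the dome overlaps the lung VOI's axial range). The residual inflates
  low shunts by a few tenths of a percentage point — small in absolute
  dose terms but visible against sub-1% truths. The package therefore
  validates end-to-end parameter recovery on motion-free cohorts (exactly
  as the physical phantom study was motion-free) and characterizes the
  motion effect separately: the exclusion demonstrably lowers the estimate
  and moves it toward truth under a 15-mm blur.
* The synthetic cohort emulates volumes, concentrations, motion and count
  statistics, but not extra-hepatic uptake, MAA breakdown over time,
  manual-ROI operator variability, or real CT texture; passing tests say
  the *pipeline* is faithful under the stated physics, not that clinical
  planar-SPECT discrepancies of a given magnitude are fully explained.

## Numerical choices

* Voxel fitting targets 0.5% per compartment with a bisection fallback on
  the quantized voxel count; grids between 2 and 8 mm are supported.
* Depth-binned collimator blur (4 planes per bin) trades a slight radial
  approximation for a fourfold speedup; the adjoint is of the binned
  operator, so the identity is exact.
* OSEM guards 0/0 by flooring forward projections at a scaled epsilon and
  zeroing voxels with zero sensitivity; an all-zero sinogram reconstructs
  to an all-zero volume.
* Seeds: every stochastic step (Poisson sampling, cohort draws) takes an
  explicit seed and restores the caller's RNG state, so identical
  configurations give byte-identical reports.
* Problem sizes in the shipped tests — 64-cube grids with 60 views for the
  phantom experiment, 48-cube grids with 24 views for cohort recovery —
  were chosen as the smallest grids at which the segmentation and bias
  properties are stable.
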