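# shuntQuant

Quantification of the hepatopulmonary **lung shunt fraction (LSF)** for
Y-90 transarterial radioembolization (TARE) planning.

Before TARE, the fraction of microspheres expected to shunt from the liver
into the lungs is estimated from a Tc-99m-MAA surrogate scan, because the
lung absorbed dose limits treatment eligibility. The shunt is defined on
image counts,

    LSF = 100 × lung counts / (lung counts + liver counts),

and the predicted lung dose follows the MIRD formalism for Y-90,

    Lung dose (Gy) = 49.38 × activity (GBq) / lung mass (kg) × LSF fraction.

Planar scintigraphy (the standard of care) overestimates the shunt because
it corrects for neither attenuation nor scatter; quantitative SPECT/CT with
attenuation correction (AC) and scatter correction (SC) largely removes the
bias and supplies the CT lung volume for patient-specific dosimetry. This
package provides everything needed to study that comparison end to end, for
physicists and method developers in nuclear-medicine dosimetry:

* **Digital phantom factory** — solves the liver/lung torso phantom's
  compartment volumes from its published filling constraints (three true
  shunt levels: 0, 3.6, 6.9%; 195 MBq total), voxelizes parametric
  anatomy with matched volumes, models free-breathing motion as an axial
  Gaussian smear, and samples whole synthetic patient cohorts with known
  ground truth.
* **Scanner simulator** — planar (anterior/posterior) and SPECT projection
  with per-ray attenuation, depth-dependent collimator response and
  energy-window scatter; OSEM reconstruction (8 iterations × 4 subsets,
  8.4-mm post-filter) with AC and SC independently toggleable. The
  projector/backprojector pair is an exact adjoint.
* **Auto-contouring workflow** — whole-body VOI from CT, lung VOI under a
  −150 HU lock with left/right split and small-component cleanup, per-lung
  2-cm inferior exclusion against motion spill-in, threshold-preset liver
  VOI on the emission volume, and count-density extrapolation of total
  lung counts (also used for partial-FOV post-therapy PET).
* **Dosimetry and cohort statistics** — MIRD lung dose; a packaged
  40-patient table of planar / SPECT/CT / post-therapy PET/CT shunt values
  with paired t tests, correlation, ratio and difference statistics.

## Worked example

Build the 3.6%-shunt torso phantom, scan and reconstruct it, and run the
full patient workflow:

```r
library(shuntQuant)

specs <- solvePhantomVolumes()
specs$lsf3.6
#> PhantomSpec: true LSF 3.60% (195.0 MBq total)
#>   lungs  : 3 kBq/mL x 2340 mL
#>   liver  : 140 kBq/mL x 1243.478 mL
#>   lesions: 390 kBq/mL x 14.2 + 21.4 mL

ph  <- buildPhantom(specs$lsf3.6, voxelMM = 6.4, dims = c(64, 64, 64))
mu  <- densityToMu(ph)
cfg <- acquisitionConfig(seed = 7)
sinos <- projectSpect(ph, mu, cfg)          # Poisson, 6M counts
rec   <- osemReconstruct(sinos, mu, ac = TRUE, sc = TRUE)
report <- runPatientPipeline(syntheticCT(ph), rec, activityGbq = 3.7)
str(report[c("lsf_percent", "lung_volume_L", "lung_mass_kg", "lung_dose_gy")])
#> List of 4
#>  $ lsf_percent  : num 3.36
#>  $ lung_volume_L: num 2.34
#>  $ lung_mass_kg : num 0.702
#>  $ lung_dose_gy : num 8.75
```

The estimated shunt (3.36%) sits slightly below the 3.60% truth — the
characteristic mild underestimate of energy-window scatter correction —
while the CT-derived lung volume matches the solved 2.34 L almost exactly;
at 3.7 GBq the predicted lung dose is 8.75 Gy, far below the 30-Gy limit.
Reconstructing the same data without corrections, or quantifying the planar
views, yields the familiar overestimates (here ≈6.0% without corrections,
≈6.2% planar anterior/posterior, ≈7.9% planar geometric mean).

Cohort statistics reproduce from the packaged patient table:

```r
recs <- patientLSFTable()
unlist(summarizeLSF(recs, "planar"))[c("mean", "min", "max")]
#>  mean    min    max
#> 5.435    1.2   15.7
round(pearsonR2(recs, "planar", "spect_acsc"), 2)
#> [1] 0.42
```

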