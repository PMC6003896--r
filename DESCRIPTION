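Package: shuntQuant
Title: Lung Shunt Fraction Quantification for Y-90 Radioembolization Planning
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the hepatopulmonary shunt fraction (LSF)
    measured before and after Y-90 transarterial radioembolization. Provides a
    voxelized liver/lung torso phantom generator with ground-truth shunt
    levels, a planar and SPECT gamma-camera simulator with ordered-subsets
    expectation-maximization (OSEM) reconstruction and independently
    toggleable CT-based attenuation and dual-energy-window scatter
    corrections, a semi-automatic CT/SPECT auto-contouring workflow (body,
    lung and threshold-based liver volumes of interest with an inferior lung
    exclusion margin), MIRD-formalism lung dosimetry, and paired statistical
    comparison of planar, SPECT/CT and post-therapy PET/CT shunt estimates on
    a packaged 40-patient cohort table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    EBImage,
    igraph,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
biocViews: Software, BiomedicalInformatics, Visualization
RoxygenNote: 7.3.3
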