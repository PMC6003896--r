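## Shared fixtures, built once per test run and cached.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(name, expr) {
  if (!exists(name, .fixtureCache)) assign(name, expr, .fixtureCache)
  get(name, .fixtureCache)
}

## torso phantom at the reduced 64-cube simulation grid
torsoPhantom64 <- function(level = "lsf3.6") {
  .cached(paste0("torso64_", level), {
    buildPhantom(solvePhantomVolumes()[[level]], voxelMM = 6.4,
                 dims = c(64, 64, 64))
  })
}

## fast acquisition protocol for unit tests (structure, not physics quality)
tinyConfig <- function(...) {
  acquisitionConfig(nViews = 12, osemIterations = 3, osemSubsets = 4,
                    matrixSize = 48, ...)
}

## a small synthetic patient on a 48-cube grid
tinyPatient <- function(seed = 11) {
  .cached(paste0("patient_", seed), {
    synthCohort(CohortSpec(1, lsfMedian = 2, lsfLogSD = 0, seed = seed),
                voxelMM = 8, dims = c(48, 48, 48))$patients[[1]]
  })
}

## noise-free AC+SC reconstruction of the 3.6% torso phantom (used by the
## segmentation and quantification tests)
torsoRecon36 <- function() {
  .cached("torsoRecon36", {
    ph <- torsoPhantom64("lsf3.6")
    mu <- densityToMu(ph)
    cfg <- acquisitionConfig()
    proj <- spectProjector(dim(ph@activity), ph@spacing, cfg)
    att <- attenuationFactors(proj, mu)
    sinos <- projectSpect(ph, mu, cfg, noise = FALSE, projector = proj,
                          atten = att)
    list(phantom = ph, mu = mu, config = cfg, projector = proj, atten = att,
         sinos = sinos,
         recon = osemReconstruct(sinos, mu, ac = TRUE, sc = TRUE,
                                 projector = proj, atten = att))
  })
}
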