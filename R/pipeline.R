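## Pipeline drivers: the phantom accuracy/precision experiment and the
## per-patient CT + emission quantification chain.

#' Run the phantom accuracy/precision experiment
#'
#' For each true shunt level, builds the voxelized phantom, simulates planar
#' and SPECT acquisitions for the requested number of noise realizations,
#' reconstructs with no corrections, AC only, and AC + SC, runs the
#' auto-contouring workflow (CT lung VOI with exclusion margin, 2\%-preset
#' liver VOI on the AC + SC reconstruction), and tabulates the shunt
#' estimate of every method. The structural outcome is a per-level,
#' per-method mean and standard deviation across realizations.
#'
#' @param lsfLevels character names of the phantom configurations to run,
#'   a subset of \code{names(solvePhantomVolumes())}
#' @param nRealizations noise realizations per level
#' @param noise Poisson noise on? (\code{FALSE} gives zero SD columns)
#' @param voxelMM,dims phantom/reconstruction grid
#' @param config an \linkS4class{AcquisitionConfig}
#' @param segConfig a \linkS4class{SegmentationConfig}
#' @param seed base seed; realization r uses seed + r
#' @return list with \code{table} (level x method mean/sd data.frame) and
#'   \code{runs} (per-realization estimates)
#' @export
runPhantomExperiment <- function(lsfLevels = c("lsf0", "lsf3.6", "lsf6.9"),
                                 nRealizations = 3, noise = TRUE,
                                 voxelMM = 6.4, dims = c(64, 64, 64),
                                 config = acquisitionConfig(),
                                 segConfig = segmentationConfig(),
                                 seed = 0) {
  specs <- solvePhantomVolumes()
  if (!all(lsfLevels %in% names(specs)))
    stop("unknown phantom configuration in lsfLevels")
  methods <- c("planar_antpost", "planar_gm", "spect_noc", "spect_ac",
               "spect_acsc")

  ## geometry, attenuation and CT segmentation are shared by all levels
  ph0 <- buildPhantom(specs[[lsfLevels[1]]], voxelMM = voxelMM, dims = dims)
  mu <- densityToMu(ph0)
  projector <- spectProjector(dims, ph0@spacing, config)
  atten <- attenuationFactors(projector, mu)
  rois <- planarROIs(ph0)
  ct <- syntheticCT(ph0)
  body <- wholeBodyVOI(ct, segConfig)
  lungs <- lungVOI(ct, body, ph0@spacing, segConfig)
  excl <- excludeInferior(lungs, segConfig@exclusionMarginCM, ph0@spacing)
  lungVolL <- (sum(lungs$left) + sum(lungs$right)) *
    prod(ph0@spacing) / 1e6

  runs <- list()
  for (lv in lsfLevels) {
    ph <- buildPhantom(specs[[lv]], voxelMM = voxelMM, dims = dims)
    for (r in seq_len(nRealizations)) {
      cfg <- initialize(config, seed = seed + 1000 * match(lv, lsfLevels) + r)
      planar <- projectPlanar(ph, mu, cfg, noise = noise)
      est <- c(
        planar_antpost = lsfPercent(planarLSF(
          planar, list(ant = rois$liverAnt, post = rois$liverPost),
          list(ant = rois$lungAnt, post = rois$lungPost), "ant_post")),
        planar_gm = lsfPercent(planarLSF(
          planar, list(ant = rois$liverAnt, post = rois$liverPost),
          list(ant = rois$lungAnt, post = rois$lungPost), "geometric_mean")))
      sinos <- projectSpect(ph, mu, cfg, noise = noise,
                            projector = projector, atten = atten)
      recons <- list(
        spect_noc = osemReconstruct(sinos, mu, ac = FALSE, sc = FALSE,
                                    projector = projector),
        spect_ac = osemReconstruct(sinos, mu, ac = TRUE, sc = FALSE,
                                   projector = projector, atten = atten),
        spect_acsc = osemReconstruct(sinos, mu, ac = TRUE, sc = TRUE,
                                     projector = projector, atten = atten))
      liver <- liverVOI(recons$spect_acsc, ph@spacing, segConfig)
      liverMask <- liver$mask & !(lungs$left | lungs$right)
      for (m in names(recons)) {
        lungCounts <- estimateLungCounts(recons[[m]], excl, lungVolL,
                                         ph@spacing)
        est[m] <- lsfPercent(volumetricLSF(recons[[m]], liverMask,
                                           lungCounts))
      }
      runs[[length(runs) + 1]] <-
        data.frame(level = lv, trueLSF = specs[[lv]]@trueLSF,
                   realization = r, method = methods,
                   lsf = unname(est[methods]))
    }
  }
  runs <- do.call(rbind, runs)
  agg <- do.call(rbind, lapply(split(runs, runs[c("level", "method")]),
    function(g) data.frame(level = g$level[1], trueLSF = g$trueLSF[1],
                           method = g$method[1], mean = mean(g$lsf),
                           sd = sd(g$lsf))))
  agg$sd[is.na(agg$sd)] <- 0
  rownames(agg) <- NULL
  list(table = agg, runs = runs)
}

#' Run the patient quantification pipeline
#'
#' Segmentation (body, lungs with exclusion margin, threshold-preset liver
#' VOI), lung count-density extrapolation, volumetric shunt fraction, CT
#' lung mass, and the MIRD lung dose. Two-bed studies supply the liver-bed
#' emission (liver counts) and the lung-bed emission (lung count density)
#' separately; a partial axial field of view is described by
#' \code{fovMask}.
#'
#' @param ct CT array, HU
#' @param emission a \linkS4class{ReconVolume}: the (liver-bed) emission
#' @param emissionLung optional lung-bed emission volume (defaults to
#'   \code{emission})
#' @param spacing voxel spacing, mm (default from \code{emission})
#' @param activityGbq administered activity for dosimetry (vector for
#'   multiple administrations); \code{NULL} skips the dose
#' @param segConfig a \linkS4class{SegmentationConfig}
#' @param liverPreset optional liver threshold preset override
#' @param fovMask optional logical mask of the lung-bed field of view
#' @return report list: shunt, counts, volumes, lung mass, dose, and the
#'   segmentation settings used
#' @export
runPatientPipeline <- function(ct, emission, emissionLung = NULL,
                               spacing = NULL, activityGbq = NULL,
                               segConfig = segmentationConfig(),
                               liverPreset = NULL, fovMask = NULL) {
  if (is.null(spacing)) spacing <- emission@spacing
  if (is.null(emissionLung)) emissionLung <- emission
  seg <- segmentStudy(ct, emission, spacing, segConfig,
                      liverPreset = liverPreset)
  lungCounts <- estimateLungCounts(emissionLung, seg@lungMaskExcl,
                                   seg@lungVolumeL, spacing,
                                   inFovMask = fovMask)
  lsf <- volumetricLSF(emission, seg@liverMask, lungCounts)
  mass <- lungMassFromCT(seg@lungVolumeL)
  report <- list(
    method = lsf@method,
    lsf_percent = lsfPercent(lsf),
    lung_counts = lsf@lungCounts,
    liver_counts = lsf@liverCounts,
    lung_volume_L = seg@lungVolumeL,
    liver_volume_L = seg@liverVolumeL,
    lung_mass_kg = mass,
    liver_preset_percent = seg@chosenPreset,
    exclusion_mm = seg@exclusionMM)
  if (!is.null(activityGbq)) {
    dose <- lungDose(activityGbq, mass, lsfPercent(lsf), "percent")
    report$activity_gbq <- sum(activityGbq)
    report$lung_dose_gy <- doseGy(dose)
  }
  report
}
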