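#' @import methods
#' @importFrom stats dnorm rnorm rlnorm runif rpois sd pt qt cor
#' @importFrom utils read.csv write.csv
NULL

## ---- phantom side ----------------------------------------------------------

#' PhantomSpec: compartment concentrations and volumes of a shunt phantom
#'
#' Describes the fillable liver/lung torso phantom (or a synthetic patient) by
#' its compartment activity concentrations (kBq/mL) and volumes (mL). The
#' ground-truth lung shunt fraction is defined on activities:
#' LSF = 100 * lung activity / (lung + liver activity), where liver activity
#' includes the lesion compartments.
#'
#' @slot lungConc activity concentration in each lung, kBq/mL
#' @slot liverConc normal-liver (liver minus lesions) concentration, kBq/mL
#' @slot lesionConc lesion concentration, kBq/mL (both lesions)
#' @slot lungVolume total lung volume (both lungs), mL
#' @slot liverVolume normal-liver volume, mL
#' @slot lesionVolumes named numeric, mL: \code{sphere}, \code{ellipsoid}
#' @slot totalActivity total activity, MBq
#' @slot trueLSF ground-truth shunt, percent
#' @export
setClass("PhantomSpec", representation(
  lungConc = "numeric", liverConc = "numeric", lesionConc = "numeric",
  lungVolume = "numeric", liverVolume = "numeric", lesionVolumes = "numeric",
  totalActivity = "numeric", trueLSF = "numeric"))

setValidity("PhantomSpec", function(object) {
  v <- c(object@lungConc, object@liverConc, object@lesionConc,
         object@lungVolume, object@liverVolume, object@lesionVolumes)
  if (any(v < 0)) return("concentrations and volumes must be >= 0")
  lungA <- object@lungConc * object@lungVolume
  liverA <- object@liverConc * object@liverVolume +
    object@lesionConc * sum(object@lesionVolumes)
  if (lungA + liverA <= 0) return("phantom holds no activity")
  lsf <- 100 * lungA / (lungA + liverA)
  if (abs(lsf - object@trueLSF) > 0.05)
    return(sprintf("trueLSF (%.3f) inconsistent with fields (%.3f)",
                   object@trueLSF, lsf))
  TRUE
})

#' Construct a PhantomSpec
#'
#' @param lungConc,liverConc,lesionConc compartment concentrations, kBq/mL
#' @param lungVolume,liverVolume compartment volumes, mL
#' @param lesionVolumes named numeric of lesion volumes (mL), names
#'   \code{sphere} and \code{ellipsoid}
#' @return a \linkS4class{PhantomSpec}; \code{trueLSF} and
#'   \code{totalActivity} are derived from the fields
#' @export
PhantomSpec <- function(lungConc, liverConc, lesionConc = 0,
                        lungVolume, liverVolume,
                        lesionVolumes = c(sphere = 0, ellipsoid = 0)) {
  lesionVolumes <- lesionVolumes[c("sphere", "ellipsoid")]
  if (any(is.na(lesionVolumes)))
    stop("lesionVolumes must carry 'sphere' and 'ellipsoid' entries")
  lungA <- lungConc * lungVolume
  liverA <- liverConc * liverVolume + lesionConc * sum(lesionVolumes)
  new("PhantomSpec", lungConc = lungConc, liverConc = liverConc,
      lesionConc = lesionConc, lungVolume = lungVolume,
      liverVolume = liverVolume, lesionVolumes = lesionVolumes,
      totalActivity = (lungA + liverA) / 1000,
      trueLSF = 100 * lungA / (lungA + liverA))
}

#' DigitalPhantom: voxelized activity/density/label volumes
#'
#' Voxel grids share dimensions; the third array axis is the
#' superior-inferior axis, with index increasing toward superior.
#' Label codes: 0 air, 1 soft tissue, 2 bone, 3 left lung, 4 right lung,
#' 5 normal liver, 6 spherical lesion, 7 ellipsoid lesion.
#'
#' @slot activity kBq/mL per voxel
#' @slot density g/mL per voxel
#' @slot labels integer compartment code per voxel
#' @slot spacing voxel spacing, mm (length 3)
#' @slot spec the generating \linkS4class{PhantomSpec} (or NULL)
#' @export
setClass("DigitalPhantom", representation(
  activity = "array", density = "array", labels = "array",
  spacing = "numeric", spec = "ANY"))

setValidity("DigitalPhantom", function(object) {
  d <- dim(object@activity)
  if (!identical(d, dim(object@density)) || !identical(d, dim(object@labels)))
    return("activity, density and label grids must share dimensions")
  if (length(object@spacing) != 3 || any(object@spacing <= 0))
    return("spacing must be 3 positive values (mm)")
  if (any(object@activity < 0)) return("negative activity")
  if (is(object@spec, "PhantomSpec")) {
    tot <- sum(object@activity) * prod(object@spacing) / 1e3 / 1e3 # MBq
    if (object@spec@totalActivity > 0 &&
        abs(tot - object@spec@totalActivity) / object@spec@totalActivity > 0.015)
      return(sprintf("voxelized activity (%.1f MBq) off spec total (%.1f MBq)",
                     tot, object@spec@totalActivity))
  }
  TRUE
})

## label codes used throughout
.LBL <- c(air = 0L, soft = 1L, bone = 2L, lungL = 3L, lungR = 4L,
          liver = 5L, lesionSphere = 6L, lesionEllipsoid = 7L)
.DENS <- c(air = 0.0012, soft = 1.0, bone = 1.5, lung = 0.3)

#' CohortSpec: sampling distributions for a synthetic patient cohort
#'
#' Defaults emulate the clinical cohort: shunt fractions log-normally
#' distributed around a 1.4\% median (spanning roughly 0.4-6\%), lung volumes
#' normal around 2.9 L truncated to 1.5-4.8 L (0.45-1.43 kg at 0.3 kg/L),
#' liver volumes around 1.6 L, free-breathing axial blur of 4-9 mm sigma,
#' and administered Y-90 activities log-normal around 3.7 GBq clipped to
#' 0.9-7.9 GBq.
#'
#' @slot nPatients number of patients
#' @slot lsfMedian,lsfLogSD log-normal parameters of LSF percent
#' @slot lungVolMeanL,lungVolSDL,lungVolRangeL lung volume distribution, L
#' @slot liverVolMeanL,liverVolSDL liver volume distribution, L
#' @slot blurSigmaRangeMM uniform range of breathing blur sigma, mm
#' @slot activityMedianGbq,activityLogSD,activityRangeGbq administered
#'   activity distribution, GBq
#' @slot seed RNG seed; fully determines the cohort
#' @export
setClass("CohortSpec", representation(
  nPatients = "numeric", lsfMedian = "numeric", lsfLogSD = "numeric",
  lungVolMeanL = "numeric", lungVolSDL = "numeric", lungVolRangeL = "numeric",
  liverVolMeanL = "numeric", liverVolSDL = "numeric",
  blurSigmaRangeMM = "numeric",
  activityMedianGbq = "numeric", activityLogSD = "numeric",
  activityRangeGbq = "numeric", seed = "numeric"))

setValidity("CohortSpec", function(object) {
  if (object@nPatients < 1) return("nPatients must be >= 1")
  if (any(object@blurSigmaRangeMM < 0)) return("blur sigma must be >= 0")
  TRUE
})

#' @rdname CohortSpec-class
#' @param nPatients,lsfMedian,lsfLogSD,lungVolMeanL,lungVolSDL,lungVolRangeL
#'   see slots
#' @param liverVolMeanL,liverVolSDL,blurSigmaRangeMM,activityMedianGbq see slots
#' @param activityLogSD,activityRangeGbq,seed see slots
#' @export
CohortSpec <- function(nPatients, lsfMedian = 1.4, lsfLogSD = 0.7,
                       lungVolMeanL = 2.9, lungVolSDL = 0.55,
                       lungVolRangeL = c(1.5, 4.8),
                       liverVolMeanL = 1.6, liverVolSDL = 0.3,
                       blurSigmaRangeMM = c(4, 9),
                       activityMedianGbq = 3.7, activityLogSD = 0.45,
                       activityRangeGbq = c(0.9, 7.9), seed = 0) {
  new("CohortSpec", nPatients = nPatients, lsfMedian = lsfMedian,
      lsfLogSD = lsfLogSD, lungVolMeanL = lungVolMeanL,
      lungVolSDL = lungVolSDL, lungVolRangeL = lungVolRangeL,
      liverVolMeanL = liverVolMeanL, liverVolSDL = liverVolSDL,
      blurSigmaRangeMM = blurSigmaRangeMM,
      activityMedianGbq = activityMedianGbq, activityLogSD = activityLogSD,
      activityRangeGbq = activityRangeGbq, seed = seed)
}

## ---- acquisition side ------------------------------------------------------

#' AcquisitionConfig: gamma-camera and reconstruction protocol
#'
#' Mirrors the clinic Tc-99m protocol: 15\% photopeak window with adjacent
#' 15\% low-energy scatter window, 60 views, 8 iterations x 4 subsets OSEM,
#' 8.4 mm FWHM Gaussian post-filter, 500k anterior planar counts and 6M total
#' SPECT counts. The default matrix is reduced to 64 for desk-scale runtime;
#' the algorithms are matrix-size agnostic.
#'
#' @slot photopeakWindowFrac,scatterWindowFrac energy window widths (fraction)
#' @slot nViews number of SPECT projection views
#' @slot matrixSize transaxial matrix (e.g. 64 or 128)
#' @slot secondsPerView acquisition time per view, s
#' @slot planarTargetCounts target counts on the anterior planar view
#' @slot spectTargetCounts target total photopeak counts across all views
#' @slot osemIterations,osemSubsets OSEM protocol; subsets must divide views
#' @slot postfilterFWHM Gaussian post-filter FWHM, mm
#' @slot collimatorA,collimatorB collimator response FWHM = A + B * depth (mm)
#' @slot scatterFraction photopeak scatter-to-primary fraction
#' @slot scatterSigma scatter kernel sigma, mm
#' @slot dewK dual-energy-window scatter weighting k
#' @slot depthBin depth planes per collimator-blur bin
#' @slot detectorOffset collimator face to body edge distance, mm
#' @slot seed RNG seed for Poisson sampling
#' @export
setClass("AcquisitionConfig", representation(
  photopeakWindowFrac = "numeric", scatterWindowFrac = "numeric",
  nViews = "numeric", matrixSize = "numeric", secondsPerView = "numeric",
  planarTargetCounts = "numeric", spectTargetCounts = "numeric",
  osemIterations = "numeric", osemSubsets = "numeric",
  postfilterFWHM = "numeric", collimatorA = "numeric", collimatorB = "numeric",
  scatterFraction = "numeric", scatterSigma = "numeric", dewK = "numeric",
  depthBin = "numeric", detectorOffset = "numeric", seed = "numeric"))

setValidity("AcquisitionConfig", function(object) {
  if (object@nViews %% object@osemSubsets != 0)
    return("osemSubsets must divide nViews")
  if (object@planarTargetCounts <= 0 || object@spectTargetCounts <= 0)
    return("count targets must be > 0")
  if (object@scatterFraction < 0 || object@dewK <= 0)
    return("scatterFraction must be >= 0 and dewK > 0")
  TRUE
})

#' @rdname AcquisitionConfig-class
#' @param photopeakWindowFrac,scatterWindowFrac,nViews,matrixSize see slots
#' @param secondsPerView,planarTargetCounts,spectTargetCounts see slots
#' @param osemIterations,osemSubsets,postfilterFWHM,collimatorA,collimatorB
#'   see slots
#' @param scatterFraction,scatterSigma,dewK,depthBin,detectorOffset,seed
#'   see slots
#' @export
acquisitionConfig <- function(photopeakWindowFrac = 0.15,
                              scatterWindowFrac = 0.15,
                              nViews = 60, matrixSize = 64,
                              secondsPerView = 10,
                              planarTargetCounts = 5e5,
                              spectTargetCounts = 6e6,
                              osemIterations = 8, osemSubsets = 4,
                              postfilterFWHM = 8.4,
                              collimatorA = 4, collimatorB = 0.05,
                              scatterFraction = 0.3, scatterSigma = 40,
                              dewK = 0.5, depthBin = 4,
                              detectorOffset = 20, seed = 0) {
  new("AcquisitionConfig",
      photopeakWindowFrac = photopeakWindowFrac,
      scatterWindowFrac = scatterWindowFrac, nViews = nViews,
      matrixSize = matrixSize, secondsPerView = secondsPerView,
      planarTargetCounts = planarTargetCounts,
      spectTargetCounts = spectTargetCounts,
      osemIterations = osemIterations, osemSubsets = osemSubsets,
      postfilterFWHM = postfilterFWHM, collimatorA = collimatorA,
      collimatorB = collimatorB, scatterFraction = scatterFraction,
      scatterSigma = scatterSigma, dewK = dewK, depthBin = depthBin,
      detectorOffset = detectorOffset, seed = seed)
}

#' AttenuationMap: linear attenuation coefficients at 140 keV
#'
#' @slot mu cm^-1 per voxel
#' @slot spacing voxel spacing, mm
#' @export
setClass("AttenuationMap", representation(mu = "array", spacing = "numeric"))

setValidity("AttenuationMap", function(object) {
  if (any(object@mu < 0)) return("mu must be >= 0")
  TRUE
})

#' PlanarPair: anterior and posterior planar images
#'
#' The posterior image is mirrored left-right, as seen from behind the
#' patient. Rows index the transverse detector axis, columns the axial axis.
#'
#' @slot anterior,posterior count matrices
#' @slot pixelSpacing mm (length 2: transverse, axial)
#' @export
setClass("PlanarPair", representation(
  anterior = "matrix", posterior = "matrix", pixelSpacing = "numeric"))

setValidity("PlanarPair", function(object) {
  if (!identical(dim(object@anterior), dim(object@posterior)))
    return("anterior/posterior shapes differ")
  if (any(object@anterior < 0) || any(object@posterior < 0))
    return("negative counts")
  TRUE
})

#' SinogramSet: photopeak and scatter-window projections
#'
#' @slot photopeak array (detector u, axial z, view)
#' @slot scatterWindow same shape as photopeak
#' @slot angles view angles, degrees
#' @slot pixelSpacing detector pixel spacing, mm
#' @slot config the \linkS4class{AcquisitionConfig} used
#' @export
setClass("SinogramSet", representation(
  photopeak = "array", scatterWindow = "array", angles = "numeric",
  pixelSpacing = "numeric", config = "AcquisitionConfig"))

setValidity("SinogramSet", function(object) {
  if (length(object@scatterWindow) > 0 &&
      !identical(dim(object@photopeak), dim(object@scatterWindow)))
    return("photopeak/scatter-window shapes differ")
  if (dim(object@photopeak)[3] != length(object@angles))
    return("third dimension must match the number of view angles")
  if (any(object@photopeak < 0) || any(object@scatterWindow < 0))
    return("negative counts")
  TRUE
})

#' ReconVolume: an OSEM-reconstructed emission volume
#'
#' @slot values relative counts per voxel (non-negative)
#' @slot corrections named logical: \code{ac}, \code{sc}
#' @slot spacing voxel spacing, mm
#' @export
setClass("ReconVolume", representation(
  values = "array", corrections = "logical", spacing = "numeric"))

setValidity("ReconVolume", function(object) {
  if (any(object@values < 0)) return("OSEM output must be non-negative")
  if (!all(c("ac", "sc") %in% names(object@corrections)))
    return("corrections must name 'ac' and 'sc'")
  TRUE
})

## ---- segmentation / quantification side ------------------------------------

#' SegmentationConfig: auto-contouring parameters
#'
#' @slot bodyHU CT threshold for the whole-body VOI, HU
#' @slot lungHULock upper HU bound locking the lung VOI
#' @slot minLungComponentML component volume filter cleaning the mediastinum
#' @slot exclusionMarginCM inferior lung exclusion margin, cm
#' @slot liverPresets percent-of-max presets for the liver VOI
#' @slot morphRadius body-closing radius, voxels
#' @export
setClass("SegmentationConfig", representation(
  bodyHU = "numeric", lungHULock = "numeric", minLungComponentML = "numeric",
  exclusionMarginCM = "numeric", liverPresets = "numeric",
  morphRadius = "numeric"))

setValidity("SegmentationConfig", function(object) {
  if (is.unsorted(object@liverPresets)) return("liver presets must ascend")
  if (object@exclusionMarginCM < 0) return("exclusion margin must be >= 0")
  TRUE
})

#' @rdname SegmentationConfig-class
#' @param bodyHU,lungHULock,minLungComponentML,exclusionMarginCM see slots
#' @param liverPresets,morphRadius see slots
#' @export
segmentationConfig <- function(bodyHU = -500, lungHULock = -150,
                               minLungComponentML = 50,
                               exclusionMarginCM = 2,
                               liverPresets = c(0.5, 1, 2, 5, 10),
                               morphRadius = 2) {
  new("SegmentationConfig", bodyHU = bodyHU, lungHULock = lungHULock,
      minLungComponentML = minLungComponentML,
      exclusionMarginCM = exclusionMarginCM, liverPresets = liverPresets,
      morphRadius = morphRadius)
}

#' SegmentationResult: body/lung/liver VOIs and CT volumes
#'
#' @slot bodyMask,leftLungMask,rightLungMask,lungMaskExcl,liverMask logical
#'   voxel arrays; \code{lungMaskExcl} is the lung VOI after the inferior
#'   exclusion margin
#' @slot lungVolumeL full lung volume from CT (pre-exclusion), L
#' @slot liverVolumeL liver VOI volume, L
#' @slot chosenPreset liver threshold preset used, percent of max
#' @slot exclusionMM the margin actually applied, mm (whole slices)
#' @export
setClass("SegmentationResult", representation(
  bodyMask = "array", leftLungMask = "array", rightLungMask = "array",
  lungMaskExcl = "array", liverMask = "array",
  lungVolumeL = "numeric", liverVolumeL = "numeric",
  chosenPreset = "numeric", exclusionMM = "numeric"))

setValidity("SegmentationResult", function(object) {
  lung <- object@leftLungMask | object@rightLungMask
  if (any(object@lungMaskExcl & !lung))
    return("exclusion VOI must be a subset of the lung VOI")
  if (any(object@liverMask & lung))
    return("liver and lung VOIs must be disjoint")
  if (any((lung | object@liverMask) & !object@bodyMask))
    return("organ VOIs must lie inside the body VOI")
  TRUE
})

#' LSFResult: a lung shunt fraction estimate
#'
#' @slot method one of \code{"planar_antpost"}, \code{"planar_gm"},
#'   \code{"volumetric"}, or \code{"counts"}
#' @slot lungCounts,liverCounts the counts entering the ratio
#' @slot lsfPercent 100 * lung / (lung + liver)
#' @export
setClass("LSFResult", representation(
  method = "character", lungCounts = "numeric", liverCounts = "numeric",
  lsfPercent = "numeric"))

setValidity("LSFResult", function(object) {
  if (object@lsfPercent < 0 || object@lsfPercent > 100)
    return("lsfPercent outside [0, 100]")
  expected <- 100 * object@lungCounts /
    (object@lungCounts + object@liverCounts)
  if (abs(expected - object@lsfPercent) > 1e-9 * max(1, expected))
    return("lsfPercent inconsistent with counts")
  TRUE
})

#' DoseResult: MIRD lung absorbed dose
#'
#' dose (Gy) = 49.38 * activity (GBq) / lung mass (kg) * shunt fraction.
#'
#' @slot activityGbq administered activity, GBq
#' @slot lungMassKg lung mass, kg
#' @slot lsfFraction shunt as a fraction (not percent)
#' @slot doseGy absorbed dose, Gy
#' @export
setClass("DoseResult", representation(
  activityGbq = "numeric", lungMassKg = "numeric", lsfFraction = "numeric",
  doseGy = "numeric"))

setValidity("DoseResult", function(object) {
  expected <- 49.38 * object@activityGbq / object@lungMassKg *
    object@lsfFraction
  if (abs(expected - object@doseGy) > 1e-9 * max(1, expected))
    return("doseGy inconsistent with the MIRD formula")
  TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "PhantomSpec", function(object) {
  cat("PhantomSpec: true LSF", sprintf("%.2f%%", object@trueLSF),
      sprintf("(%.1f MBq total)\n", object@totalActivity))
  cat("  lungs  :", object@lungConc, "kBq/mL x", object@lungVolume, "mL\n")
  cat("  liver  :", object@liverConc, "kBq/mL x", object@liverVolume, "mL\n")
  cat("  lesions:", object@lesionConc, "kBq/mL x",
      paste(round(object@lesionVolumes, 1), collapse = " + "), "mL\n")
})

setMethod("show", "DigitalPhantom", function(object) {
  d <- dim(object@activity)
  cat("DigitalPhantom:", paste(d, collapse = " x "), "voxels at",
      paste(object@spacing, collapse = " x "), "mm\n")
  cat("  total activity:",
      sprintf("%.1f MBq", sum(object@activity) * prod(object@spacing) / 1e6),
      "\n")
  if (is(object@spec, "PhantomSpec"))
    cat("  spec true LSF:", sprintf("%.2f%%", object@spec@trueLSF), "\n")
})

setMethod("show", "SinogramSet", function(object) {
  d <- dim(object@photopeak)
  cat("SinogramSet:", d[3], "views of", d[1], "x", d[2], "pixels;",
      sprintf("%.3g photopeak counts\n", sum(object@photopeak)))
})

setMethod("show", "ReconVolume", function(object) {
  cat("ReconVolume:", paste(dim(object@values), collapse = " x "),
      "| AC:", object@corrections["ac"], "SC:", object@corrections["sc"], "\n")
})

setMethod("show", "SegmentationResult", function(object) {
  cat("SegmentationResult: lung", sprintf("%.2f L", object@lungVolumeL),
      "(full), liver", sprintf("%.2f L", object@liverVolumeL),
      "at preset", object@chosenPreset, "%\n")
})

setMethod("show", "LSFResult", function(object) {
  cat(sprintf("LSF [%s]: %.2f%% (lung %.4g / liver %.4g counts)\n",
              object@method, object@lsfPercent, object@lungCounts,
              object@liverCounts))
})

setMethod("show", "DoseResult", function(object) {
  cat(sprintf("Lung dose: %.2f Gy (%.3g GBq, %.2f kg, LSF %.2f%%)\n",
              object@doseGy, object@activityGbq, object@lungMassKg,
              100 * object@lsfFraction))
})

## ---- accessors -------------------------------------------------------------

#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @describeIn DigitalPhantom-class voxel spacing in mm
#' @param x object
#' @export
setMethod("voxelSpacing", "DigitalPhantom", function(x) x@spacing)
#' @describeIn ReconVolume-class voxel spacing in mm
#' @param x object
#' @export
setMethod("voxelSpacing", "ReconVolume", function(x) x@spacing)

#' @export
activityGrid <- function(x) x@activity
#' @export
densityGrid <- function(x) x@density
#' @export
labelGrid <- function(x) x@labels
#' @export
phantomSpec <- function(x) x@spec
#' @export
reconValues <- function(x) x@values
#' @export
correctionsApplied <- function(x) x@corrections
#' @export
lsfPercent <- function(x) x@lsfPercent
#' @export
doseGy <- function(x) x@doseGy
#' @export
trueLSF <- function(x) {
  if (is(x, "DigitalPhantom")) x <- x@spec
  x@trueLSF
}
#' @export
lungVolumeL <- function(x) x@lungVolumeL
#' @export
liverVolumeL <- function(x) x@liverVolumeL
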