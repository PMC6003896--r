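## Semi-automatic auto-contouring workflow: whole-body VOI from CT, lung VOI
## under a -150 HU lock with left/right split and small-component cleanup,
## per-lung inferior exclusion margin, threshold-preset liver VOI on the
## emission volume, and partial-FOV lung count extrapolation.

#' Whole-body VOI from CT
#'
#' Thresholds the CT above the body HU level, applies a morphological
#' closing and hole fill (recovering the lungs as interior holes), and keeps
#' the largest contiguous component.
#'
#' @param ct CT array in HU
#' @param config a \linkS4class{SegmentationConfig}
#' @return logical body mask
#' @export
wholeBodyVOI <- function(ct, config = segmentationConfig()) {
  m <- ct > config@bodyHU
  if (!any(m)) stop("empty body: no voxel above the body HU threshold")
  ## close per axial slice with a disc brush (gentler on digitized convex
  ## outlines than an iterated 3-D diamond), then fill 3-D cavities; slices
  ## are zero-padded so the image border stays background
  r <- config@morphRadius
  brush <- EBImage::makeBrush(2 * r + 1, shape = "disc")
  k <- r + 1
  d <- dim(m)
  for (z in seq_len(d[3])) {
    pad <- matrix(0, d[1] + 2 * k, d[2] + 2 * k)
    pad[k + seq_len(d[1]), k + seq_len(d[2])] <- m[, , z]
    m[, , z] <- EBImage::closing(pad, brush)[k + seq_len(d[1]),
                                             k + seq_len(d[2])] > 0
  }
  m <- fillHoles3d(m)
  largestComponent(m)
}

#' Lung VOIs from CT inside the body
#'
#' Applies the upper HU lock to the whole-body VOI, removes connected
#' components smaller than the mediastinum volume filter, and assigns the
#' remaining components to the left or right lung by centroid position about
#' the mid-sagittal plane of the body.
#'
#' @param ct CT array in HU
#' @param bodyMask from \code{\link{wholeBodyVOI}}
#' @param spacing voxel spacing, mm
#' @param config a \linkS4class{SegmentationConfig}
#' @return list of logical masks \code{left} and \code{right}
#' @export
lungVOI <- function(ct, bodyMask, spacing, config = segmentationConfig()) {
  if (!any(bodyMask)) stop("empty body mask")
  cand <- ct <= config@lungHULock & bodyMask
  if (!any(cand)) stop("no lung candidate voxels under the HU lock")
  lab <- labelComponents3d(cand)
  voxML <- prod(spacing) / 1e3
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes * voxML >= config@minLungComponentML)
  if (length(keep) == 0) stop("no lung component above the volume filter")
  midX <- mean(which(apply(bodyMask, 1, any)))
  d <- dim(ct)
  xIdx <- array(rep(seq_len(d[1]), d[2] * d[3]), d)
  left <- array(FALSE, d); right <- array(FALSE, d)
  for (k in keep) {
    m <- lab == k
    if (mean(xIdx[m]) < midX) left <- left | m else right <- right | m
  }
  if (!any(left) || !any(right))
    warning("single-lung segmentation result")
  list(left = left, right = right)
}

#' Apply the inferior lung exclusion margin
#'
#' Removes, per lung, all voxels lying within the margin of that lung's own
#' most inferior voxel (axis 3 increases toward superior). The margin is
#' rounded to whole slices; the applied distance in mm is returned as an
#' attribute.
#'
#' @param lungMasks list with \code{left} and \code{right} logical masks
#' @param marginCM exclusion margin, cm
#' @param spacing voxel spacing, mm
#' @return combined lung mask with exclusion applied; attribute
#'   \code{exclusionMM} records the distance actually removed
#' @export
excludeInferior <- function(lungMasks, marginCM, spacing) {
  nSlice <- round(marginCM * 10 / spacing[3])
  out <- NULL
  for (m in lungMasks) {
    if (!any(m)) { out <- if (is.null(out)) m else out | m; next }
    zs <- which(apply(m, 3, any))
    if (nSlice >= length(zs))
      stop("exclusion margin exceeds the lung height")
    cut <- min(zs) + nSlice
    m[, , seq_len(cut - 1)] <- FALSE
    out <- if (is.null(out)) m else out | m
  }
  attr(out, "exclusionMM") <- nSlice * spacing[3]
  out
}

#' Threshold-preset liver VOI on the emission volume
#'
#' Builds the liver contour as the largest connected component above a
#' preset percentage of the maximum counts in the field of view. The preset
#' defaults to 2\% (the modal clinical choice). When a CT-derived liver
#' volume is supplied, auto-selection picks the preset whose mask volume
#' best matches it.
#'
#' @param emission a \linkS4class{ReconVolume} or array
#' @param spacing voxel spacing, mm (taken from the volume if available)
#' @param config a \linkS4class{SegmentationConfig}
#' @param preset percent-of-max override; \code{NULL} uses 2\% or
#'   auto-selection
#' @param ctLiverVolumeML optional CT liver volume driving auto-selection
#' @return list with \code{mask} (logical), \code{preset} (percent) and
#'   \code{presets} (the preset menu)
#' @export
liverVOI <- function(emission, spacing = NULL,
                     config = segmentationConfig(), preset = NULL,
                     ctLiverVolumeML = NULL) {
  vol <- if (is(emission, "ReconVolume")) emission@values else emission
  if (is.null(spacing) && is(emission, "ReconVolume"))
    spacing <- emission@spacing
  mx <- max(vol)
  if (mx <= 0) stop("all-zero emission volume")
  maskAt <- function(p) largestComponent(vol >= p / 100 * mx)
  if (is.null(preset)) {
    if (!is.null(ctLiverVolumeML)) {
      voxML <- prod(spacing) / 1e3
      vols <- vapply(config@liverPresets,
                     function(p) sum(maskAt(p)) * voxML, 0)
      preset <- config@liverPresets[which.min(abs(vols - ctLiverVolumeML))]
    } else {
      preset <- 2
    }
  }
  list(mask = maskAt(preset), preset = preset, presets = config@liverPresets)
}

#' Extrapolate total lung counts from the in-FOV lung
#'
#' Total lung counts are estimated as the mean count density over the lung
#' VOI (after exclusion) restricted to the field of view, multiplied by the
#' full CT lung volume. This is the count-density extrapolation used both
#' for the exclusion margin and for partial-FOV post-therapy PET.
#'
#' @param emission a \linkS4class{ReconVolume} or array of counts
#' @param lungMaskExcl lung VOI with the inferior exclusion applied
#' @param totalLungVolumeL full CT lung volume, L
#' @param spacing voxel spacing, mm
#' @param inFovMask optional logical mask of the field of view
#' @return estimated total lung counts
#' @export
estimateLungCounts <- function(emission, lungMaskExcl, totalLungVolumeL,
                               spacing = NULL, inFovMask = NULL) {
  vol <- if (is(emission, "ReconVolume")) emission@values else emission
  if (is.null(spacing) && is(emission, "ReconVolume"))
    spacing <- emission@spacing
  m <- lungMaskExcl
  if (!is.null(inFovMask)) m <- m & inFovMask
  if (!any(m)) stop("no lung in FOV")
  densityPerML <- mean(vol[m]) / (prod(spacing) / 1e3)
  densityPerML * totalLungVolumeL * 1e3
}

#' Run the full segmentation workflow on a CT / emission pair
#'
#' @param ct CT array in HU
#' @param emission a \linkS4class{ReconVolume} (liver contouring source)
#' @param spacing voxel spacing, mm
#' @param config a \linkS4class{SegmentationConfig}
#' @param liverPreset optional preset override (percent of max)
#' @param ctLiverVolumeML optional CT-derived liver volume (mL); when given,
#'   the preset best matching it is auto-selected
#' @return a \linkS4class{SegmentationResult}
#' @export
segmentStudy <- function(ct, emission, spacing,
                         config = segmentationConfig(), liverPreset = NULL,
                         ctLiverVolumeML = NULL) {
  body <- wholeBodyVOI(ct, config)
  lungs <- lungVOI(ct, body, spacing, config)
  excl <- excludeInferior(lungs, config@exclusionMarginCM, spacing)
  voxML <- prod(spacing) / 1e3
  lungVolL <- (sum(lungs$left) + sum(lungs$right)) * voxML / 1e3
  lv <- liverVOI(emission, spacing, config, preset = liverPreset,
                 ctLiverVolumeML = ctLiverVolumeML)
  liverMask <- lv$mask & !(lungs$left | lungs$right) & body
  new("SegmentationResult", bodyMask = body, leftLungMask = lungs$left,
      rightLungMask = lungs$right,
      lungMaskExcl = array(as.vector(excl), dim(ct)), liverMask = liverMask,
      lungVolumeL = lungVolL, liverVolumeL = sum(liverMask) * voxML / 1e3,
      chosenPreset = lv$preset, exclusionMM = attr(excl, "exclusionMM"))
}
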