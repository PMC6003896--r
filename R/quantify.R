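## Shunt fraction and MIRD lung dosimetry.
##
## LSF (%) = 100 * lung counts / (lung + liver counts)
## Lung dose (Gy) = 49.38 * activity (GBq) / lung mass (kg) * LSF fraction

#' The Y-90 MIRD dose constant, Gy kg / GBq
#' @export
MIRD_Y90_GY_KG_PER_GBQ <- 49.38

#' Lung density assumed for CT-based lung mass, kg/L
#' @export
LUNG_DENSITY_KG_PER_L <- 0.3

#' Shunt fraction from lung and liver counts
#'
#' @param lungCounts,liverCounts non-negative counts (not both zero)
#' @param method tag recorded in the result
#' @return an \linkS4class{LSFResult}
#' @examples
#' lsfPercent(lsfFromCounts(36, 964)) # 3.6
#' @export
lsfFromCounts <- function(lungCounts, liverCounts, method = "counts") {
  if (lungCounts < 0 || liverCounts < 0) stop("counts must be >= 0")
  if (lungCounts + liverCounts == 0) stop("no counts")
  new("LSFResult", method = method, lungCounts = lungCounts,
      liverCounts = liverCounts,
      lsfPercent = 100 * lungCounts / (lungCounts + liverCounts))
}

#' Planar shunt fraction
#'
#' \code{ant_post}: liver counts from the anterior view, lung counts from
#' the posterior view (the clinic method; most of the liver lies close to
#' the anterior body wall, and the posterior lung view avoids cardiac
#' attenuation). \code{geometric_mean}: per-organ geometric mean of the
#' anterior and posterior ROI sums (conjugate-view method).
#'
#' @param planar a \linkS4class{PlanarPair}
#' @param liverROI,lungROI logical matrices on the planar grid; each may be
#'   a single mask (applied to both views) or a list with \code{ant} and
#'   \code{post} masks
#' @param method \code{"ant_post"} or \code{"geometric_mean"}
#' @return an \linkS4class{LSFResult}
#' @export
planarLSF <- function(planar, liverROI, lungROI,
                      method = c("ant_post", "geometric_mean")) {
  method <- match.arg(method)
  pick <- function(roi, side) {
    m <- if (is.list(roi)) roi[[side]] else roi
    if (!any(m)) stop("empty ROI")
    m
  }
  sumROI <- function(img, m) sum(as.numeric(img[m]))
  liverAnt <- sumROI(planar@anterior, pick(liverROI, "ant"))
  liverPost <- sumROI(planar@posterior, pick(liverROI, "post"))
  lungAnt <- sumROI(planar@anterior, pick(lungROI, "ant"))
  lungPost <- sumROI(planar@posterior, pick(lungROI, "post"))
  if (method == "ant_post") {
    lsfFromCounts(lungPost, liverAnt, method = "planar_antpost")
  } else {
    lsfFromCounts(sqrt(lungAnt * lungPost), sqrt(liverAnt * liverPost),
                  method = "planar_gm")
  }
}

#' Volumetric shunt fraction from a reconstructed volume
#'
#' Liver counts are summed over the liver VOI of the emission volume; lung
#' counts come from the count-density extrapolation
#' (\code{\link{estimateLungCounts}}), which already accounts for the
#' exclusion margin and any partial field of view.
#'
#' @param emission a \linkS4class{ReconVolume} or array (the liver-bed
#'   volume)
#' @param liverMask logical liver VOI
#' @param estimatedLungCounts from \code{\link{estimateLungCounts}}
#' @return an \linkS4class{LSFResult}
#' @export
volumetricLSF <- function(emission, liverMask, estimatedLungCounts) {
  vol <- if (is(emission, "ReconVolume")) emission@values else emission
  if (!any(liverMask)) stop("empty liver mask")
  lsfFromCounts(estimatedLungCounts, sum(vol[liverMask]),
                method = "volumetric")
}

#' Lung mass from the CT lung volume
#'
#' mass (kg) = lung density (0.3 kg/L) * volume (L).
#'
#' @param lungVolumeL CT lung volume, L (> 0)
#' @param densityKgPerL lung density, kg/L
#' @return mass in kg
#' @examples
#' lungMassFromCT(2.9) # 0.87
#' @export
lungMassFromCT <- function(lungVolumeL, densityKgPerL = LUNG_DENSITY_KG_PER_L) {
  if (lungVolumeL <= 0) stop("lung volume must be > 0")
  densityKgPerL * lungVolumeL
}

#' MIRD lung absorbed dose
#'
#' The dose constant 49.38 Gy kg / GBq is the total Y-90 self-dose per unit
#' activity per unit mass, so the shunt must enter as a fraction; the
#' \code{lsfUnit} tag makes the conversion explicit. For planar estimates a
#' standard 1-kg lung mass is conventional; volumetric estimates use the
#' patient's CT lung mass. Doses from multiple administrations add: pass
#' vectors of activities/shunts to sum the combined dose.
#'
#' @param activityGbq administered activity (GBq), one value per
#'   administration
#' @param lungMassKg lung mass, kg
#' @param lsf shunt value(s), matching \code{activityGbq} in length (or one)
#' @param lsfUnit \code{"percent"} or \code{"fraction"}
#' @return a \linkS4class{DoseResult} (dose summed over administrations)
#' @examples
#' doseGy(lungDose(1, 1, 100, "percent"))     # 49.38
#' doseGy(lungDose(4.377, 1, 13.6, "percent")) # 29.4
#' @export
lungDose <- function(activityGbq, lungMassKg, lsf,
                     lsfUnit = c("percent", "fraction")) {
  lsfUnit <- match.arg(lsfUnit)
  if (any(activityGbq <= 0)) stop("activity must be > 0")
  if (lungMassKg <= 0) stop("lung mass must be > 0")
  frac <- if (lsfUnit == "percent") lsf / 100 else lsf
  if (any(frac < 0 | frac > 1)) stop("shunt outside [0, 1]")
  if (length(frac) == 1 && length(activityGbq) > 1)
    frac <- rep(frac, length(activityGbq))
  dose <- sum(MIRD_Y90_GY_KG_PER_GBQ * activityGbq / lungMassKg * frac)
  new("DoseResult", activityGbq = sum(activityGbq), lungMassKg = lungMassKg,
      lsfFraction = sum(activityGbq * frac) / sum(activityGbq),
      doseGy = dose)
}
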