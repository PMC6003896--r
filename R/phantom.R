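## Phantom factory: voxelized liver/lung torso phantoms and synthetic cohorts.
##
## Geometry is parametric (ellipsoids / elliptic cylinders); only compartment
## volumes and activity concentrations are constrained by the physical
## phantom. Axis convention: array axis 3 is superior-inferior, index
## increasing toward superior; coordinates are in mm about the grid center.

## base aspect ratios (x, y, z) of each parametric compartment
.GEOM <- list(
  bodySemi = c(175, 115),              # elliptic cylinder, full z extent
  spine = list(center = c(0, -85), radius = 14),
  lungL = list(cx = -70, cy = -5, zBottom = -60, aspect = c(0.42, 0.55, 1),
               czCap = 110),
  lungR = list(cx = 70, cy = -5, zBottom = -60, aspect = c(0.46, 0.60, 1),
               czCap = 110),
  liver = list(cx = 55, cy = 15, zTop = -30, aspect = c(1, 0.75, 0.48)),
  ## lesion centers as fractions of the liver semi-axes
  lesionSphere = list(offset = c(0.21, 0.14, -0.21)),
  lesionEllipsoid = list(offset = c(-0.37, -0.21, -0.43),
                         aspect = c(1.3, 1, 0.77)),
  lungSplit = c(left = 0.47, right = 0.53))

.gridCoords <- function(dims, spacing) {
  ctr <- (dims + 1) / 2
  list(x = (seq_len(dims[1]) - ctr[1]) * spacing[1],
       y = (seq_len(dims[2]) - ctr[2]) * spacing[2],
       z = (seq_len(dims[3]) - ctr[3]) * spacing[3])
}

## quadratic form of an axis-aligned ellipsoid, evaluated on the full grid
.ellipsoidMask <- function(co, center, semi) {
  q <- outer(outer(((co$x - center[1]) / semi[1])^2,
                   ((co$y - center[2]) / semi[2])^2, "+"),
             ((co$z - center[3]) / semi[3])^2, "+")
  q <= 1
}

## semi-axes of an ellipsoid with volume vol (mm^3) and given aspect,
## z semi-axis capped so tall compartments grow laterally instead
.semiFromVolume <- function(vol, aspect, czCap = Inf) {
  t <- (vol / (4 / 3 * pi * prod(aspect)))^(1 / 3)
  cz <- min(aspect[3] * t, czCap)
  lat <- vol / (4 / 3 * pi * cz)              # product of x,y semi-axes
  ax <- sqrt(lat * aspect[1] / aspect[2])
  c(ax, lat / ax, cz)
}

## grow/shrink an ellipsoidal compartment until its voxelized volume (counted
## on candidate voxels only) matches the target within tol
.fitCompartment <- function(co, candidate, center, semi, targetML, voxML,
                            what, inside = candidate, tol = 0.005,
                            maxIter = 8) {
  ## small compartments cannot beat the voxel granularity
  tol <- max(tol, 0.75 * voxML / targetML)
  hardTol <- max(0.02, 2 * voxML / targetML)
  best <- list(err = Inf)
  for (i in seq_len(maxIter)) {
    m <- .ellipsoidMask(co, center, semi) & candidate
    v <- sum(m) * voxML
    if (v == 0) {
      semi <- semi * 1.3
      next
    }
    err <- abs(v - targetML) / targetML
    if (err < best$err) best <- list(err = err, m = m, v = v, semi = semi)
    if (err < tol) break
    semi <- semi * (targetML / v)^(1 / 3)
  }
  if (is.infinite(best$err)) {
    stop(sprintf("cannot voxelize %s to %.0f mL: no candidate voxels",
                 what, targetML))
  }
  if (best$err >= tol) {
    ## refine by bisection on a scale factor: voxel counts are quantized, so
    ## pick the scale whose count is nearest the target
    base <- best$semi
    lo <- 0.93; hi <- 1.08
    for (i in seq_len(14)) {
      mid <- (lo + hi) / 2
      m <- .ellipsoidMask(co, center, base * mid) & candidate
      v <- sum(m) * voxML
      err <- abs(v - targetML) / targetML
      if (err < best$err) best <- list(err = err, m = m, v = v,
                                       semi = base * mid)
      if (v < targetML) lo <- mid else hi <- mid
    }
  }
  m <- best$m; v <- best$v; semi <- best$semi
  if (abs(v - targetML) / targetML > hardTol)
    stop(sprintf("cannot voxelize %s to %.0f mL (reached %.0f mL); %s",
                 what, targetML, v,
                 "compartment is clipped by the body outline or grid"))
  ## clipping check against the body outline / grid
  full <- .ellipsoidMask(co, center, semi)
  if (sum(full & !inside) / sum(full) > 0.02 + 1e-9)
    stop(sprintf("compartment '%s' overlaps the body boundary", what))
  list(mask = m, semi = semi)
}

#' Solve compartment volumes from the printed filling constraints
#'
#' The phantom's two radioactive-lung configurations share the lung and
#' lesion concentrations and differ only in the normal-liver concentration.
#' Together with the total-activity constraint at the high-liver
#' configuration, the two shunt equations determine the lung, normal-liver
#' and total lesion volumes uniquely.
#'
#' @param lungConc lung concentration in the radioactive-lung
#'   configurations, kBq/mL
#' @param liverConcs length-2 numeric: normal-liver concentration at the
#'   lower and the higher shunt level (the higher shunt has the lower liver
#'   concentration)
#' @param lesionConc lesion concentration, kBq/mL
#' @param lsfTargets the two true shunt levels, percent (ascending)
#' @param totalActivityMBq total activity at the first (low-shunt,
#'   high-liver) configuration, MBq
#' @param lesionSplit fraction of the lesion volume assigned to the sphere
#'   vs. the ellipsoid insert
#' @return named list of \linkS4class{PhantomSpec}: \code{lsf0} (cold
#'   lungs), and one per entry of \code{lsfTargets} (\code{lsf3.6} etc.)
#' @examples
#' specs <- solvePhantomVolumes()
#' specs$lsf3.6
#' @export
solvePhantomVolumes <- function(lungConc = 3, liverConcs = c(140, 65),
                                lesionConc = 390, lsfTargets = c(3.6, 6.9),
                                totalActivityMBq = 195,
                                lesionSplit = c(sphere = 0.4,
                                                ellipsoid = 0.6)) {
  stopifnot(length(liverConcs) == 2, length(lsfTargets) == 2)
  liverConcs <- unname(liverConcs)
  lsfTargets <- unname(lsfTargets)
  lungConc <- unname(lungConc)
  lesionConc <- unname(lesionConc)
  f <- lsfTargets / 100
  T <- unname(totalActivityMBq) * 1000               # kBq
  vLung <- f[1] * T / lungConc
  ## [cn1 cs; cn2 cs] [vNl; vLes] = [T(1-f1); lungA (1-f2)/f2]
  A <- rbind(c(liverConcs[1], lesionConc), c(liverConcs[2], lesionConc))
  b <- c(T * (1 - f[1]), lungConc * vLung * (1 - f[2]) / f[2])
  if (abs(det(A)) < 1e-9)
    stop("singular constraint system: the two configurations must differ ",
         "in normal-liver concentration")
  v <- solve(A, b)
  if (any(v <= 0) || vLung <= 0)
    stop("inconsistent constraints: solved volumes are not all positive")
  lesions <- v[2] * lesionSplit / sum(lesionSplit)
  names(lesions) <- names(lesionSplit)
  mk <- function(cl, cn) PhantomSpec(lungConc = cl, liverConc = cn,
                                     lesionConc = lesionConc,
                                     lungVolume = vLung, liverVolume = v[1],
                                     lesionVolumes = lesions)
  out <- list(mk(0, liverConcs[2]),
              mk(lungConc, liverConcs[1]),
              mk(lungConc, liverConcs[2]))
  names(out) <- c("lsf0", paste0("lsf", lsfTargets))
  ## substitution check: solved volumes must reproduce the constraints
  got <- vapply(out[-1], function(s) s@trueLSF, 0)
  if (any(abs(got - lsfTargets) > 0.05))
    stop("volume solution fails to reproduce the target shunt levels")
  if (abs(out[[2]]@totalActivity - totalActivityMBq) > 1)
    stop("volume solution fails to reproduce the total activity")
  out
}

#' Voxelize a phantom specification
#'
#' Places two ellipsoidal lungs, a liver ellipsoid carrying a spherical and
#' an ellipsoid lesion, a cylindrical bone spine and an elliptic-cylinder
#' soft-tissue body on a regular grid, scaling each compartment until its
#' voxelized volume matches the specification within 2\% (typically well
#' under 0.5\%). Lesion voxels are excluded from the normal-liver volume.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @param voxelMM isotropic voxel spacing, mm (2-8)
#' @param dims grid dimensions; the first two must be equal (the SPECT
#'   projector rotates in that plane). Default scales with spacing to keep a
#'   constant physical extent.
#' @return a \linkS4class{DigitalPhantom}
#' @export
buildPhantom <- function(spec, voxelMM = 4, dims = NULL) {
  stopifnot(is(spec, "PhantomSpec"))
  if (voxelMM < 2 || voxelMM > 8)
    stop("voxel spacing must lie in [2, 8] mm")
  if (is.null(dims)) dims <- round(c(512, 512, 440) / voxelMM)
  if (dims[1] != dims[2]) stop("dims[1] and dims[2] must be equal")
  spacing <- rep(voxelMM, 3)
  voxML <- prod(spacing) / 1e3
  co <- .gridCoords(dims, spacing)
  G <- .GEOM

  labels <- array(.LBL["air"], dims)
  bodyQ <- outer((co$x / G$bodySemi[1])^2, (co$y / G$bodySemi[2])^2, "+")
  body <- array(rep(bodyQ <= 1, dims[3]), dims)
  labels[body] <- .LBL["soft"]
  spineQ <- outer((co$x - G$spine$center[1])^2,
                  (co$y - G$spine$center[2])^2, "+")
  spine <- array(rep(spineQ <= G$spine$radius^2, dims[3]), dims) & body
  labels[spine] <- .LBL["bone"]

  soft <- function() labels == .LBL["soft"]
  split <- G$lungSplit / sum(G$lungSplit)
  for (side in c("left", "right")) {
    g <- if (side == "left") G$lungL else G$lungR
    vol <- spec@lungVolume * split[side] * 1e3            # mm^3
    semi <- .semiFromVolume(vol, g$aspect, g$czCap)
    center <- c(g$cx, g$cy, g$zBottom + semi[3])
    fit <- .fitCompartment(co, soft(), center, semi, vol / 1e3, voxML,
                           paste(side, "lung"), inside = body)
    labels[fit$mask] <- if (side == "left") .LBL["lungL"] else .LBL["lungR"]
  }

  liverTarget <- spec@liverVolume + sum(spec@lesionVolumes)
  if (sum(spec@lesionVolumes) > spec@liverVolume + sum(spec@lesionVolumes))
    stop("lesions larger than the liver")
  semi <- .semiFromVolume(liverTarget * 1e3, G$liver$aspect)
  liverCenter <- c(G$liver$cx, G$liver$cy, G$liver$zTop - semi[3])
  fit <- .fitCompartment(co, soft(), liverCenter, semi, liverTarget, voxML,
                         "liver", inside = body)
  labels[fit$mask] <- .LBL["liver"]
  liverSemi <- fit$semi

  inLiver <- function() labels == .LBL["liver"]
  if (spec@lesionVolumes["sphere"] > 0) {
    ctr <- liverCenter + G$lesionSphere$offset * liverSemi
    r <- (spec@lesionVolumes["sphere"] * 1e3 / (4 / 3 * pi))^(1 / 3)
    fitS <- .fitCompartment(co, inLiver(), ctr, rep(r, 3),
                            spec@lesionVolumes["sphere"], voxML,
                            "spherical lesion")
    labels[fitS$mask] <- .LBL["lesionSphere"]
  }
  if (spec@lesionVolumes["ellipsoid"] > 0) {
    ctr <- liverCenter + G$lesionEllipsoid$offset * liverSemi
    semiE <- .semiFromVolume(spec@lesionVolumes["ellipsoid"] * 1e3,
                             G$lesionEllipsoid$aspect)
    fitE <- .fitCompartment(co, inLiver(), ctr, semiE,
                            spec@lesionVolumes["ellipsoid"], voxML,
                            "ellipsoid lesion")
    labels[fitE$mask] <- .LBL["lesionEllipsoid"]
  }

  density <- array(.DENS["air"], dims)
  density[labels == .LBL["soft"]] <- .DENS["soft"]
  density[labels == .LBL["bone"]] <- .DENS["bone"]
  density[labels %in% c(.LBL["lungL"], .LBL["lungR"])] <- .DENS["lung"]
  density[labels >= .LBL["liver"]] <- .DENS["soft"]

  activity <- array(0, dims)
  activity[labels %in% c(.LBL["lungL"], .LBL["lungR"])] <- spec@lungConc
  activity[labels == .LBL["liver"]] <- spec@liverConc
  activity[labels %in% c(.LBL["lesionSphere"], .LBL["lesionEllipsoid"])] <-
    spec@lesionConc

  new("DigitalPhantom", activity = activity, density = density,
      labels = labels, spacing = spacing, spec = spec)
}

#' Ground-truth shunt recounted from the voxel grids
#'
#' Sums activity over the lung labels and the liver labels (normal liver plus
#' lesions) and applies the shunt definition. On a blurred phantom this
#' measures the shunt a perfect, noise-free scanner would see through the
#' original anatomy.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @return LSF in percent
#' @export
labelLSF <- function(phantom) {
  lab <- phantom@labels
  lung <- sum(phantom@activity[lab %in% c(.LBL["lungL"], .LBL["lungR"])])
  liver <- sum(phantom@activity[lab >= .LBL["liver"]])
  100 * lung / (lung + liver)
}

#' Smear activity along the superior-inferior axis
#'
#' Models hepatic respiratory motion during a free-breathing acquisition as a
#' Gaussian blur of the activity along the axial direction only. The blur
#' kernel is column-normalized, so total activity is conserved exactly;
#' density and label grids are untouched.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param sigmaMM blur sigma, mm (>= 0)
#' @return a \linkS4class{DigitalPhantom} with blurred activity
#' @export
applyBreathingBlur <- function(phantom, sigmaMM) {
  if (sigmaMM < 0) stop("blur sigma must be >= 0")
  if (sigmaMM == 0) return(phantom)
  dims <- dim(phantom@activity)
  dz <- phantom@spacing[3]
  K <- .gaussKernelMatrix(dims[3], dz, sigmaMM, normalize = "col")
  act <- matrix(phantom@activity, ncol = dims[3])
  out <- array(act %*% t(K), dims)
  initialize(phantom, activity = out)
}

## n x n Gaussian kernel matrix on a grid of the given spacing.
## normalize = "col": each column sums to one (mass-conserving smoother);
## normalize = "sym": symmetric matrix scaled by the full-kernel sum
## (self-adjoint, mass-conserving away from edges).
.gaussKernelMatrix <- function(n, spacing, sigmaMM, normalize = c("col", "sym")) {
  normalize <- match.arg(normalize)
  if (sigmaMM < 1e-6) return(diag(n))
  d <- abs(outer(seq_len(n), seq_len(n), "-")) * spacing
  K <- exp(-d^2 / (2 * sigmaMM^2))
  K[d > 4 * sigmaMM] <- 0
  if (normalize == "col") {
    sweep(K, 2, colSums(K), "/")
  } else {
    taps <- exp(-((-ceiling(4 * sigmaMM / spacing):
                     ceiling(4 * sigmaMM / spacing)) * spacing)^2 /
                  (2 * sigmaMM^2))
    K / sum(taps)
  }
}

#' Generate a synthetic patient cohort
#'
#' Samples per-patient shunt, lung/liver volumes, breathing blur and
#' administered activity from the distributions in a
#' \linkS4class{CohortSpec}, voxelizes each patient (uniform liver with one
#' hot 30-mL lesion at four times the liver concentration) and applies the
#' breathing blur. The seed fully determines the cohort.
#'
#' @param cspec a \linkS4class{CohortSpec}
#' @param voxelMM voxel spacing for the patient grids, mm
#' @param dims grid dimensions per patient
#' @return list with \code{patients} (each a list of \code{phantom} and
#'   \code{truth}) and \code{truth}, a data.frame of the ground-truth record
#'   per patient (shunt percent, lung volume and mass, liver volume,
#'   administered activity, blur sigma)
#' @export
synthCohort <- function(cspec, voxelMM = 8, dims = c(48, 48, 48)) {
  stopifnot(is(cspec, "CohortSpec"))
  n <- as.integer(cspec@nPatients)
  if (n < 1) stop("empty cohort")
  oldSeed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(oldSeed)) assign(".Random.seed", oldSeed, globalenv()))
  set.seed(cspec@seed)

  rtrunc <- function(n, mean, sd, range) {
    x <- rnorm(n, mean, sd)
    pmin(pmax(x, range[1]), range[2])
  }
  lsf <- pmin(rlnorm(n, log(cspec@lsfMedian), cspec@lsfLogSD), 30)
  lungV <- rtrunc(n, cspec@lungVolMeanL, cspec@lungVolSDL, cspec@lungVolRangeL)
  liverV <- rtrunc(n, cspec@liverVolMeanL, cspec@liverVolSDL,
                   c(0.8, 2.6))
  blur <- runif(n, cspec@blurSigmaRangeMM[1], cspec@blurSigmaRangeMM[2])
  act <- pmin(pmax(rlnorm(n, log(cspec@activityMedianGbq),
                          cspec@activityLogSD), cspec@activityRangeGbq[1]),
              cspec@activityRangeGbq[2])

  liverConc <- 100                       # kBq/mL; scale is arbitrary
  lesionML <- 30
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    liverA <- liverConc * (liverV[i] * 1e3 - lesionML) + 4 * liverConc * lesionML
    lungA <- lsf[i] / (100 - lsf[i]) * liverA
    spec <- PhantomSpec(lungConc = lungA / (lungV[i] * 1e3),
                        liverConc = liverConc, lesionConc = 4 * liverConc,
                        lungVolume = lungV[i] * 1e3,
                        liverVolume = liverV[i] * 1e3 - lesionML,
                        lesionVolumes = c(sphere = lesionML, ellipsoid = 0))
    ph <- buildPhantom(spec, voxelMM = voxelMM, dims = dims)
    ph <- applyBreathingBlur(ph, blur[i])
    truth <- list(id = i, lsf_percent = lsf[i], lung_volume_L = lungV[i],
                  lung_mass_kg = 0.3 * lungV[i], liver_volume_L = liverV[i],
                  activity_gbq = act[i], blur_sigma_mm = blur[i])
    patients[[i]] <- list(phantom = ph, truth = truth)
  }
  truth <- do.call(rbind, lapply(patients, function(p)
    as.data.frame(p$truth)))
  list(patients = patients, truth = truth)
}

#' Synthetic CT in Hounsfield units from the density grid
#'
#' HU = 1000 * (density - 1 g/mL) / 1 g/mL, giving approximately -700 HU in
#' lung, -999 in air, 0 in soft tissue and +500 in bone.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @return array of HU values
#' @export
syntheticCT <- function(phantom) {
  1000 * (phantom@density - 1)
}
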