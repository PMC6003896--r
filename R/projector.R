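## Rotation-based parallel-beam projector with per-ray attenuation and
## depth-dependent Gaussian collimator response.
##
## The forward operator is, per view: rotate the volume into the gantry frame
## (sparse bilinear resampling), weight each voxel by its attenuation factor
## toward the detector, and accumulate depth planes through a
## depth-binned separable Gaussian blur. The backprojector is the exact
## transpose of every factor (sparse crossprod, symmetric blur matrices,
## diagonal attenuation), so <Px, y> == <x, P'y> to numerical precision.

#' Linear attenuation map from a density grid
#'
#' mu = 0.154 cm^-1 (soft tissue at 140 keV) scaled linearly with density
#' and clipped at 0.25 cm^-1 for bone.
#'
#' @param density density grid, g/mL
#' @param spacing voxel spacing, mm
#' @return an \linkS4class{AttenuationMap}
#' @export
densityToMu <- function(density, spacing = c(4, 4, 4)) {
  if (is(density, "DigitalPhantom")) {
    spacing <- density@spacing
    density <- density@density
  }
  mu <- pmin(0.154 * density, 0.25)
  new("AttenuationMap", mu = array(mu, dim(density)), spacing = spacing)
}

## sparse bilinear rotation operator on an n x n plane (gather form):
## rotated(u, v) samples the patient frame at R(theta) (u, v)
.rotationOp <- function(n, thetaDeg) {
  ctr <- (n + 1) / 2
  th <- thetaDeg * pi / 180
  uv <- expand.grid(du = seq_len(n) - ctr, dv = seq_len(n) - ctr)
  x <- ctr + cos(th) * uv$du - sin(th) * uv$dv
  y <- ctr + sin(th) * uv$du + cos(th) * uv$dv
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  p <- seq_len(n * n)
  ii <- jj <- ww <- vector("list", 4)
  corners <- list(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  wts <- list((1 - fx) * (1 - fy), fx * (1 - fy), (1 - fx) * fy, fx * fy)
  for (k in 1:4) {
    cx <- x0 + corners[[k]][1]
    cy <- y0 + corners[[k]][2]
    ok <- cx >= 1 & cx <= n & cy >= 1 & cy <= n & wts[[k]] > 0
    ii[[k]] <- p[ok]
    jj[[k]] <- cx[ok] + n * (cy[ok] - 1)
    ww[[k]] <- wts[[k]][ok]
  }
  Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(ww),
                       dims = c(n * n, n * n))
}

#' Build a SPECT projector for a given grid and protocol
#'
#' Precomputes the per-view rotation operators and the depth-binned
#' collimator blur kernels. The projector is purely geometric; attenuation
#' factors for a given mu map are attached with \code{\link{attenuationFactors}}.
#'
#' @param dims volume dimensions (nx, nx, nz)
#' @param spacing voxel spacing, mm
#' @param config an \linkS4class{AcquisitionConfig}
#' @return a projector object consumed by \code{\link{forwardProject}},
#'   \code{\link{backProject}} and \code{\link{osemReconstruct}}
#' @export
spectProjector <- function(dims, spacing, config = acquisitionConfig()) {
  stopifnot(dims[1] == dims[2])
  n <- dims[1]; nz <- dims[3]
  angles <- seq(0, 360, length.out = config@nViews + 1)[seq_len(config@nViews)]
  ## splat (transpose-of-gather) rotation: per-view mass is conserved
  ## exactly, and the backprojector rotation is the bilinear gather
  R <- lapply(angles, function(a) Matrix::t(.rotationOp(n, -a)))
  ## depth bins along the ray axis (v); detector sits at high v
  binOf <- ceiling((n - seq_len(n) + 1) / config@depthBin)
  nb <- max(binOf)
  Ku <- Kz <- vector("list", nb)
  for (b in seq_len(nb)) {
    vs <- which(binOf == b)
    d <- mean(n - vs) * spacing[2] + config@detectorOffset
    fwhm <- config@collimatorA + config@collimatorB * d
    sig <- fwhm / (2 * sqrt(2 * log(2)))
    Ku[[b]] <- .gaussKernelMatrix(n, spacing[1], sig, normalize = "sym")
    Kz[[b]] <- .gaussKernelMatrix(nz, spacing[3], sig, normalize = "sym")
  }
  sc <- config@scatterSigma
  list(dims = dims, spacing = spacing, config = config, angles = angles,
       R = R, binOf = binOf, Ku = Ku, Kz = Kz,
       KscU = .gaussKernelMatrix(n, spacing[1], sc, normalize = "sym"),
       KscZ = .gaussKernelMatrix(nz, spacing[3], sc, normalize = "sym"))
}

#' Per-view attenuation factor volumes for a mu map
#'
#' @param projector from \code{\link{spectProjector}}
#' @param mu an \linkS4class{AttenuationMap} congruent with the projector
#' @return list (one per view) of voxel attenuation factors in the rotated
#'   frame
#' @export
attenuationFactors <- function(projector, mu) {
  if (is(mu, "AttenuationMap")) mu <- mu@mu
  if (!identical(dim(mu), as.integer(projector$dims)) &&
      !identical(dim(mu), projector$dims))
    stop("mu grid does not match the projector grid")
  n <- projector$dims[1]; nz <- projector$dims[3]
  sCm <- projector$spacing[2] / 10
  muMat <- matrix(mu, ncol = nz)
  lapply(projector$R, function(Rv) {
    mr <- array(as.matrix(Rv %*% muMat), c(n, n, nz))
    .attenCumulative(mr, sCm)
  })
}

## exp(-) of the trapezoidal path integral from each voxel to the detector
## (rays toward increasing dim-2 index)
.attenCumulative <- function(muRot, sCm) {
  n2 <- dim(muRot)[2]
  S <- muRot
  S[, n2, ] <- 0.5 * muRot[, n2, ]
  for (v in seq(n2 - 1, 1)) {
    S[, v, ] <- S[, v + 1, ] + 0.5 * (muRot[, v, ] + muRot[, v + 1, ])
  }
  exp(-sCm * S)
}

## single-view forward projection; x given as (nxy x nz) matrix
.forwardView <- function(xMat, proj, v, atten = NULL) {
  n <- proj$dims[1]; nz <- proj$dims[3]
  Xr <- array(as.matrix(proj$R[[v]] %*% xMat), c(n, n, nz))
  if (!is.null(atten)) Xr <- Xr * atten[[v]]
  P <- matrix(0, n, nz)
  for (b in seq_along(proj$Ku)) {
    vs <- which(proj$binOf == b)
    S <- Xr[, vs[1], ]
    for (j in vs[-1]) S <- S + Xr[, j, ]
    P <- P + proj$Ku[[b]] %*% S %*% proj$Kz[[b]]
  }
  P
}

## single-view backprojection (exact transpose of .forwardView)
.backView <- function(y, proj, v, atten = NULL) {
  n <- proj$dims[1]; nz <- proj$dims[3]
  acc <- array(0, c(n, n, nz))
  for (b in seq_along(proj$Ku)) {
    Tb <- proj$Ku[[b]] %*% y %*% proj$Kz[[b]]
    for (j in which(proj$binOf == b)) acc[, j, ] <- Tb
  }
  if (!is.null(atten)) acc <- acc * atten[[v]]
  as.matrix(Matrix::crossprod(proj$R[[v]], matrix(acc, n * n, nz)))
}

#' Forward-project a volume into sinogram space
#'
#' @param x volume array (or \linkS4class{DigitalPhantom} activity)
#' @param projector from \code{\link{spectProjector}}
#' @param views view indices (default all)
#' @param atten optional attenuation factors from
#'   \code{\link{attenuationFactors}}
#' @return array (detector u, axial z, view)
#' @export
forwardProject <- function(x, projector, views = NULL, atten = NULL) {
  if (is(x, "DigitalPhantom")) x <- x@activity
  if (is.null(views)) views <- seq_along(projector$R)
  n <- projector$dims[1]; nz <- projector$dims[3]
  xMat <- matrix(x, ncol = nz)
  out <- array(0, c(n, nz, length(views)))
  for (k in seq_along(views))
    out[, , k] <- .forwardView(xMat, projector, views[k], atten)
  out
}

#' Backproject a sinogram (adjoint of \code{\link{forwardProject}})
#'
#' @param y sinogram array (detector u, axial z, view)
#' @param projector from \code{\link{spectProjector}}
#' @param views view indices matching the third dimension of \code{y}
#' @param atten optional attenuation factors
#' @return volume array
#' @export
backProject <- function(y, projector, views = NULL, atten = NULL) {
  if (is.null(views)) views <- seq_along(projector$R)
  n <- projector$dims[1]; nz <- projector$dims[3]
  acc <- matrix(0, n * n, nz)
  for (k in seq_along(views))
    acc <- acc + .backView(y[, , k], projector, views[k], atten)
  array(acc, projector$dims)
}

.broadBlur <- function(P, proj) as.matrix(proj$KscU %*% P %*% proj$KscZ)

#' Simulate a SPECT acquisition
#'
#' Projects the phantom through the attenuated, collimator-blurred system
#' model, adds an energy-window scatter component (primary convolved with a
#' broad Gaussian kernel times the scatter fraction), scales total photopeak
#' counts to the protocol target, records the adjacent low-energy scatter
#' window, and Poisson-samples both unless \code{noise = FALSE}. The
#' scatter-window magnitude is scatterFraction / dewK times the blurred
#' primary, so that the dual-energy-window estimate k * window is unbiased
#' for the photopeak scatter.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param mu an \linkS4class{AttenuationMap} (attenuation is always part of
#'   the physics; the AC toggle lives in the reconstruction)
#' @param config an \linkS4class{AcquisitionConfig}
#' @param noise Poisson-sample the projections?
#' @param projector optional prebuilt projector (grid must match)
#' @param atten optional prebuilt attenuation factors for \code{mu}
#' @param recordScatterWindow acquire the adjacent scatter window? (without
#'   it, scatter-corrected reconstruction is impossible)
#' @return a \linkS4class{SinogramSet}
#' @export
projectSpect <- function(phantom, mu, config = acquisitionConfig(),
                         noise = TRUE, projector = NULL, atten = NULL,
                         recordScatterWindow = TRUE) {
  act <- phantom@activity
  if (!identical(dim(act), dim(mu@mu)))
    stop("activity and mu grids are not congruent")
  if (is.null(projector))
    projector <- spectProjector(dim(act), phantom@spacing, config)
  if (is.null(atten)) atten <- attenuationFactors(projector, mu)
  primary <- forwardProject(act, projector, atten = atten)
  nv <- dim(primary)[3]
  blurred <- primary
  for (v in seq_len(nv)) blurred[, , v] <- .broadBlur(primary[, , v], projector)
  peak <- primary + config@scatterFraction * blurred
  tot <- sum(peak)
  if (tot <= 0) {
    scale <- 0
  } else {
    scale <- config@spectTargetCounts / tot
  }
  peak <- peak * scale
  window <- blurred * (config@scatterFraction / config@dewK) * scale
  if (noise) {
    peak <- .withSeed(config@seed,
                      array(as.numeric(rpois(length(peak), peak)), dim(peak)))
    window <- .withSeed(config@seed + 1,
                        array(as.numeric(rpois(length(window), window)),
                              dim(window)))
  }
  if (!recordScatterWindow) window <- array(0, c(0, 0, 0))
  new("SinogramSet", photopeak = peak, scatterWindow = window,
      angles = projector$angles,
      pixelSpacing = projector$spacing[c(1, 3)], config = config)
}

.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

## planar projection along the y axis (dim 2); flip = TRUE views from behind
.planarView <- function(act, mu, spacing, config, flip = FALSE,
                        scatter = TRUE) {
  dims <- dim(act)
  if (flip) {
    act <- act[, rev(seq_len(dims[2])), , drop = FALSE]
    mu <- mu[, rev(seq_len(dims[2])), , drop = FALSE]
  }
  W <- .attenCumulative(mu, spacing[2] / 10)
  Xw <- act * W
  n <- dims[1]; nz <- dims[3]
  binOf <- ceiling((dims[2] - seq_len(dims[2]) + 1) / config@depthBin)
  P <- matrix(0, n, nz)
  for (b in seq_len(max(binOf))) {
    vs <- which(binOf == b)
    d <- mean(dims[2] - vs) * spacing[2] + config@detectorOffset
    sig <- (config@collimatorA + config@collimatorB * d) / (2 * sqrt(2 * log(2)))
    Ku <- .gaussKernelMatrix(n, spacing[1], sig, normalize = "sym")
    Kz <- .gaussKernelMatrix(nz, spacing[3], sig, normalize = "sym")
    S <- Xw[, vs[1], ]
    for (j in vs[-1]) S <- S + Xw[, j, ]
    P <- P + Ku %*% S %*% Kz
  }
  P <- as.matrix(P)
  if (scatter && config@scatterFraction > 0) {
    KsU <- .gaussKernelMatrix(n, spacing[1], config@scatterSigma, "sym")
    KsZ <- .gaussKernelMatrix(nz, spacing[3], config@scatterSigma, "sym")
    P <- P + config@scatterFraction * as.matrix(KsU %*% P %*% KsZ)
  }
  if (flip) P <- P[rev(seq_len(n)), , drop = FALSE]
  P
}

#' Simulate an anterior/posterior planar acquisition
#'
#' Attenuated line integrals toward each detector with depth-dependent
#' collimator blur and additive scatter; the anterior total is scaled to the
#' protocol's planar count target and the posterior view is scaled by the
#' same factor. Only the photopeak window is recorded, as in the clinic
#' planar protocol. The posterior image is left-right mirrored (viewed from
#' behind).
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @param mu an \linkS4class{AttenuationMap}
#' @param config an \linkS4class{AcquisitionConfig}
#' @param noise Poisson-sample the images?
#' @return a \linkS4class{PlanarPair}
#' @export
projectPlanar <- function(phantom, mu, config = acquisitionConfig(),
                          noise = TRUE) {
  act <- phantom@activity
  if (!identical(dim(act), dim(mu@mu)))
    stop("activity and mu grids are not congruent")
  ant <- .planarView(act, mu@mu, phantom@spacing, config, flip = FALSE)
  post <- .planarView(act, mu@mu, phantom@spacing, config, flip = TRUE)
  tot <- sum(ant)
  scale <- if (tot > 0) config@planarTargetCounts / tot else 0
  ant <- ant * scale
  post <- post * scale
  if (noise) {
    ant <- .withSeed(config@seed + 2,
                     matrix(as.numeric(rpois(length(ant), ant)), nrow(ant)))
    post <- .withSeed(config@seed + 3,
                      matrix(as.numeric(rpois(length(post), post)), nrow(post)))
  }
  new("PlanarPair", anterior = ant, posterior = post,
      pixelSpacing = phantom@spacing[c(1, 3)])
}

#' Planar liver/lung ROIs from the phantom ground truth
#'
#' Projects the liver (with lesions) and lung labels along the
#' anterior-posterior axis and returns 2-D masks on the planar grid; pixels
#' where the two organs overlap in projection are removed from both, keeping
#' the ROIs disjoint as drawn in the clinic. Posterior masks are mirrored to
#' match the posterior image orientation.
#'
#' @param phantom a \linkS4class{DigitalPhantom}
#' @return list with \code{liverAnt}, \code{liverPost}, \code{lungAnt},
#'   \code{lungPost} logical matrices
#' @export
planarROIs <- function(phantom) {
  lab <- phantom@labels
  proj2d <- function(mask) apply(mask, c(1, 3), any)
  liver <- proj2d(lab >= .LBL["liver"])
  lung <- proj2d(lab == .LBL["lungL"] | lab == .LBL["lungR"])
  both <- liver & lung
  liver <- liver & !both
  lung <- lung & !both
  mirror <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]
  list(liverAnt = liver, liverPost = mirror(liver),
       lungAnt = lung, lungPost = mirror(lung))
}
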