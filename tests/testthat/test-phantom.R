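test_that("volume solver reproduces the filling constraints", {
  specs <- solvePhantomVolumes()
  s <- specs$lsf3.6
  ## frozen from solving the 2x2 linear system by hand:
  ## V_lung = 0.036 * 195000 / 3; 75 V_nl = 93260.87; 390 V_le = 13893.04
  expect_equal(s@lungVolume, 2340, tolerance = 1e-6)
  expect_equal(s@liverVolume, 1243.478, tolerance = 1e-4)
  expect_equal(sum(s@lesionVolumes), 35.623, tolerance = 1e-3)
  ## substitution: 3*2340 / (3*2340 + 140*1243.478 + 390*35.623)
  expect_equal(s@trueLSF, 3.6, tolerance = 0.05)
  expect_equal(specs$lsf6.9@trueLSF, 6.9, tolerance = 0.05)
  expect_equal(s@totalActivity, 195, tolerance = 1 / 195)
  expect_equal(specs$lsf0@trueLSF, 0)
  expect_equal(specs$lsf0@lungConc, 0)
})

test_that("solver rejects degenerate constraint systems", {
  expect_error(solvePhantomVolumes(liverConcs = c(65, 65)), "singular")
  expect_error(solvePhantomVolumes(lsfTargets = c(6.9, 3.6)), "positive")
})

test_that("solver round-trips arbitrary volume sets", {
  set.seed(42)
  for (i in 1:5) {
    vols <- c(lung = runif(1, 1500, 4000), liver = runif(1, 800, 2000),
              les = runif(1, 20, 80))
    concs <- c(lung = 3, liver1 = 140, liver2 = 65, les = 390)
    lsf <- function(cLiver) {
      lungA <- concs["lung"] * vols["lung"]
      100 * lungA / (lungA + cLiver * vols["liver"] + concs["les"] * vols["les"])
    }
    tot <- (concs["lung"] * vols["lung"] + concs["liver1"] * vols["liver"] +
              concs["les"] * vols["les"]) / 1000
    got <- solvePhantomVolumes(lsfTargets = c(lsf(140), lsf(65)),
                               totalActivityMBq = tot)$lsf0
    expect_equal(got@lungVolume, unname(vols["lung"]), tolerance = 1e-3)
    expect_equal(got@liverVolume, unname(vols["liver"]), tolerance = 1e-3)
    expect_equal(sum(got@lesionVolumes), unname(vols["les"]),
                 tolerance = 1e-3)
  }
})

test_that("voxelized phantom honors volumes, activity and ground-truth shunt", {
  ph <- torsoPhantom64()
  spec <- phantomSpec(ph)
  expect_equal(labelLSF(ph), 3.6, tolerance = 0.1 / 3.6)
  voxML <- prod(voxelSpacing(ph)) / 1e3
  lab <- labelGrid(ph)
  expect_equal(sum(lab %in% 3:4) * voxML, spec@lungVolume, tolerance = 0.02)
  expect_equal(sum(lab == 5) * voxML, spec@liverVolume, tolerance = 0.02)
  expect_equal(sum(lab %in% 6:7) * voxML, sum(spec@lesionVolumes),
               tolerance = 0.05)
  totMBq <- sum(activityGrid(ph)) * prod(voxelSpacing(ph)) / 1e6
  expect_equal(totMBq, spec@totalActivity, tolerance = 0.01)
  expect_true(all(densityGrid(ph) %in% c(0.0012, 0.3, 1.0, 1.5)))
})

test_that("zero-activity spec gives an empty activity grid, and shunt is
           scale-invariant in the concentrations", {
  ph0 <- buildPhantom(solvePhantomVolumes()$lsf0, voxelMM = 6.4,
                      dims = c(64, 64, 64))
  expect_equal(labelLSF(ph0), 0)
  expect_true(all(activityGrid(ph0)[labelGrid(ph0) %in% 3:4] == 0))
  expect_identical(densityGrid(ph0), densityGrid(torsoPhantom64()))
  s <- solvePhantomVolumes()$lsf3.6
  s2 <- PhantomSpec(2 * s@lungConc, 2 * s@liverConc, 2 * s@lesionConc,
                    s@lungVolume, s@liverVolume, s@lesionVolumes)
  expect_equal(s2@trueLSF, s@trueLSF)
})

test_that("discretized shunt error shrinks as voxels refine", {
  spec <- solvePhantomVolumes()$lsf3.6
  errs <- vapply(c(8, 6, 4), function(v)
    abs(labelLSF(buildPhantom(spec, voxelMM = v)) - 3.6), 0)
  expect_true(all(diff(errs) < 1e-9))
  expect_lt(errs[length(errs)], 0.05)
})

test_that("breathing blur conserves activity and only smears superiorly-
           inferiorly", {
  ph <- torsoPhantom64()
  expect_identical(applyBreathingBlur(ph, 0), ph)
  expect_error(applyBreathingBlur(ph, -1), ">= 0")
  phb <- applyBreathingBlur(ph, 15)
  expect_equal(sum(activityGrid(phb)), sum(activityGrid(ph)),
               tolerance = 1e-3)
  expect_identical(densityGrid(phb), densityGrid(ph))
  expect_identical(labelGrid(phb), labelGrid(ph))
  ## liver activity spills into the lungs: the label-mask shunt rises
  expect_gt(labelLSF(phb), 3.6)
  ## activity in the inferior 2-cm lung band never decreases
  lung <- array(labelGrid(ph) %in% 3:4, dim(labelGrid(ph)))
  zs <- which(apply(lung, 3, any))
  nband <- ceiling(20 / voxelSpacing(ph)[3])
  band <- lung
  band[, , -(min(zs):(min(zs) + nband - 1))] <- FALSE
  expect_gte(sum(activityGrid(phb)[band]), sum(activityGrid(ph)[band]))
})

test_that("synthetic cohorts are seed-deterministic with faithful ground
           truth", {
  cs <- CohortSpec(3, seed = 5)
  a <- synthCohort(cs)
  b <- synthCohort(cs)
  expect_identical(a$truth, b$truth)
  expect_identical(activityGrid(a$patients[[2]]$phantom),
                   activityGrid(b$patients[[2]]$phantom))
  ## degenerate shunt distribution
  d <- synthCohort(CohortSpec(3, lsfMedian = 2, lsfLogSD = 0, seed = 1))
  expect_equal(d$truth$lsf_percent, rep(2, 3))
  ## lung mass = 0.3 kg/L * volume
  expect_equal(d$truth$lung_mass_kg, 0.3 * d$truth$lung_volume_L)
  expect_error(synthCohort(CohortSpec(0)), "nPatients")
})
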