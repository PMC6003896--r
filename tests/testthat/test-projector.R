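test_that("density-to-mu mapping is linear with a bone clip", {
  expect_equal(densityToMu(array(1, c(2, 2, 2)))@mu[1], 0.154)
  expect_equal(densityToMu(array(0.3, c(2, 2, 2)))@mu[1], 0.0462)
  expect_equal(densityToMu(array(0, c(2, 2, 2)))@mu[1], 0)
  expect_equal(densityToMu(array(1.9, c(2, 2, 2)))@mu[1], 0.25)
})

test_that("projector and backprojector are exact adjoints", {
  cfg <- tinyConfig()
  dims <- c(32, 32, 24)
  proj <- spectProjector(dims, c(8, 8, 8), cfg)
  mu <- new("AttenuationMap",
            mu = array(runif(prod(dims), 0, 0.15), dims),
            spacing = c(8, 8, 8))
  att <- attenuationFactors(proj, mu)
  set.seed(3)
  for (A in list(NULL, att)) {
    x <- array(runif(prod(dims)), dims)
    y <- array(runif(32 * 24 * cfg@nViews), c(32, 24, cfg@nViews))
    lhs <- sum(forwardProject(x, proj, atten = A) * y)
    rhs <- sum(x * backProject(y, proj, atten = A))
    expect_lt(abs(lhs - rhs) / abs(lhs), 1e-6)
  }
})

test_that("a central point source projects equally into every view", {
  cfg <- tinyConfig(collimatorA = 0, collimatorB = 0, scatterFraction = 0)
  dims <- c(33, 33, 17)
  proj <- spectProjector(dims, c(8, 8, 8), cfg)
  x <- array(0, dims)
  x[17, 17, 9] <- 1
  p <- forwardProject(x, proj)
  totals <- apply(p, 3, sum)
  expect_lt(diff(range(totals)) / mean(totals), 0.005)
})

test_that("zero activity produces all-zero sinograms; same seed reproduces
           the same noise", {
  ph <- torsoPhantom64()
  mu <- densityToMu(ph)
  zero <- initialize(ph, activity = array(0, dim(activityGrid(ph))),
                     spec = NULL)
  cfg <- acquisitionConfig(nViews = 12)
  s0 <- projectSpect(zero, mu, cfg, noise = FALSE)
  expect_true(all(s0@photopeak == 0) && all(s0@scatterWindow == 0))
  s1 <- projectSpect(ph, mu, cfg, noise = TRUE)
  s2 <- projectSpect(ph, mu, cfg, noise = TRUE)
  expect_identical(s1@photopeak, s2@photopeak)
  expect_true(all(s1@photopeak == round(s1@photopeak)))
})

test_that("without attenuation or scatter, anterior and posterior planar
           views are mirror images with unbiased organ ratios", {
  ph <- torsoPhantom64()
  muFree <- new("AttenuationMap", mu = array(0, dim(activityGrid(ph))),
                spacing = voxelSpacing(ph))
  cfg <- acquisitionConfig(scatterFraction = 0, collimatorA = 0,
                           collimatorB = 0)
  pl <- projectPlanar(ph, muFree, cfg, noise = FALSE)
  mirrored <- pl@posterior[rev(seq_len(nrow(pl@posterior))), ]
  expect_equal(pl@anterior, mirrored, tolerance = 1e-8)
  rois <- planarROIs(ph)
  est <- planarLSF(pl, list(ant = rois$liverAnt, post = rois$liverPost),
                   list(ant = rois$lungAnt, post = rois$lungPost),
                   "ant_post")
  ## ROI-restricted counts track the activity ratio closely (the ROIs
  ## exclude the small projected organ overlap)
  expect_equal(lsfPercent(est), 3.6, tolerance = 0.03)
  gm <- planarLSF(pl, list(ant = rois$liverAnt, post = rois$liverPost),
                  list(ant = rois$lungAnt, post = rois$lungPost),
                  "geometric_mean")
  expect_equal(lsfPercent(gm), lsfPercent(est), tolerance = 0.01)
})

test_that("mismatched activity and mu grids are rejected", {
  ph <- torsoPhantom64()
  muBad <- new("AttenuationMap", mu = array(0.1, c(8, 8, 8)),
               spacing = c(4, 4, 4))
  expect_error(projectPlanar(ph, muBad), "congruent")
  expect_error(projectSpect(ph, muBad), "congruent")
})
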