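test_that("3-D morphology primitives behave on constructed shapes", {
  m <- array(FALSE, c(12, 12, 12))
  m[2:5, 2:5, 2:5] <- TRUE          # blob A, 64 voxels
  m[8:11, 8:11, 8:11] <- TRUE       # blob B, 64 voxels
  m[7, 2, 2] <- TRUE                # single-voxel speck
  lab <- labelComponents3d(m)
  expect_equal(max(lab), 3)
  expect_equal(sort(tabulate(lab[lab > 0])), c(1, 64, 64))
  ## hole filling
  h <- array(FALSE, c(10, 10, 10))
  h[2:9, 2:9, 2:9] <- TRUE
  h[5:6, 5:6, 5:6] <- FALSE         # interior cavity
  expect_true(all(fillHoles3d(h)[2:9, 2:9, 2:9]))
  ## open notch survives filling (touches the border)
  h2 <- h; h2[5:6, 5:6, 1:9] <- FALSE
  expect_false(any(fillHoles3d(h2)[5:6, 5:6, 1]))
})

test_that("whole-body VOI recovers the body and is idempotent", {
  ph <- torsoPhantom64()
  ct <- syntheticCT(ph)
  body <- wholeBodyVOI(ct)
  truthVox <- sum(labelGrid(ph) > 0)
  expect_lt(abs(sum(body) - truthVox) / truthVox, 0.02)
  ## idempotence: segmenting the body-masked CT returns the same mask
  ct2 <- ct
  ct2[!body] <- -1000
  expect_identical(wholeBodyVOI(ct2), body)
  expect_error(wholeBodyVOI(array(-1000, c(8, 8, 8))), "empty body")
})

test_that("lung VOI recovers the solved lung volume and drops small air
           pockets", {
  ph <- torsoPhantom64()
  ct <- syntheticCT(ph)
  body <- wholeBodyVOI(ct)
  lungs <- lungVOI(ct, body, voxelSpacing(ph))
  voxML <- prod(voxelSpacing(ph)) / 1e3
  got <- (sum(lungs$left) + sum(lungs$right)) * voxML
  expect_lt(abs(got - 2340) / 2340, 0.05)
  ## left/right split matches the generating labels
  expect_gt(sum(lungs$left & labelGrid(ph) == 3) / sum(lungs$left), 0.99)
  ## a ~10 mL air pocket in the abdomen is removed by the volume filter
  ct3 <- ct
  ct3[30:32, 34:36, 12:14] <- -900
  lungs3 <- lungVOI(ct3, wholeBodyVOI(ct3), voxelSpacing(ph))
  expect_false(any((lungs3$left | lungs3$right)[30:32, 34:36, 12:14]))
  ## no candidates under the lock is an error
  ctSolid <- ct
  ctSolid[ctSolid <= -150 & body] <- 0
  expect_error(lungVOI(ctSolid, body, voxelSpacing(ph)), "no lung")
})

test_that("inferior exclusion removes whole slices per lung", {
  d <- c(8, 8, 50)
  lungA <- array(FALSE, d); lungA[2:4, 2:4, 5:44] <- TRUE  # 40 slices
  lungB <- array(FALSE, d); lungB[6:8, 2:4, 9:44] <- TRUE
  out <- excludeInferior(list(left = lungA, right = lungB), 2,
                         c(2.5, 2.5, 2.5))
  expect_equal(attr(out, "exclusionMM"), 20)
  ## 2 cm at 2.5 mm slices = 8 slices, counted from each lung's own base
  expect_equal(which(apply(out & lungA, 3, any))[1], 13)
  expect_equal(which(apply(out & lungB, 3, any))[1], 17)
  expect_equal(sum(lungA) - sum(out & lungA), 9 * 8)
  ## zero margin is the identity
  id <- excludeInferior(list(left = lungA, right = lungB), 0, c(2.5, 2.5, 2.5))
  expect_equal(sum(xor(id, lungA | lungB)), 0)
  expect_error(excludeInferior(list(left = lungA), 50, c(2.5, 2.5, 2.5)),
               "exceeds")
})

test_that("liver VOI presets behave at the limits", {
  cfg <- segmentationConfig()
  expect_equal(cfg@liverPresets, c(0.5, 1, 2, 5, 10))
  rec <- torsoRecon36()$recon
  lv <- liverVOI(rec)
  expect_equal(lv$preset, 2)
  expect_equal(lv$presets, c(0.5, 1, 2, 5, 10))
  ## 100% keeps only the hottest voxel's component
  top <- liverVOI(rec, preset = 100)
  expect_lt(sum(top$mask), 10)
  expect_error(liverVOI(array(0, c(4, 4, 4)), spacing = c(4, 4, 4)),
               "all-zero")
})

test_that("lung count extrapolation is exact for uniform activity and
           robust to a partial FOV", {
  d <- c(16, 16, 30)
  lung <- array(FALSE, d); lung[4:13, 4:13, 6:25] <- TRUE
  em <- array(0, d); em[lung] <- 3
  sp <- c(4, 4, 4)
  volL <- sum(lung) * prod(sp) / 1e6
  full <- estimateLungCounts(em, lung, volL, sp)
  expect_equal(full, sum(em), tolerance = 0.01)
  fov <- array(FALSE, d); fov[, , 16:30] <- TRUE
  half <- estimateLungCounts(em, lung, volL, sp, inFovMask = fov)
  expect_equal(half, full, tolerance = 0.02)
  expect_equal(estimateLungCounts(em * 0, lung, volL, sp), 0)
  noFov <- array(FALSE, d)
  expect_error(estimateLungCounts(em, lung, volL, sp, inFovMask = noFov),
               "no lung in FOV")
})

test_that("full segmentation result satisfies its structural invariants", {
  tr <- torsoRecon36()
  ph <- tr$phantom
  seg <- segmentStudy(syntheticCT(ph), tr$recon, voxelSpacing(ph))
  expect_s4_class(seg, "SegmentationResult")
  expect_true(validObject(seg))
  ## exclusion affects counts only: the recorded lung volume is pre-exclusion
  voxL <- prod(voxelSpacing(ph)) / 1e6
  expect_equal(seg@lungVolumeL,
               (sum(seg@leftLungMask) + sum(seg@rightLungMask)) * voxL)
  expect_gt(sum(seg@leftLungMask | seg@rightLungMask), sum(seg@lungMaskExcl))
})
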