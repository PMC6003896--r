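test_that("shunt-from-counts implements the defining ratio", {
  expect_equal(lsfPercent(lsfFromCounts(0, 1000)), 0)
  expect_equal(lsfPercent(lsfFromCounts(36, 964)), 3.6)
  ## solved phantom activities at the 6.9% configuration:
  ## lung 3 * 2340 = 7020 kBq; liver 65 * 1243.478 + 390 * 35.623 = 94719 kBq
  expect_equal(lsfPercent(lsfFromCounts(7020, 94719.13)), 6.90,
               tolerance = 0.001)
  expect_error(lsfFromCounts(0, 0), "no counts")
  expect_error(lsfFromCounts(-1, 10), ">= 0")
  ## scale invariance
  set.seed(9)
  for (i in 1:5) {
    a <- runif(1, 1, 100); b <- runif(1, 100, 1e4); c <- runif(1, 0.1, 1e4)
    expect_equal(lsfPercent(lsfFromCounts(a * c, b * c)),
                 lsfPercent(lsfFromCounts(a, b)))
  }
})

test_that("planar methods agree when views are identical and reject empty
           ROIs", {
  img <- matrix(runif(64, 10, 50), 8, 8)
  pair <- new("PlanarPair", anterior = img, posterior = img,
              pixelSpacing = c(4, 4))
  liver <- matrix(FALSE, 8, 8); liver[1:4, ] <- TRUE
  lung <- matrix(FALSE, 8, 8); lung[6:8, ] <- TRUE
  ap <- planarLSF(pair, liver, lung, "ant_post")
  gm <- planarLSF(pair, liver, lung, "geometric_mean")
  expect_equal(lsfPercent(ap), lsfPercent(gm))
  expect_error(planarLSF(pair, matrix(FALSE, 8, 8), lung), "empty ROI")
})

test_that("volumetric shunt is a pure ratio of its count inputs", {
  vol <- array(runif(4^3, 0, 5), c(4, 4, 4))
  mask <- array(c(TRUE, FALSE), c(4, 4, 4))
  a <- volumetricLSF(vol, mask, 100)
  expect_equal(a@method, "volumetric")
  expect_equal(lsfPercent(volumetricLSF(vol, mask, 0)), 0)
  b <- volumetricLSF(vol * 2, mask, 200)
  expect_equal(lsfPercent(a), lsfPercent(b))
  expect_error(volumetricLSF(vol, mask & FALSE, 10), "empty")
})

test_that("CT lung mass uses the 0.3 kg/L density", {
  expect_equal(lungMassFromCT(1), 0.3)
  expect_equal(lungMassFromCT(2.9), 0.87)
  expect_error(lungMassFromCT(0), "> 0")
})

test_that("MIRD lung dose reproduces the worked values and is linear", {
  expect_equal(doseGy(lungDose(1, 1, 100, "percent")), 49.38)
  expect_equal(doseGy(lungDose(3, 0.9, 0, "percent")), 0)
  ## inverted from the reported 29.4 Gy at 13.6% shunt and 1 kg
  expect_equal(doseGy(lungDose(4.377, 1, 13.6, "percent")), 29.4,
               tolerance = 0.002)
  expect_error(lungDose(1, 0, 10), "> 0")
  expect_error(lungDose(1, 1, 120, "percent"), "outside")
  ## linear in activity and shunt, inverse in mass
  d0 <- doseGy(lungDose(2, 0.8, 5, "percent"))
  expect_equal(doseGy(lungDose(4, 0.8, 5, "percent")), 2 * d0)
  expect_equal(doseGy(lungDose(2, 0.8, 10, "percent")), 2 * d0)
  expect_equal(doseGy(lungDose(2, 1.6, 5, "percent")), d0 / 2)
  ## percent and fraction tags give the same dose
  expect_equal(doseGy(lungDose(2, 0.8, 3.6, "percent")),
               doseGy(lungDose(2, 0.8, 0.036, "fraction")))
  ## two administrations combine additively
  expect_equal(doseGy(lungDose(c(2, 3), 1, c(5, 10), "percent")),
               doseGy(lungDose(2, 1, 5, "percent")) +
                 doseGy(lungDose(3, 1, 10, "percent")))
})
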