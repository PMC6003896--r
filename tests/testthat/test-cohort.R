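recs <- patientLSFTable()

test_that("the packaged patient table passes its integrity checks", {
  expect_equal(nrow(recs), 40)
  expect_equal(sum(!is.na(recs$lsf_pet_acsc)), 20)
  ok <- recs[, -1]
  expect_true(all(ok >= 0 & ok <= 100, na.rm = TRUE))
  ## the value checksum would flag any edit of the shipped fixture
  ck <- shuntQuant:::.PATIENT_TABLE_CHECKSUM
  expect_equal(sum(recs[, -1], na.rm = TRUE), ck$total)
})

test_that("cohort summaries reproduce the published means and ranges", {
  pl <- summarizeLSF(recs, "planar")
  expect_equal(round(pl$mean, 1), 5.4)
  expect_equal(c(pl$min, pl$max), c(1.2, 15.7))
  sp <- summarizeLSF(recs, "spect_acsc")
  expect_equal(round(sp$mean, 1), 1.5)
  expect_equal(c(sp$min, sp$max), c(0.4, 6.0))
  ## PET subset (n = 20)
  expect_equal(round(summarizeLSF(recs, "planar", "pet_only")$mean, 1), 4.1)
  expect_equal(round(summarizeLSF(recs, "spect_acsc", "pet_only")$mean, 1),
               1.0)
  pet <- summarizeLSF(recs, "pet_acsc", "pet_only")
  expect_equal(round(pet$mean, 1), 1.0)
  expect_equal(c(pet$min, pet$max), c(0.3, 2.8))
  one <- summarizeLSF(recs[5, ], "planar")
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  expect_error(summarizeLSF(recs[0, ], "planar"), "empty")
})

test_that("paired t matches the reference implementation and the published
           decisions", {
  same <- pairedT(cbind(recs, lsf_copy = recs$lsf_planar),
                  "planar", "copy")
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  ## oracle: stats::t.test on the same pairs
  for (pair in list(c("spect_acsc", "pet_acsc"), c("planar", "pet_acsc"),
                    c("planar", "spect_acsc"))) {
    sub <- if (any(grepl("pet", pair))) "pet_only" else "all"
    got <- pairedT(recs, pair[1], pair[2], sub)
    r <- recs[!is.na(recs$lsf_pet_acsc) | sub == "all", ]
    ref <- t.test(r[[paste0("lsf_", pair[1])]],
                  r[[paste0("lsf_", pair[2])]], paired = TRUE)
    expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }
  ## SPECT vs PET: no significant difference (published p = 0.968 from
  ## full-precision values; the printed table gives 0.95)
  expect_gt(pairedT(recs, "spect_acsc", "pet_acsc", "pet_only")$p, 0.9)
  ## planar vs PET: strongly significant (published p = 0.0002)
  expect_lt(pairedT(recs, "planar", "pet_acsc", "pet_only")$p, 0.001)
  ## planar vs SPECT over all 40: p < 0.0001
  expect_lt(pairedT(recs, "planar", "spect_acsc")$p, 1e-4)
  expect_error(pairedT(recs[1, ], "planar", "spect_acsc"), "n >= 2")
})

test_that("paired t agrees with a sign-flip permutation test on the
           planar-vs-PET contrast", {
  r <- recs[!is.na(recs$lsf_pet_acsc), ]
  d <- r$lsf_planar - r$lsf_pet_acsc
  set.seed(17)
  tObs <- mean(d) / (sd(d) / sqrt(length(d)))
  perm <- replicate(4000, {
    s <- d * sample(c(-1, 1), length(d), replace = TRUE)
    mean(s) / (sd(s) / sqrt(length(s)))
  })
  pPerm <- mean(abs(perm) >= abs(tObs))
  expect_lt(pPerm, 0.01)
  expect_lt(pairedT(recs, "planar", "pet_acsc", "pet_only")$p, 0.01)
})

test_that("correlation, ratio and difference statistics reproduce the
           published values", {
  expect_equal(pearsonR2(cbind(recs, lsf_lin = 2 * recs$lsf_planar + 1),
                         "planar", "lin"), 1)
  expect_equal(pearsonR2(cbind(recs, lsf_anti = -recs$lsf_planar),
                         "planar", "anti"), 1)
  ## published R^2 = 0.46 was computed from full-precision clinic values;
  ## the printed 1-dp table gives 0.42
  expect_equal(pearsonR2(recs, "planar", "spect_acsc"), 0.46,
               tolerance = 0.05 / 0.46)
  expect_error(pearsonR2(cbind(recs, lsf_const = 1), "planar", "const"),
               "variance")

  rm <- ratioMean(recs, "planar", "spect_acsc")
  expect_equal(round(rm$meanOfRatios, 1), 4.3)
  expect_equal(round(rm$ratioOfMeans, 1), 3.6)
  expect_equal(ratioMean(recs, "planar", "planar")$meanOfRatios, 1)
  bad <- recs; bad$lsf_spect_acsc[7] <- 0
  expect_error(ratioMean(bad, "planar", "spect_acsc"), "patient 7")

  dPl <- diffStats(recs, "planar", "pet_acsc", "pet_only", 5)
  expect_equal(dPl$maxAbsDiff, 12.3)
  expect_equal(dPl$countExceeding, 3)
  dSp <- diffStats(recs, "spect_acsc", "pet_acsc", "pet_only", 5)
  expect_equal(dSp$maxAbsDiff, 1.6)
  expect_equal(dSp$countExceeding, 0)
  self <- diffStats(recs, "planar", "planar")
  expect_equal(c(self$maxAbsDiff, self$countExceeding), c(0, 0))
})

test_that("paired t holds its nominal type-I error on null cohorts", {
  set.seed(23)
  n <- 20
  hits <- replicate(2000, {
    base <- rlnorm(n, 0, 0.5)
    a <- base + rnorm(n, 0, 0.3)
    b <- base + rnorm(n, 0, 0.3)
    r <- data.frame(lsf_a = a, lsf_b = b)
    pairedT(r, "a", "b")$p < 0.05
  })
  expect_equal(mean(hits), 0.05, tolerance = 0.02 / 0.05)
})
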