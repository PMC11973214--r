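test_that("the phantom carries the declared labels, bounded intensities and is deterministic", {
  ph <- makePhantom(phantomSpec(shape = c(24, 24, 24)))
  expect_setequal(unique(as.vector(voxelData(ph$seg))), c(0, 2, 4, 43, 17, 53))
  expect_gte(min(voxelData(ph$template)), 0)
  expect_lte(max(voxelData(ph$template)), 1)
  ph2 <- makePhantom(phantomSpec(shape = c(24, 24, 24)))
  expect_identical(voxelData(ph$template), voxelData(ph2$template))
  expect_identical(voxelData(ph$seg), voxelData(ph2$seg))
})

test_that("overlapping or non-nested phantom structures are rejected", {
  sp <- phantomSpec(shape = c(24, 24, 24))
  sp$ventricles[[2]]$center <- sp$ventricles[[1]]$center + c(1, 0, 0)
  expect_error(makePhantom(sp), "overlap")
  sp <- phantomSpec(shape = c(24, 24, 24))
  sp$hippocampi[[1]]$center <- c(2, 2, 2)
  expect_error(makePhantom(sp), "nested")
})

test_that("the synthetic aging field scales linearly and vanishes at zero rate", {
  ph <- testPhantom()
  z <- makeAgingField(ph$template, ph$seg, ph$spec, rate = 0)
  expect_identical(max(abs(voxelData(z))), 0)
  v1 <- makeAgingField(ph$template, ph$seg, ph$spec, rate = 0.03)
  v2 <- makeAgingField(ph$template, ph$seg, ph$spec, rate = 0.06)
  expect_identical(voxelData(v2), 2 * voxelData(v1))
  # zero outside the brain
  outside <- rep(voxelData(ph$seg) == 0, 3)
  expect_true(all(voxelData(v1)[outside] == 0))
})

test_that("30 years of the aging flow enlarges ventricles and shrinks hippocampi", {
  sp <- phantomSpec(shape = c(48, 48, 48))
  ph <- makePhantom(sp)
  v <- makeAgingField(ph$template, ph$seg, sp, rate = 0.05)
  segOld <- warpVolume(ph$seg, integrateSVF(VelocityField(30 * voxelData(v))))
  ventBefore <- sum(voxelData(ph$seg) %in% c(4, 43))
  ventAfter <- sum(voxelData(segOld) %in% c(4, 43))
  hipBefore <- sum(voxelData(ph$seg) %in% c(17, 53))
  hipAfter <- sum(voxelData(segOld) %in% c(17, 53))
  expect_gt(ventAfter, ventBefore)
  expect_lt(hipAfter, hipBefore)
})

test_that("planted subject parameters are recovered exactly without noise", {
  ph <- testPhantom()
  vAge <- makeAgingField(ph$template, ph$seg, ph$spec, rate = 0.05)
  # degenerate subject: nothing planted, nothing happens
  s0 <- makeSubject(ph$template, vAge, asTrue = 0, adsTrue = 0,
                    noiseSigma = 0, seed = 1)
  expect_identical(max(abs(voxelData(s0$svfTrue))), 0)
  expect_equal(voxelData(s0$image), voxelData(ph$template), tolerance = 1e-12)
  # pure aging
  s5 <- makeSubject(ph$template, vAge, asTrue = 5, adsTrue = 0,
                    noiseSigma = 0, seed = 1, warpImage = FALSE)
  sm <- decomposeVoxelwise(s5$svfTrue, vAge)
  m <- regionMask("ventricles", ph$seg)
  agg <- aggregateRegion(rejectOutliers(sm, vAge, m, 0))
  expect_equal(agg$AS, 5, tolerance = 1e-3)
  expect_lt(agg$ADS, 1e-3)
  # aging plus orthogonal disease component
  s <- makeSubject(ph$template, vAge, asTrue = 2, adsTrue = 0.7,
                   noiseSigma = 0, seed = 2, warpImage = FALSE)
  sm <- decomposeVoxelwise(s$svfTrue, vAge)
  agg <- aggregateRegion(rejectOutliers(sm, vAge, m, 0))
  expect_equal(agg$AS, 2, tolerance = 1e-3)
  expect_equal(agg$ADS, 0.7, tolerance = 1e-3)
})

test_that("the planted disease direction is voxel-wise orthogonal to the aging field", {
  ph <- testPhantom()
  vAge <- makeAgingField(ph$template, ph$seg, ph$spec, rate = 0.05)
  s <- makeSubject(ph$template, vAge, asTrue = 1, adsTrue = 0.5,
                   noiseSigma = 0, seed = 9, warpImage = FALSE)
  wa <- matrix(voxelData(s$w), ncol = 3)
  va <- matrix(voxelData(vAge), ncol = 3)
  act <- sqrt(rowSums(va^2)) > 1e-8
  dots <- abs(rowSums(wa[act, ] * va[act, ]))
  expect_lt(max(dots), 1e-6)
  # unit magnitude on the active support
  expect_equal(range(sqrt(rowSums(wa[act, ]^2))), c(1, 1), tolerance = 1e-9)
})

test_that("cohort generation is reproducible and writes a coherent layout", {
  spec <- cohortSpec(nPerGroup = c(CN = 4L, CDR1 = 2L),
                     noiseSigma = 0.02, seed = 5L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  c1 <- makeCohort(spec, d1, shape = c(20, 20, 20), images = TRUE)
  c2 <- makeCohort(spec, d2, shape = c(20, 20, 20), images = TRUE)
  expect_identical(c1$truth[, -1], c2$truth[, -1])
  expect_equal(nrow(c1$truth), 6)
  expect_true(all(file.exists(unlist(c1$files))))
  expect_true(all(file.exists(file.path(d1, "svf",
                                        paste0(c1$truth$scan_id, ".nii.gz")))))
  expect_true(all(file.exists(file.path(d1, "img",
                                        paste0(c1$truth$scan_id, ".nii.gz")))))
  svf1 <- loadExternalSVF(file.path(d1, "svf", "scan001.nii.gz"))
  svf2 <- loadExternalSVF(file.path(d2, "svf", "scan001.nii.gz"))
  expect_identical(voxelData(svf1), voxelData(svf2))
  # empty group: valid but empty outputs
  c0 <- makeCohort(cohortSpec(nPerGroup = c(CN = 0L)),
                   withr::local_tempdir(), shape = c(16, 16, 16),
                   images = FALSE)
  expect_equal(nrow(c0$truth), 0)
  expect_true(file.exists(file.path(c0$dir, "demographics.csv")))
})
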