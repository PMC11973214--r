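# Independent per-voxel projection oracle: least-squares coefficient of one
# 3-vector on another via qr(), residual norm from the fitted residuals —
# a different code path from the vectorized decomposition.
oracleProject <- function(vs, v0) {
  fit <- lsfit(matrix(v0, ncol = 1), vs, intercept = FALSE)
  list(a = unname(fit$coefficients), r = sqrt(sum(fit$residuals^2)))
}

test_that("voxel-wise decomposition recovers planted coefficients against a projection oracle", {
  d <- c(10, 10, 100)   # 10^4 voxels
  n <- prod(d)
  set.seed(17)
  v0m <- matrix(rnorm(n * 3), ncol = 3)
  a <- runif(n, -2, 2)
  wm <- matrix(rnorm(n * 3), ncol = 3)
  wm <- wm - (rowSums(wm * v0m) / rowSums(v0m^2)) * v0m   # per-voxel orthogonal
  wn <- sqrt(rowSums(wm^2))
  wm <- wm / wn * runif(n, 0, 1)
  vsm <- a * v0m + wm
  sm <- decomposeVoxelwise(VelocityField(array(vsm, c(d, 3))),
                           VelocityField(array(v0m, c(d, 3))))
  expect_true(all(sm@validMask))
  expect_lt(max(abs(as.vector(sm@asMap) - a)), 1e-6)
  expect_lt(max(abs(as.vector(sm@adsMap) - sqrt(rowSums(wm^2)))), 1e-6)
  # spot-check 25 voxels against the independent qr-based oracle
  idx <- sample(n, 25)
  for (i in idx) {
    o <- oracleProject(vsm[i, ], v0m[i, ])
    expect_equal(as.vector(sm@asMap)[i], o$a, tolerance = 1e-8)
    expect_equal(as.vector(sm@adsMap)[i], o$r, tolerance = 1e-8)
  }
})

test_that("projection identities: parallel, orthogonal and anti-parallel fields", {
  d <- c(6, 6, 6)
  set.seed(4)
  v0 <- VelocityField(array(rnorm(prod(d) * 3, sd = 1), c(d, 3)))
  # subject identical to v0: AS = 1, ADS = 0
  sm <- decomposeVoxelwise(v0, v0)
  expect_lt(max(abs(sm@asMap - 1)), 1e-12)
  expect_lt(max(sm@adsMap), 1e-6)
  # anti-parallel subject: negative AS (slower-than-normal aging)
  sm <- decomposeVoxelwise(VelocityField(-3 * voxelData(v0)), v0)
  expect_lt(max(abs(sm@asMap + 3)), 1e-12)
  # voxel-wise orthogonal subject of magnitude m: AS = 0, ADS = m
  w <- dbmaging:::.orthogonalUnitField(voxelData(v0))
  sm <- decomposeVoxelwise(VelocityField(0.8 * w), v0)
  expect_lt(max(abs(sm@asMap)), 1e-9)
  expect_lt(max(abs(sm@adsMap - 0.8)), 1e-9)
})

test_that("Pythagoras and scaling invariants hold per voxel", {
  d <- c(8, 8, 8)
  set.seed(23)
  v0 <- VelocityField(array(rnorm(prod(d) * 3), c(d, 3)))
  vs <- VelocityField(array(rnorm(prod(d) * 3), c(d, 3)))
  sm <- decomposeVoxelwise(vs, v0)
  n0 <- dbmaging:::.fieldNorm(voxelData(v0))
  ns <- dbmaging:::.fieldNorm(voxelData(vs))
  lhs <- ns^2
  rhs <- (sm@asMap * n0)^2 + sm@adsMap^2
  expect_lt(max(abs(lhs - rhs) / pmax(lhs, 1e-12)), 1e-6)
  # linearity: scaling the subject scales AS by alpha, ADS by |alpha|
  for (alpha in c(2.5, -1.5)) {
    sm2 <- decomposeVoxelwise(VelocityField(alpha * voxelData(vs)), v0)
    expect_equal(sm2@asMap, alpha * sm@asMap, tolerance = 1e-10)
    expect_equal(sm2@adsMap, abs(alpha) * sm@adsMap, tolerance = 1e-10)
  }
})

test_that("voxels with negligible aging-field magnitude are marked invalid", {
  d <- c(6, 6, 6)
  v0a <- array(0, c(d, 3)); v0a[, , 1:3, 1] <- 1
  vs <- VelocityField(array(1, c(d, 3)))
  sm <- decomposeVoxelwise(vs, VelocityField(v0a))
  expect_identical(sm@validMask, array(v0a[, , , 1] != 0, d))
  expect_true(all(is.na(sm@asMap[!sm@validMask])))
})

test_that("quantile outlier rejection matches a sort-based oracle and is monotone", {
  d <- c(6, 6, 6)
  n <- prod(d)
  set.seed(8)
  norms <- sample(seq(0.1, 2, length.out = n))   # distinct magnitudes
  v0a <- array(0, c(d, 3)); v0a[, , , 1] <- norms
  v0 <- VelocityField(v0a)
  vs <- VelocityField(array(rnorm(n * 3), c(d, 3)))
  sm <- decomposeVoxelwise(vs, v0)
  region <- array(TRUE, d)
  # quantile 0 retains every valid in-region voxel
  expect_equal(aggregateRegion(rejectOutliers(sm, v0, region, 0))$nVoxels, n)
  # quantile 0.5 with distinct values retains the upper half (sort oracle)
  kept <- rejectOutliers(sm, v0, region, 0.5)
  thr <- quantile(norms, 0.5, type = 7)
  expect_equal(sum(kept@validMask), sum(norms >= thr))
  expect_equal(sum(kept@validMask), ceiling(n / 2))
  expect_identical(kept@validMask, array(v0a[, , , 1] >= thr, d))
  # retained counts are non-increasing over the quantile grid
  counts <- vapply(seq(0, 0.9, 0.1), function(q)
    sum(rejectOutliers(sm, v0, region, q)@validMask), numeric(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(rejectOutliers(sm, v0, region, 1), "quantile")
  expect_error(rejectOutliers(sm, v0, array(FALSE, d), 0), "no valid voxels")
})

test_that("regional aggregation is the arithmetic mean over retained voxels", {
  d <- c(5, 5, 5)
  asm <- array(2.5, d); adsm <- array(0.3, d)
  sm <- new("ScoreMap", asMap = asm, adsMap = adsm,
            validMask = array(TRUE, d))
  agg <- aggregateRegion(sm)
  expect_equal(agg$AS, 2.5)
  expect_equal(agg$ADS, 0.3)
  # two-voxel mean
  vm <- array(FALSE, d); vm[1] <- TRUE; vm[2] <- TRUE
  asm[1] <- 1; asm[2] <- 3
  sm <- new("ScoreMap", asMap = asm, adsMap = adsm, validMask = vm)
  expect_equal(aggregateRegion(sm)$AS, 2)
  # random map against an independent mean
  set.seed(12)
  asm <- array(rnorm(prod(d)), d); adsm <- array(abs(rnorm(prod(d))), d)
  vm <- array(rbinom(prod(d), 1, 0.6) == 1, d)
  sm <- new("ScoreMap", asMap = asm, adsMap = adsm, validMask = vm)
  agg <- aggregateRegion(sm)
  expect_equal(agg$AS, sum(asm[vm]) / sum(vm), tolerance = 1e-12)
  expect_equal(agg$ADS, sum(adsm[vm]) / sum(vm), tolerance = 1e-12)
})

test_that("quantile selection maximizes the CN AS-age fit", {
  grid <- seq(0, 0.9, 0.1)
  # exact linear AS with no noise: R^2 = 1 everywhere, smallest tie chosen
  ages <- seq(61, 89, length.out = 15)
  rec <- do.call(rbind, lapply(grid, function(q)
    data.frame(quantile = q, age = ages, AS = ages - 60, nVoxels = 100)))
  sel <- selectQuantile(rec, grid)
  expect_equal(sel@r2PerQuantile, rep(1, 10), tolerance = 1e-12)
  expect_equal(sel@chosenQuantile, 0)
  # R^2 values match the closed-form simple-regression oracle
  set.seed(99)
  rec2 <- do.call(rbind, lapply(grid, function(q)
    data.frame(quantile = q, age = ages,
               AS = (ages - 60) + rnorm(15, sd = 3 * (1 - q)),
               nVoxels = round(100 * (1 - q)) + 1)))
  sel2 <- selectQuantile(rec2, grid)
  for (i in seq_along(grid)) {
    sub <- rec2[abs(rec2$quantile - grid[i]) < 1e-9, ]
    sst <- sum((sub$AS - mean(sub$AS))^2)
    b <- sum((sub$age - mean(sub$age)) * (sub$AS - mean(sub$AS))) /
         sum((sub$age - mean(sub$age))^2)
    sse <- sum((sub$AS - mean(sub$AS) - b * (sub$age - mean(sub$age)))^2)
    expect_equal(sel2@r2PerQuantile[i], 1 - sse / sst, tolerance = 1e-10)
  }
  expect_equal(sel2@chosenQuantile,
               grid[which.max(sel2@r2PerQuantile)])
  expect_error(selectQuantile(data.frame(quantile = 0, age = rep(70, 5),
                                         AS = rnorm(5)), grid = 0),
               "zero variance")
})

test_that("rejection by aging-field magnitude raises the CN fit when noise sits at small magnitudes", {
  # planted-noise simulation: constant-amplitude SVF noise makes the
  # voxel-wise AS noisiest exactly where ||v0|| is smallest, so thresholding
  # on ||v0|| must improve the AS-age fit.
  d <- c(12, 12, 12)
  n <- prod(d)
  set.seed(55)
  mag <- array(runif(n, 0.02, 1), d)
  v0a <- array(0, c(d, 3)); v0a[, , , 1] <- mag
  v0 <- VelocityField(v0a)
  region <- array(TRUE, d)
  grid <- seq(0, 0.9, 0.1)
  ages <- runif(50, 60, 90)
  rows <- list()
  for (s in seq_len(50)) {
    vs <- (ages[s] - 60) * v0a + array(rnorm(n * 3, sd = 0.15), c(d, 3))
    sm <- decomposeVoxelwise(VelocityField(vs), v0)
    for (q in grid) {
      agg <- aggregateRegion(rejectOutliers(sm, v0, region, q))
      rows[[length(rows) + 1L]] <- data.frame(quantile = q, age = ages[s],
                                              AS = agg$AS,
                                              nVoxels = agg$nVoxels)
    }
  }
  sel <- selectQuantile(do.call(rbind, rows), grid)
  expect_gt(sel@chosenQuantile, 0)
  expect_gte(max(sel@r2PerQuantile), sel@r2PerQuantile[1])
})

test_that("planted regional scores are recovered through the full scoring path", {
  ph <- testPhantom()
  vAge <- makeAgingField(ph$template, ph$seg, ph$spec, rate = 0.05)
  subj <- makeSubject(ph$template, vAge, asTrue = 3, adsTrue = 0.4,
                      noiseSigma = 0, seed = 2, warpImage = FALSE)
  tab <- scoreScan(subj$svfTrue, vAge, segRef = ph$seg,
                   regions = c("ventricles", "hippocampi-amygdala"),
                   quantiles = 0)
  expect_equal(tab$AS, rep(3, 2), tolerance = 1e-3)
  expect_equal(tab$ADS, rep(0.4, 2), tolerance = 1e-3)
})
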