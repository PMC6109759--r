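test_that("model order estimation recovers planted structure", {
  set.seed(41)
  grid <- c(12L, 12L, 6L); V <- prod(grid); T <- 100L
  A <- matrix(rnorm(T * 3), T, 3)
  S <- matrix(0, 3, V)
  S[1, 1:80] <- rnorm(80) * 5
  S[2, 301:380] <- rnorm(80) * 5
  S[3, 601:680] <- rnorm(80) * 5
  Y <- t(A %*% S) + matrix(rnorm(V * T), V, T)   # SNR ~ 10 on sources
  s <- seriesFromMatrix(Y, grid)
  expect_equal(estimateModelOrder(s), 3L)
  # deterministic
  expect_equal(estimateModelOrder(s), estimateModelOrder(s))

  # pure isotropic noise: clamp floor
  noise <- seriesFromMatrix(matrix(rnorm(V * T), V, T), grid)
  expect_equal(estimateModelOrder(noise), 2L)
  expect_equal(estimateModelOrder(noise, method = "mp"), 2L)

  short <- seriesFromMatrix(matrix(rnorm(V * 10), V, 10), grid)
  expect_error(estimateModelOrder(short), "20 volumes")
})

test_that("noise-free planted sources are recovered almost perfectly", {
  p <- plantedTwoSource(noiseSd = 0, seed = 43)
  dec <- spatialICA(p$series, 2, seed = 3)
  for (m in p$maps) {
    match <- matchComponent(dec, m)
    expect_gt(match@spatialPcc, 0.99)
  }
  # time-courses recovered up to sign/scale
  m1 <- matchComponent(dec, p$maps[[1]])
  tc <- timecourses(dec)[, m1@componentIndex]
  expect_gt(abs(cor(tc, p$timecourses[[1]])), 0.99)
})

test_that("rank-1 data with one component returns the planted map", {
  grid <- c(10L, 10L, 4L)
  map <- array(0, grid); map[3:6, 3:6, 2:3] <- 1
  a <- sin(seq(0, 8 * pi, length.out = 60))
  Y <- outer(as.vector(map), a)
  dec <- spatialICA(seriesFromMatrix(Y, grid), 1, seed = 4)
  expect_equal(nComponents(dec), 1L)
  m <- matchComponent(dec, map)
  expect_gt(m@spatialPcc, 0.999)
})

test_that("decompositions reconstruct the PCA-reduced demeaned data", {
  p <- plantedTwoSource(noiseSd = 0.5, seed = 47)
  dec <- spatialICA(p$series, 2, seed = 5)
  Y <- seriesMatrix(p$series)
  Y <- Y - rowMeans(Y)
  C <- crossprod(Y) / nrow(Y)
  e <- eigen(C, symmetric = TRUE)
  U <- e$vectors[, 1:2]
  reduced <- t(U %*% crossprod(U, t(Y)))   # voxels x time rank-2 projection
  expect_lt(max(abs(reconstruct(dec) - t(reduced))) / max(abs(reduced)),
            1e-4)
  # maps are z-scored
  expect_equal(rowMeans(spatialMaps(dec)), c(0, 0), tolerance = 1e-10)
  expect_equal(apply(spatialMaps(dec), 1, sd), c(1, 1), tolerance = 1e-10)
  # explained variance fractions are sane
  expect_true(all(dec@explainedVariance >= 0))
  expect_lte(sum(dec@explainedVariance), 1)
})

test_that("spatial ICA is seeded and deterministic", {
  p <- plantedTwoSource(noiseSd = 0.5, seed = 53)
  d1 <- spatialICA(p$series, 2, seed = 9)
  d2 <- spatialICA(p$series, 2, seed = 9)
  expect_identical(spatialMaps(d1), spatialMaps(d2))
  expect_identical(timecourses(d1), timecourses(d2))
})

test_that("sign fixing flips map and time-course together", {
  p <- plantedTwoSource(noiseSd = 0, seed = 59)
  dec <- spatialICA(p$series, 2, seed = 7)
  i <- matchComponent(dec, p$maps[[1]])@componentIndex
  recon <- reconstruct(dec)

  flipped <- dec
  flipped@maps[i, ] <- -flipped@maps[i, ]
  flipped@mapMean[i] <- -flipped@mapMean[i]
  flipped@timecourses[, i] <- -flipped@timecourses[, i]

  fixed <- fixSign(flipped, i, p$maps[[1]])
  expect_equal(fixed@maps[i, ], dec@maps[i, ] *
                 sign(cor(dec@maps[i, ], p$maps[[1]][dec@mask])))
  expect_identical(reconstruct(fixed), recon)

  # already-positive correlation: unchanged
  pos <- fixSign(fixed, i, p$maps[[1]])
  expect_identical(pos@maps, fixed@maps)

  # zero correlation: tie broken toward +1 (unchanged)
  orth <- array(0, dim(dec@mask))
  zeroFix <- fixSign(dec, i, orth)
  expect_identical(zeroFix@maps, dec@maps)
})

test_that("component matching returns the argmax with ties to lower index", {
  p <- plantedTwoSource(noiseSd = 0, seed = 61)
  dec <- spatialICA(p$series, 2, seed = 8)
  m <- matchComponent(dec, p$maps[[1]], "visual")
  expect_gt(m@spatialPcc, 0.9)
  expect_gte(m@spatialPcc, 0)

  # a reference orthogonal to everything still returns an argmax
  set.seed(1)
  noiseRef <- array(rnorm(prod(dim(dec@mask))), dim(dec@mask))
  mN <- matchComponent(dec, noiseRef)
  expect_true(mN@componentIndex %in% c(1L, 2L))

  # degenerate duplicate components: lower index wins
  dup <- dec
  best <- dec@maps[m@componentIndex, ]
  dup@maps[1, ] <- best
  dup@maps[2, ] <- best
  expect_equal(matchComponent(dup, p$maps[[1]])@componentIndex, 1L)
})

test_that("cohort concatenation records boundaries and round-trips", {
  sc <- tinyScene()
  co <- generateCohort(2, sc, masterSeed = 67)
  cc <- concatenateCohort(list(co[[1]]$series, co[[2]]$series))
  expect_equal(nVolumes(cc), 320L)
  expect_identical(cc@boundaries, c(160L, 160L))

  # slicing then re-normalizing is the identity on normalized blocks
  s1 <- sliceSubject(cc, 1)
  expect_equal(fcEquiv:::.varianceNormalize(s1)@data, s1@data,
               tolerance = 1e-12)
  cc2 <- concatenateCohort(list(s1, sliceSubject(cc, 2)))
  expect_equal(cc2@data, cc@data, tolerance = 1e-12)

  # single subject: identity up to per-voxel variance normalization
  ccOne <- concatenateCohort(list(co[[1]]$series))
  vn <- fcEquiv:::.varianceNormalize(co[[1]]$series)
  expect_identical(ccOne@data[, , , ], vn@data)

  bad <- seriesFromMatrix(matrix(rnorm(32), 8), c(2L, 2L, 2L))
  expect_error(concatenateCohort(list(co[[1]]$series, bad)), "mismatch")
})

test_that("ICA errors are informative", {
  p <- plantedTwoSource(noiseSd = 0.5, seed = 71)
  expect_error(spatialICA(p$series, 500), "nComponents")
  emptyMask <- array(FALSE, dim(p$series@data)[1:3])
  expect_error(spatialICA(p$series, 2, mask = emptyMask), "empty")
  # forced non-convergence carries the restart/iteration information
  expect_error(spatialICA(p$series, 6, seed = 1, restarts = 2, maxIter = 1,
                          tol = 1e-12),
               "converge")
})
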