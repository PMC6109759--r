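test_that("Pearson correlation matches the hand-computed covariance oracle", {
  # hand oracle: a = (1,2,3,4), b = (2,1,4,3): cov = 1, sd_a = sd_b = sqrt(5/3)
  expect_equal(pcc(c(1, 2, 3, 4), c(2, 1, 4, 3)), 0.6, tolerance = 1e-12)
  expect_equal(pcc(1:10, 1:10), 1.0)
  # orthogonality over whole periods
  t <- seq(0, 2 * pi, length.out = 401)[-401]
  expect_lt(abs(pcc(sin(t), cos(t))), 1e-6)
  # symmetry and affine invariance
  set.seed(3)
  a <- rnorm(30); b <- rnorm(30)
  expect_equal(pcc(a, b), pcc(b, a))
  expect_equal(pcc(2.5 * a + 7, b), pcc(a, b), tolerance = 1e-12)
  # guards
  expect_error(pcc(rep(1, 10), rnorm(10)), "zero-variance")
  expect_error(pcc(1:4, 1:5), "equal length")
  expect_error(pcc(1:2, 2:1), "at least 3")
})

test_that("Dice overlap follows the set formula", {
  a <- array(0, c(4, 4, 1)); b <- array(0, c(4, 4, 1))
  a[1:4, 1, 1] <- 5          # |A| = 4
  b[1:2, 1, 1] <- 5          # overlap 2
  b[1:4, 2, 1] <- 5          # |B| = 6
  expect_equal(diceAtZ(a, b, 3), 0.4)
  expect_equal(diceAtZ(a, a, 3), 1.0)
  disjoint <- array(0, c(4, 4, 1)); disjoint[1:3, 4, 1] <- 5
  expect_equal(diceAtZ(a, disjoint, 3), 0.0)
  # symmetry
  expect_equal(diceAtZ(a, b, 3), diceAtZ(b, a, 3))
  # both supports empty: missing with a reason
  z <- array(0, c(4, 4, 1))
  d <- diceAtZ(z, z, 3)
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "empty")
  expect_error(diceAtZ(a, b, -1), "> 0")
  expect_error(diceAtZ(a, array(0, c(2, 2, 1))), "grid")
})

test_that("task correlation z statistic is calibrated and capped", {
  v <- generateEventSchedule(10, 6.2, c(4, 18), 1.2, c(0.5, 3.5), 100,
                             condition = "visual", seed = 73)
  X <- buildDesignMatrix(list(visual = v), 100, 1)
  x <- designValues(X)[, "visual"]

  # perfect fit: r = 1, capped z
  perfect <- taskCorrelation(x, X, "visual")
  expect_equal(perfect$r, 1)
  expect_equal(perfect$z, 40)

  # z matches the lm oracle on a noisy time-course
  set.seed(5)
  y <- 0.5 * x + rnorm(100)
  tc <- taskCorrelation(y, X, "visual")
  lmT <- summary(lm(y ~ x))$coefficients[2, 3]
  expect_equal(tc$z, qnorm(pt(lmT, 98)), tolerance = 1e-6)
  expect_equal(tc$r, cor(y, x), tolerance = 1e-12)

  # white-noise calibration: P(|z| > 1.96) = 0.05 +/- 0.01
  set.seed(7)
  zs <- replicate(4000, taskCorrelation(rnorm(100), X, "visual")$z)
  expect_lt(abs(mean(abs(zs) > 1.96) - 0.05), 0.01)

  expect_error(taskCorrelation(rnorm(100), X, "nope"), "not in the design")
  expect_error(taskCorrelation(rnorm(50), X, "visual"), "length")
})

test_that("self-comparison of a decomposition gives perfect similarity", {
  p <- plantedTwoSource(noiseSd = 0.5, seed = 79)
  dec <- spatialICA(p$series, 2, seed = 3)
  rec <- compareNetworks(dec, dec, p$maps[[1]], "visual")
  expect_equal(rec$temporalPcc, 1)
  expect_equal(rec$spatialPcc, 1)
  expect_equal(rec$dice, 1)
})

test_that("network comparison is invariant to component order and sign", {
  p <- plantedTwoSource(noiseSd = 0.5, seed = 83)
  dec <- spatialICA(p$series, 2, seed = 3)
  decB <- spatialICA(seriesFromMatrix(
    seriesMatrix(p$series) + 0, dim(p$series@data)[1:3]), 2, seed = 4)

  base <- compareNetworks(dec, decB, p$maps[[1]], "visual")

  # permute and negate the components of the first decomposition
  perm <- dec
  perm@maps <- dec@maps[2:1, ]
  perm@mapMean <- dec@mapMean[2:1]
  perm@mapScale <- dec@mapScale[2:1]
  perm@timecourses <- dec@timecourses[, 2:1]
  perm@explainedVariance <- dec@explainedVariance[2:1]
  perm@maps[1, ] <- -perm@maps[1, ]
  perm@mapMean[1] <- -perm@mapMean[1]
  perm@timecourses[, 1] <- -perm@timecourses[, 1]

  swapped <- compareNetworks(perm, decB, p$maps[[1]], "visual")
  expect_equal(swapped$temporalPcc, base$temporalPcc, tolerance = 1e-12)
  expect_equal(swapped$spatialPcc, base$spatialPcc, tolerance = 1e-12)
  expect_equal(swapped$dice, base$dice)
})

test_that("network comparison enforces grid and length agreement", {
  p <- plantedTwoSource(noiseSd = 0.5, seed = 89)
  dec <- spatialICA(p$series, 2, seed = 3)
  shorter <- seriesFromMatrix(seriesMatrix(p$series)[, 1:60],
                              dim(p$series@data)[1:3])
  decS <- spatialICA(shorter, 2, seed = 3)
  expect_error(compareNetworks(dec, decS, p$maps[[1]], "visual"), "length")
})
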