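test_that("OLS betas match lm and are exact on noise-free data", {
  grid <- c(3L, 3L, 2L)
  nVox <- prod(grid); nVol <- 80L
  v <- generateEventSchedule(10, 6.2, c(4, 18), 1.2, c(0.5, 3.5), 80,
                             condition = "visual", seed = 6)
  X <- buildDesignMatrix(list(visual = v), nVol, 1)
  Xv <- designValues(X)
  set.seed(9)
  trueBetas <- matrix(rnorm(nVox * 2), nVox, 2)  # visual + constant
  Y <- trueBetas %*% t(Xv)
  fit <- fitGlm(seriesFromMatrix(Y, grid), X)
  expect_equal(as.vector(fit@betas[, , , 1]), trueBetas[, 1],
               tolerance = 1e-8)
  expect_equal(as.vector(fit@betas[, , , 2]), trueBetas[, 2],
               tolerance = 1e-8)

  # noisy voxel: betas, t and z match an independent lm oracle
  y <- Y[1, ] + rnorm(nVol)
  fitN <- fitGlm(seriesFromMatrix(matrix(y, 1), c(1L, 1L, 1L)), X)
  lmFit <- summary(lm(y ~ Xv[, "visual"]))
  expect_equal(fitN@betas[1, 1, 1, 1], lmFit$coefficients[2, 1],
               tolerance = 1e-6)
  tOracle <- lmFit$coefficients[2, 3]
  zOracle <- qnorm(pt(tOracle, nVol - 2))
  expect_equal(fitN@zMaps[1, 1, 1, 1], zOracle, tolerance = 1e-6)
})

test_that("rank-deficient and mismatched designs error", {
  v <- eventSchedule("visual", 5, 1, scanDuration = 40)
  X <- buildDesignMatrix(list(visual = v, visual2 = v), 40, 1)
  s <- seriesFromMatrix(matrix(rnorm(40), 1), c(1L, 1L, 1L))
  expect_error(fitGlm(s, X), "rank")
  Xok <- buildDesignMatrix(list(visual = v), 40, 1)
  sBad <- seriesFromMatrix(matrix(rnorm(30), 1), c(1L, 1L, 1L))
  expect_error(fitGlm(sBad, Xok), "volumes")
})

test_that("residuals are orthogonal to every regressor and reconstruct the data", {
  sc <- tinyScene()
  sub <- generateCohort(2, sc, masterSeed = 8)[[1]]
  X <- buildDesignMatrix(sub$schedules, nVolumes(sub$series), 1)
  fit <- fitGlm(sub$series, X)
  R <- t(matrix(fit@residuals, ncol = nVolumes(sub$series)))  # time x voxels
  Xv <- designValues(X)
  rNorm <- sqrt(colSums(R^2))
  for (j in seq_len(ncol(Xv))) {
    cNorm <- sqrt(sum(Xv[, j]^2))
    expect_lt(max(abs(crossprod(Xv[, j], R)) / (rNorm * cNorm + 1e-300)),
              1e-6)
  }
  # design %*% beta + residual reproduces the input
  B <- t(matrix(fit@betas, ncol = ncol(Xv)))                  # p x voxels
  recon <- Xv %*% B + R
  Y <- t(seriesMatrix(sub$series))
  expect_lt(max(abs(recon - Y)) / max(abs(Y)), 1e-8)
})

test_that("residualization restores the mean, is idempotent, and kills task correlation", {
  sc <- tinyScene()
  sub <- generateCohort(2, sc, masterSeed = 11)[[1]]
  X <- buildDesignMatrix(sub$schedules, nVolumes(sub$series), 1)
  fit <- fitGlm(sub$series, X)
  res <- residualize(sub$series, fit)
  expect_identical(dim(res@data), dim(sub$series@data))
  # temporal means preserved
  expect_equal(rowMeans(seriesMatrix(res)), rowMeans(seriesMatrix(sub$series)),
               tolerance = 1e-8)

  # idempotence: second pass with the same design changes nothing
  fit2 <- fitGlm(res, X)
  res2 <- residualize(res, fit2)
  expect_lt(max(abs(res2@data - res@data)) / max(abs(res@data)), 1e-6)

  # post-residualization correlation with the task regressor ~ 0, everywhere
  x <- designValues(X)[, "visual"]
  cors <- cor(t(seriesMatrix(res)), x)
  expect_lt(max(abs(cors)), 1e-6)

  # shape mismatch guard
  other <- generateCohort(2, sc, masterSeed = 12)[[1]]
  short <- new("VolumeSeries",
               data = other$series@data[, , , 1:100, drop = FALSE],
               voxelSize = other$series@voxelSize, tr = 1)
  expect_error(residualize(short, fit), "shape")
})

test_that("task-free residualization leaves voxel series nearly unchanged", {
  sc <- defaultScene(visualCoupling = 0, dmnCoupling = 0)
  sub <- generateCohort(2, sc, masterSeed = 13)[[1]]
  X <- buildDesignMatrix(sub$schedules, nVolumes(sub$series), 1)
  fit <- fitGlm(sub$series, X)
  res <- residualize(sub$series, fit)
  Y <- seriesMatrix(sub$series); Yr <- seriesMatrix(res)
  cors <- vapply(seq_len(nrow(Y)), function(v) cor(Y[v, ], Yr[v, ]),
                 numeric(1))
  expect_gt(min(cors), 0.95)
})

test_that("group map flags consistent effects and handles degenerate variance", {
  grid <- c(5L, 5L, 2L)
  # identical nonzero betas across subjects: capped z
  b <- array(0, grid); b[2, 2, 1] <- 1; b[3, 3, 2] <- -2
  g <- groupMap(list(b, b, b, b))
  expect_equal(g[2, 2, 1], 40)
  expect_equal(g[3, 3, 2], -40)
  expect_equal(g[1, 1, 1], 0)

  # null calibration: i.i.d. N(0,1) betas, P(z > 3) ~ pnorm(-3)
  set.seed(21)
  nVox <- 20000L
  maps <- lapply(1:20, function(i) array(rnorm(nVox), c(100L, 200L, 1L)))
  gz <- groupMap(maps)
  expect_lt(abs(mean(gz > 3) - 0.0013), 0.002)

  expect_error(groupMap(list(b, b)), "3 subjects")
  expect_error(groupMap(list(b, b, array(0, c(2, 2, 2)))), "mismatch")
})
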