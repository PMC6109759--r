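test_that("network templates enforce their invariants", {
  grid <- c(8L, 8L, 4L)
  m <- fcEquiv:::.gaussianBlob(grid, c(4, 4, 2), 1.5)
  tpl <- networkTemplate("visual", spatialMap = m, taskCoupling = 1,
                         taskCondition = "visual", spontaneousAmplitude = 1)
  expect_equal(max(tpl@spatialMap), 1)
  expect_true(all(tpl@spatialMap >= 0))
  expect_error(networkTemplate("nope", spatialMap = m), "label")
  expect_error(networkTemplate("visual", spatialMap = m, taskCoupling = 1,
                               taskCondition = ""), "taskCondition")
})

test_that("noise-free drift-free synthesis reconstructs exactly from ground truth", {
  sc <- tinyScene()
  templates <- fcEquiv:::.sceneTemplates(sc)
  v <- generateEventSchedule(10, 6.2, c(4, 18), 1.2, c(0.5, 3.5), 160,
                             condition = "visual", seed = 31)
  out <- synthesizeSubject(templates, list(visual = v),
                           voxelSize = sc$voxelSize, tr = 1, nVolumes = 160L,
                           noiseSd = 0, driftAmplitude = 0, baseline = 100,
                           seed = 5)
  expect_identical(max(abs(out$series@data - reconstructTruth(out$truth))), 0)
})

test_that("noise-free in-support signal equals baseline + gain * map * regressor", {
  grid <- c(8L, 8L, 4L)
  map <- fcEquiv:::.gaussianBlob(grid, c(4, 4, 2), 1.5)
  tpl <- networkTemplate("visual", spatialMap = map, taskCoupling = 2,
                         taskCondition = "visual", spontaneousAmplitude = 0)
  v <- eventSchedule("visual", c(10, 30), c(2, 2), scanDuration = 80)
  out <- synthesizeSubject(list(tpl), list(visual = v), tr = 1,
                           nVolumes = 80L, noiseSd = 0, driftAmplitude = 0,
                           baseline = 50, seed = 1)
  x <- fcEquiv:::.convolvedRegressor(v, 80, 1)
  Y <- seriesMatrix(out$series)
  vox <- which(as.vector(map) > 0)[1]
  expect_equal(Y[vox, ], 50 + 2 * as.vector(map)[vox] * x, tolerance = 1e-12)

  # negative coupling: in-support voxels anticorrelate with the regressor
  tplNeg <- networkTemplate("dmn", spatialMap = map, taskCoupling = -0.6,
                            taskCondition = "visual",
                            spontaneousAmplitude = 0)
  outNeg <- synthesizeSubject(list(tplNeg), list(visual = v), tr = 1,
                              nVolumes = 80L, noiseSd = 0,
                              driftAmplitude = 0, baseline = 50, seed = 1)
  yNeg <- seriesMatrix(outNeg$series)[vox, ]
  expect_lt(cor(yNeg, x), -0.99)
})

test_that("spontaneous time-courses pass the task-decorrelation screen", {
  sc <- tinyScene()
  sub <- generateCohort(2, sc, masterSeed = 17)[[1]]
  X <- designValues(buildDesignMatrix(sub$schedules, 160, 1))
  X <- X[, setdiff(colnames(X), "constant")]
  for (j in seq_along(sub$truth@templates)) {
    s <- sub$truth@spontaneous[, j]
    if (sd(s) > 0)
      expect_lt(max(abs(cor(s, X))), 0.1)
  }
})

test_that("overlapping spontaneous templates are rejected", {
  grid <- c(8L, 8L, 4L)
  m1 <- fcEquiv:::.gaussianBlob(grid, c(4, 4, 2), 1.5)
  m2 <- fcEquiv:::.gaussianBlob(grid, c(5, 4, 2), 1.5)
  t1 <- networkTemplate("visual", "a", m1, spontaneousAmplitude = 1)
  t2 <- networkTemplate("dmn", "b", m2, spontaneousAmplitude = 1)
  v <- eventSchedule("visual", 10, 1, scanDuration = 60)
  expect_error(
    synthesizeSubject(list(t1, t2), list(visual = v), nVolumes = 60L,
                      seed = 1),
    "overlap")
})

test_that("cohorts are seeded, unique per subject, and reproducible", {
  sc <- tinyScene()
  co <- generateCohort(2, sc, masterSeed = 23)
  expect_false(identical(onsets(co[[1]]$schedules$visual),
                         onsets(co[[2]]$schedules$visual)))
  co2 <- generateCohort(2, sc, masterSeed = 23)
  expect_identical(co[[1]]$series@data, co2[[1]]$series@data)
  expect_identical(co[[2]]$truth@spontaneous, co2[[2]]$truth@spontaneous)
  expect_error(generateCohort(1, sc), ">= 2")
})

test_that("task regressors are nearly uncorrelated across subjects", {
  # full design statistics: 55 events over 360 s, as in the study
  regs <- vapply(1:10, function(i) {
    s <- generateEventSchedule(55, 6.2, c(4, 18), 1.2, c(0.5, 3.5), 360,
                               condition = "visual", seed = 29 + i)
    fcEquiv:::.convolvedRegressor(s, 360, 1)
  }, numeric(360))
  cm <- cor(regs)
  offDiag <- abs(cm[upper.tri(cm)])
  expect_equal(length(offDiag), 45)
  expect_lt(mean(offDiag), 0.2)
})
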