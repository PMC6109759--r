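# Small fixtures built in code. The tiny scene keeps unit tests fast; the
# acceptance tests use the full default scene.

tinyScene <- function(visualCoupling = 1.0, dmnCoupling = -0.6,
                      spontaneousAmplitude = 1.0, noiseSd = 0.5) {
  sc <- defaultScene(grid = c(12L, 12L, 6L),
                     visualCoupling = visualCoupling,
                     dmnCoupling = dmnCoupling,
                     spontaneousAmplitude = spontaneousAmplitude,
                     noiseSd = noiseSd)
  sc$nVolumes <- 160L
  sc$events <- list(nEvents = 20L, meanGap = 6.2, gapRange = c(4, 18),
                    meanDuration = 1.2, durationRange = c(0.5, 3.5))
  sc$templates[[1]]$center <- c(3.5, 6, 2.5)
  sc$templates[[1]]$sigma <- 1.3
  sc$templates[[2]]$center <- c(9, 8, 4.5)
  sc$templates[[2]]$sigma <- 1.3
  sc$templates[[3]]$center <- c(9, 5, 4)
  sc$templates[[3]]$sigma <- 1.3
  sc
}

# a VolumeSeries from a voxels x time matrix on a given grid
seriesFromMatrix <- function(Y, grid, voxelSize = c(3, 3, 5.5), tr = 1) {
  stopifnot(nrow(Y) == prod(grid))
  new("VolumeSeries", data = array(Y, c(grid, ncol(Y))),
      voxelSize = voxelSize, tr = tr)
}

# single-voxel series embedded in a minimal grid (per-voxel operations)
singleVoxelSeries <- function(y, tr = 1) {
  seriesFromMatrix(matrix(y, nrow = 1), grid = c(1L, 1L, 1L), tr = tr)
}

# planted two-source scene: disjoint spatial blobs with independent
# time-courses, optional noise; returns series plus ground-truth maps and
# time-courses
plantedTwoSource <- function(grid = c(12L, 12L, 6L), nVolumes = 120L,
                             noiseSd = 0, seed = 1) {
  withr::with_seed(seed, {
    m1 <- array(0, grid); m1[2:5, 2:5, 2:4] <- 1
    m2 <- array(0, grid); m2[8:11, 7:10, 3:5] <- 1
    a1 <- stats::rnorm(nVolumes)
    a2 <- stats::rnorm(nVolumes)
    Y <- outer(as.vector(m1), a1) + outer(as.vector(m2), a2)
    if (noiseSd > 0) Y <- Y + stats::rnorm(length(Y), sd = noiseSd)
    list(series = seriesFromMatrix(Y, grid),
         maps = list(m1, m2), timecourses = list(a1, a2))
  })
}
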