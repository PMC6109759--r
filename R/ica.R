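#' Temporally concatenated multi-subject series
#'
#' A [VolumeSeries-class] whose time axis stacks several subjects (each
#' variance-normalized per voxel before stacking), with the per-subject
#' volume counts recorded so subject blocks can be sliced back out.
#'
#' @slot boundaries integer vector of per-subject volume counts.
#' @seealso [concatenateCohort()], [sliceSubject()]
#' @export
setClass("ConcatenatedSeries", contains = "VolumeSeries",
         representation(boundaries = "integer"))

# per-voxel demean + unit variance (constant voxels are left at zero)
.varianceNormalize <- function(series) {
  d <- dim(series@data)
  Y <- seriesMatrix(series)
  mu <- rowMeans(Y)
  s <- sqrt(rowSums((Y - mu)^2) / (d[4] - 1))
  s[s == 0] <- 1
  out <- (Y - mu) / s
  dim(out) <- d
  new("VolumeSeries", data = out, voxelSize = series@voxelSize, tr = series@tr)
}

#' Temporally concatenate a cohort for group ICA
#'
#' Each subject's series is variance-normalized per voxel, then the series
#' are stacked along time. Subject boundaries are recorded.
#'
#' @param seriesList list of [VolumeSeries-class] on identical grids.
#' @return a [ConcatenatedSeries-class].
#' @export
concatenateCohort <- function(seriesList) {
  stopifnot(length(seriesList) >= 1)
  g <- gridDim(seriesList[[1]])
  for (s in seriesList)
    if (!identical(gridDim(s), g)) stop("grid mismatch between subjects")
  norm <- lapply(seriesList, .varianceNormalize)
  data <- array(0, c(g, sum(vapply(norm, nVolumes, 1L))))
  at <- 0L
  for (s in norm) {
    data[, , , at + seq_len(nVolumes(s))] <- s@data
    at <- at + nVolumes(s)
  }
  new("ConcatenatedSeries", data = data,
      voxelSize = seriesList[[1]]@voxelSize, tr = seriesList[[1]]@tr,
      boundaries = vapply(norm, nVolumes, 1L))
}

#' Extract one subject's block from a concatenated series
#'
#' @param concatenated a [ConcatenatedSeries-class].
#' @param index subject index.
#' @return the subject's (variance-normalized) [VolumeSeries-class].
#' @export
sliceSubject <- function(concatenated, index) {
  b <- concatenated@boundaries
  stopifnot(index >= 1, index <= length(b))
  off <- c(0L, cumsum(b))[index]
  new("VolumeSeries",
      data = concatenated@data[, , , off + seq_len(b[index]), drop = FALSE],
      voxelSize = concatenated@voxelSize, tr = concatenated@tr)
}

# Laplace-approximation log evidence (Minka) for every candidate PCA rank,
# evaluated on the eigenvalue spectrum of the voxel-sample covariance
# (nSamples voxels, d = n_features time points). The pairwise eigenvalue
# term is split into a within-retained part, accumulated incrementally over
# ranks, and a retained-vs-noise-floor part, vectorized per rank.
.laplaceEvidenceAll <- function(spectrum, ranks, nSamples) {
  d <- length(spectrum)
  eps <- 1e-15
  logN <- log(nSamples)
  spectrum <- pmax(spectrum, 0)
  cumLog <- cumsum(log(pmax(spectrum, eps)))
  cumSum <- cumsum(spectrum)
  total <- cumSum[d]
  i <- seq_len(d)
  cumPu <- cumsum(lgamma((d - i + 1) / 2) - ((d - i + 1) / 2) * log(pi))

  maxRank <- max(ranks)
  Aincr <- numeric(maxRank)   # within-retained pair term, A(k) - A(k-1)
  for (k in seq.int(2L, maxRank)) {
    ii <- seq_len(k - 1L)
    Aincr[k] <- sum(log(pmax((spectrum[ii] - spectrum[k]) *
                             (1 / spectrum[k] - 1 / spectrum[ii]), eps)) +
                    logN)
  }
  Acum <- cumsum(Aincr)

  # retained-vs-floor pair term needs sums of log(lambda_i - lambda_j) over
  # j > k for every retained i: precompute row cumulative sums of the
  # pairwise log-difference matrix (upper triangle)
  LD <- log(pmax(outer(spectrum, spectrum, `-`), eps))
  LD[lower.tri(LD, diag = TRUE)] <- 0
  RC <- t(apply(LD, 1, cumsum))          # RC[i, k] = sum_{i<j<=k} LD[i, j]
  rowTotCum <- cumsum(RC[, d])           # sum_{i<=k} of full-row sums
  diagCS <- diag(apply(RC, 2, cumsum))   # sum_{i<=k} RC[i, k]

  vapply(ranks, function(k) {
    if (spectrum[k] < eps) return(-Inf)
    v <- max(eps, (total - cumSum[k]) / (d - k))
    ii <- seq_len(k)
    B <- (rowTotCum[k] - diagCS[k]) +
      (d - k) * sum(log(pmax(1 / v - 1 / spectrum[ii], eps)) + logN)
    pu <- -k * log(2) + cumPu[k]
    pl <- -cumLog[k] * nSamples / 2
    pv <- -log(v) * nSamples * (d - k) / 2
    m <- d * k - k * (k + 1) / 2
    pp <- log(2 * pi) * (m + k) / 2
    pu + pl + pv + pp - (Acum[k] + B) / 2 - k * logN / 2
  }, numeric(1))
}

# Marchenko-Pastur quantiles (descending) and upper bulk edge for aspect
# ratio gamma = d / nEff, unit noise variance.
.mpQuantiles <- function(d, gamma) {
  a <- (1 - sqrt(gamma))^2
  b <- (1 + sqrt(gamma))^2
  x <- seq(a + 1e-9, b - 1e-9, length.out = 4000)
  dens <- sqrt(pmax((b - x) * (x - a), 0)) / (2 * pi * gamma * x)
  cdf <- cumsum(dens)
  cdf <- cdf / max(cdf)
  p <- (seq_len(d) - 0.5) / d
  list(q = rev(stats::approx(cdf, x, xout = p, rule = 2)$y), edge = b)
}

# Fit the noise bulk of an eigenspectrum with a Marchenko-Pastur law whose
# effective sample count (spatial smoothing correlates voxel samples) and
# noise variance are chosen to match the middle quantiles; count the
# eigenvalues above the fitted bulk edge.
.mpOrder <- function(lambda, nVoxels) {
  d <- length(lambda)
  fitIdx <- seq.int(floor(0.35 * d), floor(0.85 * d))
  best <- NULL
  bestErr <- Inf
  for (cfac in 2^seq(0, 5, by = 0.25)) {
    nEff <- nVoxels / cfac
    if (nEff <= d + 1) next
    m <- .mpQuantiles(d, d / nEff)
    s2 <- stats::median(lambda[fitIdx]) / stats::median(m$q[fitIdx])
    err <- mean((log(lambda[fitIdx]) - log(s2 * m$q[fitIdx]))^2)
    if (err < bestErr) {
      bestErr <- err
      best <- list(edge = s2 * m$edge)
    }
  }
  sum(lambda > best$edge)
}

#' Estimate the ICA model order from the PCA eigenspectrum
#'
#' `method = "laplace"` computes the Laplace approximation to the Bayesian
#' evidence of each PCA rank (Minka's criterion) on the eigenspectrum of the
#' voxel-demeaned data and returns the rank with maximal evidence. Its
#' isotropic-residual assumption holds for unfiltered data; spatial smoothing
#' (which correlates the voxel samples) and temporal filtering (which colors
#' the spectrum) inflate it badly. `method = "mp"` instead fits a
#' Marchenko-Pastur noise bulk — with an effective sample count absorbing the
#' smoothing-induced voxel correlation — to the middle of the spectrum and
#' counts the eigenvalues above the bulk edge; this is the variant the
#' pipeline uses on preprocessed data. Both are deterministic and clamped to
#' `[2, n_volumes - 5]`.
#'
#' @param series a [VolumeSeries-class] with at least 20 volumes.
#' @param mask optional 3D logical array of voxels to include (default: all).
#' @param method "laplace" or "mp" (see above).
#' @return integer estimated number of components.
#' @export
estimateModelOrder <- function(series, mask = NULL,
                               method = c("laplace", "mp")) {
  method <- match.arg(method)
  d <- dim(series@data)
  if (d[4] < 20) stop("at least 20 volumes required (got ", d[4], ")")
  Y <- seriesMatrix(series)
  if (!is.null(mask)) Y <- Y[.flatten3D(mask), , drop = FALSE]
  Y <- Y - rowMeans(Y)
  nSamples <- nrow(Y)
  C <- crossprod(Y) / nSamples
  lambda <- rev(sort(eigen(C, symmetric = TRUE, only.values = TRUE)$values))
  lambda <- pmax(lambda, 0)
  hi <- min(d[4] - 5L, nSamples - 1L)
  k <- if (method == "laplace") {
    ranks <- seq.int(2L, hi)
    ev <- .laplaceEvidenceAll(lambda, ranks, nSamples)
    ranks[which.max(ev)]
  } else {
    .mpOrder(lambda, nSamples)
  }
  min(max(k, 2L), hi)
}

# one deflation (one-unit) FastICA run on whitened spatial data Z (k x V),
# logcosh contrast with Gram-Schmidt decorrelation against earlier rows;
# returns the orthonormal unmixing matrix, the maximum per-component
# iteration count and a convergence flag. Deflation converges component by
# component, which keeps the noise-floor directions of low-order forced
# decompositions from stalling a joint update.
.fastICARun <- function(Z, maxIter, tol) {
  k <- nrow(Z); V <- ncol(Z)
  W <- matrix(0, k, k)
  worstIter <- 0L
  for (i in seq_len(k)) {
    converged <- FALSE
    # a stalled one-unit iteration (oscillation between nearby extrema of the
    # empirical contrast) is retried from a fresh random start; the iteration
    # budget is shared across retries
    budget <- maxIter
    while (budget > 0 && !converged) {
      w <- stats::rnorm(k)
      w <- w / sqrt(sum(w^2))
      damping <- 1
      for (iter in seq_len(min(budget, 200L))) {
        s <- drop(crossprod(w, Z))
        g <- tanh(s)
        wNew <- drop(Z %*% g / V) - mean(1 - g^2) * w
        if (damping < 1) wNew <- damping * wNew + (1 - damping) * w
        if (i > 1) {
          prev <- W[seq_len(i - 1), , drop = FALSE]
          wNew <- wNew - drop(crossprod(prev, prev %*% wNew))
        }
        wNew <- wNew / sqrt(sum(wNew^2))
        delta <- abs(abs(sum(wNew * w)) - 1)
        w <- wNew
        if (delta < tol) { converged <- TRUE; break }
        if (iter %% 50 == 0) damping <- damping / 2  # stabilize oscillations
      }
      budget <- budget - iter
      worstIter <- max(worstIter, maxIter - budget)
    }
    if (!converged)
      return(list(W = W, iterations = worstIter, converged = FALSE))
    W[i, ] <- w
  }
  list(W = W, iterations = worstIter, converged = TRUE)
}

.logcoshNegentropy <- function(S) {
  gaussRef <- 0.3745672  # E[log cosh(x)] for x ~ N(0,1)
  sum((rowMeans(log(cosh(S))) - gaussRef)^2)
}

#' Spatial ICA decomposition of a BOLD series
#'
#' Voxel time series are demeaned, the time dimension is PCA-reduced to
#' `nComponents`, and FastICA with the logcosh contrast (symmetric
#' decorrelation) unmixes the voxel dimension so that the rows of the spatial
#' map matrix are maximally non-Gaussian spatial sources; the corresponding
#' mixing columns are the component time-courses. Maps are z-scored;
#' components are ordered by descending explained variance. Several seeded
#' restarts are run and the one with the highest total negentropy is kept, to
#' stabilize the stochastic initialization.
#'
#' @param series a [VolumeSeries-class] (or [ConcatenatedSeries-class] from
#'   [concatenateCohort()]).
#' @param nComponents integer number of components (<= n_volumes), or "auto"
#'   to use [estimateModelOrder()].
#' @param mask optional 3D logical array (default: all voxels).
#' @param seed integer seed for the FastICA restarts.
#' @param restarts number of seeded restarts (default 5).
#' @param maxIter maximum FastICA iterations per restart (default 1000).
#' @param tol convergence tolerance on the unmixing update (default 1e-4).
#' @return an [ICADecomposition-class].
#' @seealso [matchComponent()], [fixSign()], [reconstruct()]
#' @export
spatialICA <- function(series, nComponents = "auto", mask = NULL, seed = 1L,
                       restarts = 5L, maxIter = 1000L, tol = 1e-4) {
  d <- dim(series@data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(identical(dim(mask), d[1:3]))
  if (sum(mask) == 0) stop("mask is empty")
  if (identical(nComponents, "auto"))
    nComponents <- estimateModelOrder(series, mask)
  k <- as.integer(nComponents)
  if (k < 1 || k > d[4])
    stop("'nComponents' must be in [1, n_volumes]")

  Y <- seriesMatrix(series)[.flatten3D(mask), , drop = FALSE]
  Y <- Y - rowMeans(Y)
  V <- nrow(Y)
  C <- crossprod(Y) / V                       # T x T
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values[seq_len(k)], .Machine$double.eps)
  U <- e$vectors[, seq_len(k), drop = FALSE]
  Z <- t(U / rep(sqrt(lambda), each = d[4])) %*% t(Y)   # k x V, white

  if (k == 1) {
    best <- list(W = matrix(1, 1, 1), iterations = 0L, converged = TRUE)
    bestSeed <- as.integer(seed)
  } else {
    best <- NULL; bestSeed <- NA_integer_; bestNeg <- -Inf
    failed <- integer(0)
    for (r in seq_len(restarts)) {
      rs <- .childSeed(seed, r)
      run <- .withSeed(rs, .fastICARun(Z, maxIter, tol))
      if (!run$converged) { failed <- c(failed, run$iterations); next }
      neg <- .logcoshNegentropy(run$W %*% Z)
      if (neg > bestNeg) { bestNeg <- neg; best <- run; bestSeed <- rs }
    }
    if (is.null(best))
      stop("FastICA did not converge in any of ", restarts,
           " restarts (", maxIter, " iterations each)")
  }

  S <- best$W %*% Z                                    # k x V sources
  A <- (U * rep(sqrt(lambda), each = d[4])) %*% t(best$W)  # T x k mixing

  # order by descending explained variance fraction
  totalVar <- sum(pmax(e$values, 0))
  compVar <- diag(best$W %*% (lambda * t(best$W)))     # W diag(lambda) W'
  ord <- order(compVar, decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  A <- A[, ord, drop = FALSE]
  compVar <- compVar[ord]

  mapMean <- rowMeans(S)
  mapScale <- sqrt(rowSums((S - mapMean)^2) / (ncol(S) - 1))
  maps <- (S - mapMean) / mapScale

  boundaries <- if (is(series, "ConcatenatedSeries")) series@boundaries
                else d[4]
  new("ICADecomposition",
      maps = maps, timecourses = A,
      mapScale = mapScale, mapMean = mapMean,
      explainedVariance = compVar / totalVar,
      mask = mask, voxelSize = series@voxelSize, tr = series@tr,
      boundaries = as.integer(boundaries),
      seed = as.integer(bestSeed), iterations = as.integer(best$iterations))
}

#' Fix the sign of one component against a reference map
#'
#' ICA components are determined only up to sign. If the component's spatial
#' correlation with the reference is negative, both the map and its
#' time-course are negated (their product, hence the reconstruction, is
#' unchanged). A zero correlation is left as is.
#'
#' @param decomposition an [ICADecomposition-class].
#' @param componentIndex component to fix.
#' @param referenceMap 3D reference map on the decomposition grid.
#' @return the (possibly sign-flipped) [ICADecomposition-class].
#' @export
fixSign <- function(decomposition, componentIndex, referenceMap) {
  i <- as.integer(componentIndex)
  stopifnot(i >= 1, i <= nComponents(decomposition))
  ref <- .flatten3D(referenceMap)[.flatten3D(decomposition@mask)]
  if (stats::sd(ref) == 0) return(decomposition)  # no direction to fix toward
  r <- stats::cor(decomposition@maps[i, ], ref)
  if (is.finite(r) && r < 0) {
    decomposition@maps[i, ] <- -decomposition@maps[i, ]
    decomposition@mapMean[i] <- -decomposition@mapMean[i]
    decomposition@timecourses[, i] <- -decomposition@timecourses[, i]
  }
  decomposition
}

#' Match a decomposition component to a reference network map
#'
#' Returns the component maximizing the absolute spatial Pearson correlation
#' with the reference (ties broken by lower index), together with the sign
#' flip that makes the correlation positive. A poor best match is still
#' returned; callers may threshold.
#'
#' @param decomposition an [ICADecomposition-class].
#' @param referenceMap 3D reference map on the decomposition grid.
#' @param label network label to record ("visual", "dmn", "other").
#' @return a [NetworkMatch-class].
#' @export
matchComponent <- function(decomposition, referenceMap, label = "other") {
  stopifnot(identical(dim(referenceMap), dim(decomposition@mask)))
  ref <- .flatten3D(referenceMap)[.flatten3D(decomposition@mask)]
  r <- as.vector(stats::cor(t(decomposition@maps), ref))
  r[!is.finite(r)] <- 0
  i <- which.max(abs(r))
  new("NetworkMatch",
      componentIndex = as.integer(i),
      sign = if (r[i] < 0) -1 else 1,
      spatialPcc = abs(r[i]),
      label = label)
}
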