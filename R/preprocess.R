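.filterCache <- new.env(parent = emptyenv())

# Gaussian-weighted running-line smoother matrix (T x T). Row t holds the
# linear-filter weights whose dot product with a series gives the local
# weighted-linear-fit value at t. Reproduces constants and straight lines
# exactly. Cached per (n, sigma): the pipeline reuses one matrix across a
# whole cohort.
.runningLineMatrix <- function(n, sigma) {
  key <- paste(n, sigma)
  if (!is.null(.filterCache[[key]])) return(.filterCache[[key]])
  .filterCache[[key]] <- .runningLineMatrixUncached(n, sigma)
  .filterCache[[key]]
}

.runningLineMatrixUncached <- function(n, sigma) {
  idx <- seq_len(n)
  L <- matrix(0, n, n)
  for (t in idx) {
    u <- idx - t
    w <- exp(-u^2 / (2 * sigma^2))
    s0 <- sum(w); s1 <- sum(w * u); s2 <- sum(w * u^2)
    L[t, ] <- w * (s2 - u * s1) / (s0 * s2 - s1^2)
  }
  L
}

# Cosine basis of slow drifts below `cutoff` Hz (DCT-II, excluding DC).
.dctBasis <- function(n, tr, cutoff) {
  kMax <- floor(2 * n * tr * cutoff)
  if (kMax < 1) return(NULL)
  t <- seq_len(n) - 0.5
  vapply(seq_len(kMax), function(k) cos(pi * k * t / n), numeric(n))
}

#' Temporal high-pass filter
#'
#' Removes slow trends from every voxel time series and re-adds the voxel's
#' original temporal mean. The default method subtracts a Gaussian-weighted
#' running-line trend with sigma (in volumes) of `1/(2 * cutoff * tr)`, the
#' FSL convention; the alternative `"dct"` method regresses out a discrete
#' cosine basis of all drift frequencies below the cutoff, which has a sharper
#' roll-off.
#'
#' @param series a [VolumeSeries-class].
#' @param cutoff high-pass cutoff frequency (Hz); must be positive and below
#'   the Nyquist frequency `1/(2 * tr)`. Default 0.01 Hz.
#' @param method "gaussian-line" (default) or "dct".
#' @return a filtered [VolumeSeries-class] with unchanged geometry.
#' @export
highpassFilter <- function(series, cutoff = 0.01,
                           method = c("gaussian-line", "dct")) {
  method <- match.arg(method)
  tr <- series@tr
  if (cutoff <= 0) stop("'cutoff' must be > 0")
  if (cutoff >= 1 / (2 * tr))
    stop("'cutoff' must be below the Nyquist frequency ", 1 / (2 * tr), " Hz")
  d <- dim(series@data)
  Y <- seriesMatrix(series)                       # voxels x time
  mu <- rowMeans(Y)
  if (method == "gaussian-line") {
    sigma <- 1 / (2 * cutoff * tr)
    L <- .runningLineMatrix(d[4], sigma)
    out <- Y - tcrossprod(Y, L) + mu
  } else {
    B <- .dctBasis(d[4], tr, cutoff)
    if (is.null(B)) {
      out <- Y
    } else {
      B <- scale(B, center = TRUE, scale = FALSE)
      coef <- Y %*% B %*% solve(crossprod(B))
      out <- Y - tcrossprod(coef, B) - rowMeans(Y - tcrossprod(coef, B)) + mu
    }
  }
  dim(out) <- d
  new("VolumeSeries", data = out, voxelSize = series@voxelSize, tr = tr)
}

# 1D Gaussian convolution matrix with rows renormalized at the borders, so
# constants are preserved and no signal leaks out of the volume.
.gaussKernelMatrix <- function(n, sigmaVox) {
  if (sigmaVox <= 0) return(diag(n))
  idx <- seq_len(n)
  K <- exp(-outer(idx, idx, `-`)^2 / (2 * sigmaVox^2))
  K / rowSums(K)
}

#' 3D spatial Gaussian smoothing
#'
#' Convolves each volume with a separable 3D Gaussian of the requested full
#' width at half maximum. The per-axis sigma in voxels is
#' `fwhm / (2 sqrt(2 ln 2)) / voxelSize`. Kernel rows are renormalized at the
#' volume borders (mass-conserving: a constant volume stays constant).
#' `fwhm = 0` is the identity.
#'
#' @param series a [VolumeSeries-class].
#' @param fwhm full width at half maximum in mm (>= 0). Default 5.
#' @return a smoothed [VolumeSeries-class].
#' @export
smoothSpatial <- function(series, fwhm = 5) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(series)
  d <- dim(series@data)
  sigmaMm <- fwhm / (2 * sqrt(2 * log(2)))
  a <- series@data
  for (axis in 1:3) {
    K <- .gaussKernelMatrix(d[axis], sigmaMm / series@voxelSize[axis])
    perm <- c(axis, setdiff(1:4, axis))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    dim(ap) <- c(dp[1], prod(dp[-1]))
    ap <- K %*% ap
    dim(ap) <- dp
    a <- aperm(ap, order(perm))
  }
  new("VolumeSeries", data = a, voxelSize = series@voxelSize, tr = series@tr)
}

#' Global intensity normalization
#'
#' Scales the whole 4D dataset so its global median equals `targetMedian`
#' (default 1e4). The median is computed over all voxels and volumes, or over
#' `mask` voxels if one is supplied (synthetic volumes have no anatomical
#' background to exclude by default).
#'
#' @param series a [VolumeSeries-class].
#' @param targetMedian target global median (signal units).
#' @param mask optional 3D logical array restricting the median computation.
#' @return a rescaled [VolumeSeries-class].
#' @export
intensityNormalize <- function(series, targetMedian = 1e4, mask = NULL) {
  vals <- if (is.null(mask)) series@data else {
    stopifnot(identical(dim(mask), dim(series@data)[1:3]))
    seriesMatrix(series)[.flatten3D(mask), ]
  }
  med <- stats::median(vals)
  if (!is.finite(med) || med <= 0)
    stop("global median must be positive for intensity normalization (got ",
         med, ")")
  new("VolumeSeries", data = series@data * (targetMedian / med),
      voxelSize = series@voxelSize, tr = series@tr)
}

#' Standard preprocessing pipeline
#'
#' Applies, in fixed order: temporal high-pass filtering, 3D spatial
#' smoothing, global intensity normalization. Each stage can be skipped.
#'
#' @param series a [VolumeSeries-class].
#' @param highpassHz high-pass cutoff (Hz), see [highpassFilter()].
#' @param fwhmMm smoothing FWHM (mm), see [smoothSpatial()].
#' @param targetMedian target global median, see [intensityNormalize()].
#' @param skipHighpass,skipSmooth,skipNormalize logical stage switches.
#' @param highpassMethod filter implementation, see [highpassFilter()].
#' @return the preprocessed [VolumeSeries-class].
#' @export
preprocessSeries <- function(series, highpassHz = 0.01, fwhmMm = 5,
                             targetMedian = 1e4,
                             skipHighpass = FALSE, skipSmooth = FALSE,
                             skipNormalize = FALSE,
                             highpassMethod = "gaussian-line") {
  if (!skipHighpass) series <- highpassFilter(series, highpassHz,
                                              method = highpassMethod)
  if (!skipSmooth) series <- smoothSpatial(series, fwhmMm)
  if (!skipNormalize) series <- intensityNormalize(series, targetMedian)
  series
}
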