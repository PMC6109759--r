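#' Voxelwise first-level GLM fit
#'
#' Ordinary least squares of every voxel time series on the design matrix.
#' For each regressor, t = beta / SE(beta) with `n_volumes - n_regressors`
#' degrees of freedom is converted to a z statistic through the t CDF
#' (capped at +/- 40). Residuals and the per-voxel temporal mean are stored
#' for residualization.
#'
#' @param series a [VolumeSeries-class].
#' @param design a [DesignMatrix-class] with as many rows as the series has
#'   volumes; must be full column rank.
#' @return a [GLMResult-class].
#' @seealso [residualize()], [groupMap()]
#' @export
fitGlm <- function(series, design) {
  X <- design@values
  d <- dim(series@data)
  if (nrow(X) != d[4])
    stop("design has ", nrow(X), " rows but the series has ", d[4], " volumes")
  p <- ncol(X)
  qrX <- qr(X)
  if (qrX$rank < p) stop("design matrix is rank-deficient")
  Y <- t(seriesMatrix(series))                 # time x voxels
  beta <- qr.coef(qrX, Y)                      # p x voxels
  resid <- Y - X %*% beta
  df <- d[4] - p
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  se <- sqrt(outer(diag(XtXinv), sigma2))      # p x voxels
  tstat <- beta / se
  tstat[!is.finite(tstat)] <- 0
  z <- .tToZ(tstat, df)
  degen <- se == 0 & beta != 0        # perfect fits: cap instead of Inf
  z[degen] <- sign(beta[degen]) * 40

  nVox <- prod(d[1:3])
  betas <- array(t(beta), c(d[1:3], p))
  zMaps <- array(t(z), c(d[1:3], p))
  residuals <- array(t(resid), d)
  temporalMean <- array(rowMeans(seriesMatrix(series)), d[1:3])
  new("GLMResult",
      betas = betas, zMaps = zMaps, residuals = residuals,
      temporalMean = temporalMean, design = design,
      voxelSize = series@voxelSize, tr = series@tr)
}

#' Residualize a series with respect to a fitted GLM
#'
#' Returns `residual(v, t) + temporalMean(v)`: the series with all modeled
#' task variance removed and the mean volume restored. Geometry and TR are
#' preserved. Residualizing a second time with the same design changes
#' nothing (OLS residuals are already orthogonal to the design).
#'
#' @param series the [VolumeSeries-class] the GLM was fit on (shape checked).
#' @param glm the matching [GLMResult-class].
#' @return the residualized [VolumeSeries-class].
#' @export
residualize <- function(series, glm) {
  d <- dim(series@data)
  if (!identical(d, dim(glm@residuals)))
    stop("series shape does not match the GLM fit")
  out <- glm@residuals + as.vector(glm@temporalMean)  # mean recycled over t
  new("VolumeSeries", data = out, voxelSize = series@voxelSize,
      tr = series@tr)
}

#' Group-level z map from subject coefficient maps
#'
#' Voxelwise one-sample t test across subjects (t = mean / (sd / sqrt(n)),
#' dof = n - 1), converted to z through the t CDF and capped at +/- 40
#' (zero-variance voxels with a nonzero mean hit the cap).
#'
#' @param betaMaps list of >= 3 subject 3D coefficient maps on one grid.
#' @return 3D z map.
#' @export
groupMap <- function(betaMaps) {
  n <- length(betaMaps)
  if (n < 3) stop("at least 3 subjects required")
  d <- dim(betaMaps[[1]])
  for (b in betaMaps) if (!identical(dim(b), d)) stop("grid mismatch")
  B <- vapply(betaMaps, .flatten3D, numeric(prod(d)))   # voxels x subjects
  m <- rowMeans(B)
  s <- sqrt(rowSums((B - m)^2) / (n - 1))
  t <- numeric(length(m))
  ok <- s > 0
  t[ok] <- m[ok] / (s[ok] / sqrt(n))
  z <- .tToZ(t, n - 1)
  degen <- !ok & m != 0
  z[degen] <- sign(m[degen]) * 40
  array(z, d)
}
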