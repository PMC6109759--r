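#' Pearson correlation coefficient
#'
#' Standard product-moment correlation, the similarity metric used for both
#' time-courses and spatial maps. Errors on zero-variance input rather than
#' returning NA.
#'
#' @param a,b numeric vectors of equal length >= 3, each with nonzero
#'   variance.
#' @return correlation in \[-1, 1\].
#' @export
pcc <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 3) stop("at least 3 observations required")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero-variance input to Pearson correlation")
  stats::cor(a, b)
}

#' Dice overlap of thresholded z maps
#'
#' Binarizes each map at `value >= zThreshold` (the positive tail; matched
#' components are sign-fixed positive toward their reference) and returns
#' `2 |A intersect B| / (|A| + |B|)`. If both supports are empty the overlap
#' is undefined: `NA` is returned with the reason in the "reason" attribute.
#'
#' @param mapA,mapB z maps (3D arrays or vectors) on the same grid.
#' @param zThreshold positive threshold, default 3.
#' @return overlap in \[0, 1\], or `NA` with a "reason" attribute.
#' @export
diceAtZ <- function(mapA, mapB, zThreshold = 3) {
  if (!identical(dim(mapA), dim(mapB)) || length(mapA) != length(mapB))
    stop("maps must share a grid")
  if (zThreshold <= 0) stop("'zThreshold' must be > 0")
  a <- mapA >= zThreshold
  b <- mapB >= zThreshold
  if (sum(a) + sum(b) == 0)
    return(structure(NA_real_, reason = "both thresholded supports empty"))
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Correlation and z statistic of a time-course against a task regressor
#'
#' `r` is the Pearson correlation with the named design column; the z
#' statistic comes from the OLS regression of the time-course on that column
#' (with intercept), t converted to z with `n - 2` degrees of freedom and
#' capped at +/- 40.
#'
#' @param timecourse numeric vector, one value per volume.
#' @param design a [DesignMatrix-class] with matching row count.
#' @param condition name of the design column to test against.
#' @return list with elements `r` and `z`.
#' @export
taskCorrelation <- function(timecourse, design, condition) {
  X <- design@values
  if (!condition %in% colnames(X))
    stop("condition '", condition, "' not in the design")
  x <- X[, condition]
  n <- length(timecourse)
  if (n != length(x)) stop("time-course length does not match the design")
  r <- pcc(timecourse, x)
  if (abs(r) >= 1 - 1e-12) {
    z <- sign(r) * 40
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    z <- .tToZ(t, n - 2)
  }
  list(r = r, z = as.numeric(z))
}

# component z map embedded back into the 3D grid (NA outside the mask)
.componentMap3D <- function(decomposition, index) {
  out <- array(NA_real_, dim(decomposition@mask))
  out[decomposition@mask] <- decomposition@maps[index, ]
  out
}

#' Compare one network between two decompositions of the same subject
#'
#' The labeled network is identified independently in each decomposition by
#' [matchComponent()] against the reference map and sign-fixed toward it;
#' the record then holds the temporal Pearson correlation of the two matched
#' time-courses, the spatial Pearson correlation of the two matched z maps
#' (over all in-mask voxels, unthresholded), and their Dice overlap at the z
#' threshold. The result is invariant to component order and sign in both
#' decompositions.
#'
#' @param original decomposition of the original data.
#' @param residualized decomposition of the residualized data (same subject,
#'   same grid; equal time-course lengths are required).
#' @param referenceMap 3D reference map identifying the network.
#' @param label network label ("visual" or "dmn").
#' @param zThreshold Dice threshold on the z-scored maps, default 3.
#' @param subjectId subject identifier stored in the record.
#' @param condition "observed" or "null".
#' @param permutationIndex permutation round for null records (NA otherwise).
#' @return one-row data.frame: subject, network, condition, permutation,
#'   temporalPcc, spatialPcc, dice, diceReason, componentOriginal,
#'   componentResidualized.
#' @export
compareNetworks <- function(original, residualized, referenceMap, label,
                            zThreshold = 3, subjectId = "s1",
                            condition = "observed",
                            permutationIndex = NA_integer_) {
  if (!identical(dim(original@mask), dim(residualized@mask)))
    stop("decompositions are on different grids")
  if (nVolumes(original) != nVolumes(residualized))
    stop("time-course lengths differ (group vs subject decompositions?)")
  mo <- matchComponent(original, referenceMap, label)
  mr <- matchComponent(residualized, referenceMap, label)
  original <- fixSign(original, mo@componentIndex, referenceMap)
  residualized <- fixSign(residualized, mr@componentIndex, referenceMap)

  tPcc <- pcc(original@timecourses[, mo@componentIndex],
              residualized@timecourses[, mr@componentIndex])
  commonMask <- original@mask & residualized@mask
  a <- .componentMap3D(original, mo@componentIndex)[commonMask]
  b <- .componentMap3D(residualized, mr@componentIndex)[commonMask]
  sPcc <- pcc(a, b)
  dice <- diceAtZ(a, b, zThreshold)
  data.frame(
    subject = subjectId, network = label, condition = condition,
    permutation = permutationIndex,
    temporalPcc = tPcc, spatialPcc = sPcc, dice = as.numeric(dice),
    diceReason = if (is.na(dice)) attr(dice, "reason") else "",
    componentOriginal = mo@componentIndex,
    componentResidualized = mr@componentIndex,
    stringsAsFactors = FALSE
  )
}
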