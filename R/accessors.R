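#' @describeIn nVolumes time extent of the 4D data array.
#' @export
setMethod("nVolumes", "VolumeSeries", function(x) dim(x@data)[4L])

#' @describeIn nVolumes rows of the time-course matrix.
#' @export
setMethod("nVolumes", "ICADecomposition", function(x) nrow(x@timecourses))

#' @describeIn nVolumes rows of the design matrix.
#' @export
setMethod("nVolumes", "DesignMatrix", function(x) nrow(x@values))

#' @describeIn gridDim spatial extents of the 4D data array.
#' @export
setMethod("gridDim", "VolumeSeries", function(x) dim(x@data)[1:3])

#' @describeIn gridDim spatial extents of the mask.
#' @export
setMethod("gridDim", "ICADecomposition", function(x) dim(x@mask))

#' @describeIn gridDim spatial extents of the beta maps.
#' @export
setMethod("gridDim", "GLMResult", function(x) dim(x@temporalMean))

#' @describeIn repetitionTime TR of the series.
#' @export
setMethod("repetitionTime", "VolumeSeries", function(x) x@tr)

#' @describeIn repetitionTime TR of the design rows.
#' @export
setMethod("repetitionTime", "DesignMatrix", function(x) x@tr)

#' @describeIn nEvents event count.
#' @export
setMethod("nEvents", "EventSchedule", function(x) length(x@onsets))

#' @describeIn onsets onsets in seconds.
#' @export
setMethod("onsets", "EventSchedule", function(x) x@onsets)

#' @describeIn durations durations in seconds.
#' @export
setMethod("durations", "EventSchedule", function(x) x@durations)

#' @describeIn seriesMatrix flatten the 4D array to voxels x time.
#' @export
setMethod("seriesMatrix", "VolumeSeries", function(x) {
  d <- dim(x@data)
  dim(x@data) <- c(prod(d[1:3]), d[4L])
  x@data
})

#' @describeIn nComponents component count.
#' @export
setMethod("nComponents", "ICADecomposition", function(x) nrow(x@maps))

#' @describeIn spatialMaps z-scored maps.
#' @export
setMethod("spatialMaps", "ICADecomposition", function(x) x@maps)

#' @describeIn timecourses mixing matrix.
#' @export
setMethod("timecourses", "ICADecomposition", function(x) x@timecourses)

#' @describeIn reconstruct rank-k reconstruction of the demeaned data.
#' @export
setMethod("reconstruct", "ICADecomposition", function(x) {
  raw <- x@maps * x@mapScale + x@mapMean  # row-wise recycling of k-vectors
  x@timecourses %*% raw
})

#' @describeIn designValues the regressor matrix itself.
#' @export
setMethod("designValues", "DesignMatrix", function(x) x@values)

#' @describeIn designValues the design used in the fit.
#' @export
setMethod("designValues", "GLMResult", function(x) x@design@values)

.regressorIndex <- function(x, regressor) {
  nm <- colnames(x@design@values)
  if (is.character(regressor)) {
    i <- match(regressor, nm)
    if (is.na(i)) stop("unknown regressor '", regressor, "'")
    i
  } else as.integer(regressor)
}

#' @describeIn zMap extract one regressor's z map.
#' @export
setMethod("zMap", "GLMResult", function(x, regressor) {
  i <- .regressorIndex(x, regressor)
  x@zMaps[, , , i, drop = TRUE]
})

#' @describeIn betaMap extract one regressor's coefficient map.
#' @export
setMethod("betaMap", "GLMResult", function(x, regressor) {
  i <- .regressorIndex(x, regressor)
  x@betas[, , , i, drop = TRUE]
})

setMethod("show", "EventSchedule", function(object) {
  cat(sprintf(
    "EventSchedule '%s': %d events over %.1f s (mean spacing %.2f s)\n",
    object@condition, nEvents(object), object@scanDuration,
    if (nEvents(object) > 1) mean(diff(object@onsets)) else NA_real_
  ))
})

setMethod("show", "VolumeSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "VolumeSeries: %d x %d x %d voxels (%.1f x %.1f x %.1f mm), %d volumes, TR %.2f s\n",
    d[1], d[2], d[3], object@voxelSize[1], object@voxelSize[2],
    object@voxelSize[3], d[4], object@tr
  ))
})

setMethod("show", "DesignMatrix", function(object) {
  cat(sprintf(
    "DesignMatrix: %d volumes x %d regressors (%s), TR %.2f s\n",
    nrow(object@values), ncol(object@values),
    paste(colnames(object@values), collapse = ", "), object@tr
  ))
})

setMethod("show", "GLMResult", function(object) {
  d <- gridDim(object)
  cat(sprintf(
    "GLMResult: %d x %d x %d grid, %d volumes, regressors: %s\n",
    d[1], d[2], d[3], dim(object@residuals)[4],
    paste(colnames(object@design@values), collapse = ", ")
  ))
})

setMethod("show", "ICADecomposition", function(object) {
  cat(sprintf(
    "ICADecomposition: %d components, %d volumes, %d in-mask voxels (%.1f%% variance explained)\n",
    nComponents(object), nVolumes(object), ncol(object@maps),
    100 * sum(object@explainedVariance)
  ))
  if (length(object@boundaries) > 1)
    cat(sprintf("  concatenated: %d subjects\n", length(object@boundaries)))
})

setMethod("show", "NetworkMatch", function(object) {
  cat(sprintf(
    "NetworkMatch '%s': component %d (sign %+d), spatial Pcc = %.3f\n",
    object@label, object@componentIndex, as.integer(object@sign),
    object@spatialPcc
  ))
})

setMethod("show", "NullDistribution", function(object) {
  cat(sprintf(
    "NullDistribution: %d rounds x %d subjects, %d records\n",
    object@nRounds, ncol(object@permutationMap), nrow(object@records)
  ))
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(
    "StudyConfig: %d subjects, seed %d, ICA components: %s, %d null round(s), alpha %.3f\n",
    object@nSubjects, object@seed, as.character(object@ica$nComponents),
    object@equivalence$nRounds, object@equivalence$alpha
  ))
})
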