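#' Number of volumes (time points) of an object
#' @param x object with a time dimension.
#' @return integer count of volumes.
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))

#' Spatial grid dimensions of an object
#' @param x object with a voxel grid.
#' @return integer vector (nx, ny, nz).
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' Repetition time (s)
#' @param x object sampled at a TR.
#' @return numeric scalar, seconds.
#' @export
setGeneric("repetitionTime", function(x) standardGeneric("repetitionTime"))

#' Number of events in a schedule
#' @param x an [EventSchedule-class].
#' @return integer event count.
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' Event onsets (s)
#' @param x an [EventSchedule-class].
#' @return numeric vector of onsets.
#' @export
setGeneric("onsets", function(x) standardGeneric("onsets"))

#' Event durations (s)
#' @param x an [EventSchedule-class].
#' @return numeric vector of durations.
#' @export
setGeneric("durations", function(x) standardGeneric("durations"))

#' Voxels-by-time matrix view of a series
#' @param x a [VolumeSeries-class].
#' @return numeric matrix, n_voxels x n_volumes.
#' @export
setGeneric("seriesMatrix", function(x) standardGeneric("seriesMatrix"))

#' Number of components of a decomposition
#' @param x an [ICADecomposition-class].
#' @return integer component count.
#' @export
setGeneric("nComponents", function(x) standardGeneric("nComponents"))

#' Component spatial maps
#' @param x an [ICADecomposition-class].
#' @return k x n_inmask_voxels matrix of z-scored spatial maps.
#' @export
setGeneric("spatialMaps", function(x) standardGeneric("spatialMaps"))

#' Component time-courses
#' @param x an [ICADecomposition-class].
#' @return n_volumes x k mixing matrix.
#' @export
setGeneric("timecourses", function(x) standardGeneric("timecourses"))

#' Reconstruct the PCA-reduced data from a decomposition
#'
#' Returns `timecourses %*% rawMaps` where the raw source maps undo the
#' z-scoring; this equals the rank-k PCA reduction of the voxel-demeaned input.
#'
#' @param x an [ICADecomposition-class].
#' @return n_volumes x n_inmask_voxels matrix.
#' @export
setGeneric("reconstruct", function(x) standardGeneric("reconstruct"))

#' Design matrix values
#' @param x a [DesignMatrix-class] or [GLMResult-class].
#' @return numeric matrix of regressor values.
#' @export
setGeneric("designValues", function(x) standardGeneric("designValues"))

#' Per-regressor z-statistic map
#' @param x a [GLMResult-class].
#' @param regressor regressor name or index.
#' @return 3D z map.
#' @export
setGeneric("zMap", function(x, regressor) standardGeneric("zMap"))

#' Per-regressor beta map
#' @param x a [GLMResult-class].
#' @param regressor regressor name or index.
#' @return 3D coefficient map.
#' @export
setGeneric("betaMap", function(x, regressor) standardGeneric("betaMap"))
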