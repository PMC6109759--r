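#' @import methods
NULL

#' Stimulus event schedule for one condition
#'
#' Holds the onsets, durations and amplitudes of one condition's events for a
#' single subject, together with the scan duration they must fit into.
#' Times are in seconds.
#'
#' @slot condition single condition label (e.g. "visual", "audio", "motor").
#' @slot onsets numeric vector of event onsets (s), strictly increasing.
#' @slot durations numeric vector of event durations (s), all positive.
#' @slot amplitudes numeric vector of event amplitudes (unitless, default 1).
#' @slot scanDuration scalar scan duration (s); every event must end before it.
#'
#' @seealso [generateEventSchedule()], [deriveMotorSchedule()], [readEvents()]
#' @export
setClass("EventSchedule",
  representation(
    condition = "character",
    onsets = "numeric",
    durations = "numeric",
    amplitudes = "numeric",
    scanDuration = "numeric"
  )
)

setValidity("EventSchedule", function(object) {
  msg <- character()
  n <- length(object@onsets)
  if (length(object@condition) != 1L || !nzchar(object@condition))
    msg <- c(msg, "'condition' must be a single non-empty label")
  if (length(object@durations) != n || length(object@amplitudes) != n)
    msg <- c(msg, "onsets, durations and amplitudes must have equal length")
  if (length(object@scanDuration) != 1L || !is.finite(object@scanDuration) ||
      object@scanDuration <= 0)
    msg <- c(msg, "'scanDuration' must be a single positive number")
  if (n > 0) {
    if (any(!is.finite(object@onsets)) || any(object@onsets < 0))
      msg <- c(msg, "onsets must be finite and >= 0")
    if (n > 1 && any(diff(object@onsets) <= 0))
      msg <- c(msg, "onsets must be strictly increasing")
    if (any(!is.finite(object@durations)) || any(object@durations <= 0))
      msg <- c(msg, "durations must be finite and > 0")
    if (length(msg) == 0 &&
        any(object@onsets + object@durations > object@scanDuration + 1e-9))
      msg <- c(msg, "every event must satisfy onset + duration <= scanDuration")
  }
  if (length(msg)) msg else TRUE
})

#' Ground-truth network template for synthesis
#'
#' A spatial weight map plus the signals attached to it: a signed task
#' coupling (positive BOLD > 0, negative BOLD < 0, uncoupled = 0) applied to
#' the HRF-convolved boxcar of `taskCondition`, and an independent spontaneous
#' fluctuation (low-pass-filtered Gaussian noise) scaled by
#' `spontaneousAmplitude`.
#'
#' @slot label one of "visual", "dmn", "other"; used for template matching.
#' @slot name unique template identifier within a scene.
#' @slot spatialMap 3D nonnegative weight array, max value 1.
#' @slot taskCoupling signed unitless gain on the convolved task regressor.
#' @slot taskCondition condition name the template couples to ("" if uncoupled).
#' @slot spontaneousAmplitude signal-unit SD of the spontaneous fluctuation.
#' @slot spontaneousCutoff low-pass corner frequency (Hz) of the fluctuation.
#' @slot hrf HRF name used for this template's task response ("double-gamma"
#'   or "boynton"); an override hook for modeling non-canonical responses.
#'
#' @export
setClass("NetworkTemplate",
  representation(
    label = "character",
    name = "character",
    spatialMap = "array",
    taskCoupling = "numeric",
    taskCondition = "character",
    spontaneousAmplitude = "numeric",
    spontaneousCutoff = "numeric",
    hrf = "character"
  )
)

setValidity("NetworkTemplate", function(object) {
  msg <- character()
  if (!object@label %in% c("visual", "dmn", "other"))
    msg <- c(msg, "'label' must be one of 'visual', 'dmn', 'other'")
  if (length(dim(object@spatialMap)) != 3L)
    msg <- c(msg, "'spatialMap' must be a 3D array")
  else {
    if (any(!is.finite(object@spatialMap)) || any(object@spatialMap < 0))
      msg <- c(msg, "'spatialMap' must be finite and nonnegative")
    else if (abs(max(object@spatialMap) - 1) > 1e-8)
      msg <- c(msg, "'spatialMap' must be normalized to max 1")
  }
  if (abs(object@taskCoupling) > 0 && !nzchar(object@taskCondition))
    msg <- c(msg, "a task-coupled template must name its 'taskCondition'")
  if (object@spontaneousAmplitude < 0)
    msg <- c(msg, "'spontaneousAmplitude' must be >= 0")
  if (object@spontaneousCutoff <= 0)
    msg <- c(msg, "'spontaneousCutoff' must be > 0")
  if (length(msg)) msg else TRUE
})

#' A 4D BOLD series with voxel geometry and repetition time
#'
#' @slot data 4D numeric array (x, y, z, t), all finite.
#' @slot voxelSize voxel edge lengths in mm, length 3.
#' @slot tr repetition time in seconds.
#'
#' @seealso [synthesizeSubject()], [readVolumeSeries()], [nVolumes()]
#' @export
setClass("VolumeSeries",
  representation(
    data = "array",
    voxelSize = "numeric",
    tr = "numeric"
  )
)

setValidity("VolumeSeries", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "'data' must be a 4D array (x, y, z, t)")
  else if (any(!is.finite(object@data)))
    msg <- c(msg, "all values must be finite")
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    msg <- c(msg, "'voxelSize' must be three positive lengths (mm)")
  if (length(object@tr) != 1L || !is.finite(object@tr) || object@tr <= 0)
    msg <- c(msg, "'tr' must be a single positive number (s)")
  if (length(msg)) msg else TRUE
})

#' Ground truth of one synthesized subject
#'
#' Records everything needed to reconstruct the noise-free signal exactly:
#' the templates, the exact spontaneous time-courses and task signals drawn,
#' the drift, baseline and schedules.
#'
#' @slot templates list of [NetworkTemplate-class] objects.
#' @slot spontaneous matrix (n_volumes x n_templates) of spontaneous
#'   time-courses in signal units (already scaled by each template's
#'   amplitude); column names are the template names.
#' @slot taskSignals matrix (n_volumes x n_templates) of
#'   `taskCoupling * (HRF convolved boxcar)` per template.
#' @slot drift numeric drift time-course (n_volumes).
#' @slot driftMap 3D array of per-voxel drift loadings (smooth positive
#'   field; the drift signal at voxel v is `driftMap(v) * drift(t)`).
#' @slot baseline scalar baseline intensity.
#' @slot schedules named list of [EventSchedule-class], one per condition.
#' @slot seed integer seed the subject was generated from.
#'
#' @export
setClass("SubjectGroundTruth",
  representation(
    templates = "list",
    spontaneous = "matrix",
    taskSignals = "matrix",
    drift = "numeric",
    driftMap = "array",
    baseline = "numeric",
    schedules = "list",
    seed = "integer"
  )
)

setValidity("SubjectGroundTruth", function(object) {
  msg <- character()
  k <- length(object@templates)
  if (k == 0) msg <- c(msg, "at least one template required")
  if (ncol(object@spontaneous) != k || ncol(object@taskSignals) != k)
    msg <- c(msg, "spontaneous/taskSignals must have one column per template")
  if (nrow(object@spontaneous) != nrow(object@taskSignals) ||
      nrow(object@spontaneous) != length(object@drift))
    msg <- c(msg, "time dimensions of spontaneous, taskSignals and drift differ")
  if (length(msg)) msg else TRUE
})

#' First-level GLM design matrix
#'
#' HRF-convolved condition regressors sampled at volume acquisition times,
#' plus an explicit intercept column named "constant". Regressors are not
#' mean-centered; the intercept absorbs the mean.
#'
#' @slot values numeric matrix, n_volumes x n_regressors, with column names.
#' @slot tr repetition time (s) the rows are sampled at.
#'
#' @seealso [buildDesignMatrix()]
#' @export
setClass("DesignMatrix",
  representation(values = "matrix", tr = "numeric")
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  v <- object@values
  if (is.null(colnames(v)) || any(!nzchar(colnames(v))))
    msg <- c(msg, "all columns must be named")
  if (any(!is.finite(v)))
    msg <- c(msg, "all values must be finite")
  if (any(apply(v, 2, function(x) all(x == 0))))
    msg <- c(msg, "no all-zero column allowed")
  if (length(object@tr) != 1L || object@tr <= 0)
    msg <- c(msg, "'tr' must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Result of a first-level voxelwise GLM fit
#'
#' @slot betas 4D array (x, y, z, regressor) of OLS coefficients.
#' @slot zMaps 4D array (x, y, z, regressor) of z statistics (t converted to z
#'   through the t CDF, capped at +/-40).
#' @slot residuals 4D array of OLS residuals, same shape as the input series.
#' @slot temporalMean 3D array of per-voxel temporal means of the input.
#' @slot design the [DesignMatrix-class] used in the fit.
#' @slot voxelSize voxel edge lengths (mm) inherited from the input series.
#' @slot tr repetition time (s).
#'
#' @seealso [fitGlm()], [residualize()]
#' @export
setClass("GLMResult",
  representation(
    betas = "array",
    zMaps = "array",
    residuals = "array",
    temporalMean = "array",
    design = "DesignMatrix",
    voxelSize = "numeric",
    tr = "numeric"
  )
)

#' Spatial ICA decomposition
#'
#' Rows of `maps` are z-scored spatial sources (mean 0, SD 1 over in-mask
#' voxels); `timecourses` columns are the corresponding mixing time-courses.
#' The raw source map of component i is `maps[i, ] * mapScale[i] + mapMean[i]`,
#' so `timecourses %*% rawMaps` reproduces the PCA-reduced, voxel-demeaned
#' data (see [reconstruct()]).
#'
#' @slot maps k x n_inmask_voxels matrix of z-scored spatial maps.
#' @slot timecourses n_volumes x k mixing matrix.
#' @slot mapScale,mapMean per-component scale/mean removed by z-scoring.
#' @slot explainedVariance per-component fraction of total data variance.
#' @slot mask 3D logical array of included voxels.
#' @slot voxelSize voxel edge lengths (mm).
#' @slot tr repetition time (s).
#' @slot boundaries integer vector of per-subject volume counts (length 1 for
#'   a single subject; longer after [concatenateCohort()]).
#' @slot seed integer seed of the kept FastICA restart.
#' @slot iterations FastICA iterations of the kept restart.
#'
#' @seealso [spatialICA()], [matchComponent()], [fixSign()]
#' @export
setClass("ICADecomposition",
  representation(
    maps = "matrix",
    timecourses = "matrix",
    mapScale = "numeric",
    mapMean = "numeric",
    explainedVariance = "numeric",
    mask = "array",
    voxelSize = "numeric",
    tr = "numeric",
    boundaries = "integer",
    seed = "integer",
    iterations = "integer"
  )
)

setValidity("ICADecomposition", function(object) {
  msg <- character()
  k <- nrow(object@maps)
  if (ncol(object@timecourses) != k)
    msg <- c(msg, "'timecourses' must have one column per component")
  if (length(object@mapScale) != k || length(object@mapMean) != k ||
      length(object@explainedVariance) != k)
    msg <- c(msg, "per-component slots must have length k")
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L)
    msg <- c(msg, "'mask' must be a 3D logical array")
  else if (sum(object@mask) != ncol(object@maps))
    msg <- c(msg, "'maps' columns must equal the number of in-mask voxels")
  if (any(object@explainedVariance < -1e-12) ||
      sum(object@explainedVariance) > 1 + 1e-8)
    msg <- c(msg, "explained variance fractions must be >= 0 and sum to <= 1")
  if (length(msg)) msg else TRUE
})

#' Match of an ICA component to a reference network map
#'
#' @slot componentIndex index of the best-matching component.
#' @slot sign +1 or -1; the sign flip applied so the map correlates
#'   positively with the reference.
#' @slot spatialPcc Pearson correlation with the reference after sign fixing
#'   (always >= 0).
#' @slot label network label of the reference ("visual", "dmn", "other").
#'
#' @seealso [matchComponent()]
#' @export
setClass("NetworkMatch",
  representation(
    componentIndex = "integer",
    sign = "numeric",
    spatialPcc = "numeric",
    label = "character"
  )
)

#' Permutation null distribution of network similarity
#'
#' Similarity records obtained by residualizing each subject with a DONOR
#' subject's task timing (a derangement: no subject keeps its own timing),
#' re-running ICA, and comparing against the subject's original-data
#' decomposition.
#'
#' @slot records data.frame of similarity records with condition "null".
#' @slot permutationMap integer matrix (n_rounds x n_subjects); entry (r, i)
#'   is the donor subject index for subject i in round r.
#' @slot nRounds number of permutation rounds.
#' @slot seed integer seed of the permutation draw.
#'
#' @seealso [buildNull()], [equivalenceTest()]
#' @export
setClass("NullDistribution",
  representation(
    records = "data.frame",
    permutationMap = "matrix",
    nRounds = "integer",
    seed = "integer"
  )
)

setValidity("NullDistribution", function(object) {
  msg <- character()
  pm <- object@permutationMap
  if (nrow(pm) != object@nRounds)
    msg <- c(msg, "'permutationMap' must have one row per round")
  if (ncol(pm) >= 1 && any(pm == col(pm)))
    msg <- c(msg, "every permutation round must be a derangement (no fixed points)")
  if (length(msg)) msg else TRUE
})

#' Study configuration
#'
#' Full parameterization of a simulated study: the synthetic scene, the
#' preprocessing, GLM, ICA, similarity and equivalence-test options, and the
#' master seed. Serializable to YAML via [writeStudyConfig()].
#'
#' @slot nSubjects number of subjects in the cohort (>= 2).
#' @slot seed master integer seed; every stochastic stage derives from it.
#' @slot scene named list of scene parameters (see [defaultScene()]).
#' @slot preprocess named list: highpassHz, fwhmMm, targetMedian, and logical
#'   skip flags skipHighpass/skipSmooth/skipNormalize.
#' @slot glm named list: hrf ("double-gamma" or "boynton"), conditions.
#' @slot ica named list: nComponents (integer or "auto"), restarts, maxIter, tol.
#' @slot similarity named list: zThreshold.
#' @slot equivalence named list: nRounds, alpha.
#' @slot outputDir output directory ("" to keep results in memory only).
#'
#' @seealso [studyConfig()], [runStudy()]
#' @export
setClass("StudyConfig",
  representation(
    nSubjects = "integer",
    seed = "integer",
    scene = "list",
    preprocess = "list",
    glm = "list",
    ica = "list",
    similarity = "list",
    equivalence = "list",
    outputDir = "character"
  )
)
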