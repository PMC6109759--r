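#' Construct a ground-truth network template
#'
#' @param label "visual", "dmn" or "other".
#' @param name unique template name within a scene (defaults to the label).
#' @param spatialMap 3D nonnegative weight array; normalized to max 1.
#' @param taskCoupling signed gain on the HRF-convolved task regressor
#'   (> 0 positive BOLD, < 0 negative BOLD, 0 uncoupled).
#' @param taskCondition condition the template couples to ("" if uncoupled).
#' @param spontaneousAmplitude SD (signal units) of the spontaneous
#'   fluctuation attached to the map.
#' @param spontaneousCutoff low-pass corner (Hz) of the fluctuation.
#' @param hrf HRF name for this template's task response (override hook for
#'   non-canonical responses; default the canonical double-gamma).
#' @return a [NetworkTemplate-class].
#' @export
networkTemplate <- function(label, name = label, spatialMap,
                            taskCoupling = 0, taskCondition = "",
                            spontaneousAmplitude = 0,
                            spontaneousCutoff = 0.1,
                            hrf = "double-gamma") {
  m <- max(spatialMap)
  if (m > 0) spatialMap <- spatialMap / m
  new("NetworkTemplate",
      label = label, name = name, spatialMap = spatialMap,
      taskCoupling = taskCoupling, taskCondition = taskCondition,
      spontaneousAmplitude = spontaneousAmplitude,
      spontaneousCutoff = spontaneousCutoff, hrf = hrf)
}

#' Default synthetic scene
#'
#' The scene emulates the study design: a 20 x 20 x 10 voxel grid
#' (3 x 3 x 5.5 mm), TR 1 s, 360 volumes, at least 55 visual and 55 audio
#' events (mean spacing 6.2 s in 4-18 s, mean duration 1.2 s in 0.5-3.5 s)
#' plus a motor response at each visual offset. Three sources are planted:
#'
#' * `visual`: positive BOLD (coupling +1.0 to the visual condition) plus an
#'   independent spontaneous fluctuation (amplitude 1.0) on one map — the
#'   visual functional-connectivity network, whose time-course is therefore
#'   task-correlated.
#' * `dmn`: the default-mode functional-connectivity network, carrying only a
#'   spontaneous fluctuation (amplitude 1.0).
#' * `dmn_task`: the task-evoked DMN deactivation (coupling -0.6, no
#'   spontaneous signal) on a map that overlaps the `dmn` map but has a
#'   distinct spatial profile. DMN nodes are known to show hemodynamic
#'   responses distinct from the network's coherent fluctuation, which is why
#'   spatial ICA extracts a DMN component whose time-course is unrelated to
#'   the task even though the region shows robust negative BOLD.
#'
#' @param grid integer length-3 voxel grid.
#' @param visualCoupling,dmnCoupling task gains of the visual network and the
#'   DMN deactivation (the negative BOLD amplitude relative to positive is not
#'   established; -0.6 reflects its weaker signal).
#' @param spontaneousAmplitude spontaneous SD of both FC networks.
#' @param noiseSd white measurement noise SD (signal units).
#' @return a named list of scene parameters accepted by [generateCohort()].
#' @export
defaultScene <- function(grid = c(20L, 20L, 10L),
                         visualCoupling = 1.0, dmnCoupling = -0.6,
                         spontaneousAmplitude = 1.0, noiseSd = 0.5) {
  list(
    grid = as.integer(grid),
    voxelSize = c(3, 3, 5.5),
    tr = 1,
    nVolumes = 360L,
    baseline = 100,
    noiseSd = noiseSd,
    driftAmplitude = 0.5,
    driftPeriod = 128,
    responseDuration = 0.5,
    events = list(nEvents = 55L, meanGap = 6.2, gapRange = c(4, 18),
                  meanDuration = 1.2, durationRange = c(0.5, 3.5)),
    templates = list(
      list(label = "visual", name = "visual",
           center = c(6, 10.5, 3.5), sigma = 2.2,
           taskCoupling = visualCoupling, taskCondition = "visual",
           spontaneousAmplitude = spontaneousAmplitude,
           spontaneousCutoff = 0.1),
      list(label = "dmn", name = "dmn",
           center = c(15, 13, 7), sigma = 2.2,
           taskCoupling = 0, taskCondition = "",
           spontaneousAmplitude = spontaneousAmplitude,
           spontaneousCutoff = 0.1),
      list(label = "other", name = "dmn_task",
           center = c(15, 8.5, 6), sigma = 2.2,
           taskCoupling = dmnCoupling, taskCondition = "visual",
           spontaneousAmplitude = 0,
           spontaneousCutoff = 0.1)
    )
  )
}

.sceneTemplates <- function(scene) {
  lapply(scene$templates, function(sp) {
    networkTemplate(
      label = sp$label, name = sp$name,
      spatialMap = .gaussianBlob(scene$grid, sp$center, sp$sigma),
      taskCoupling = sp$taskCoupling, taskCondition = sp$taskCondition,
      spontaneousAmplitude = sp$spontaneousAmplitude,
      spontaneousCutoff = sp$spontaneousCutoff,
      hrf = if (is.null(sp$hrf)) "double-gamma" else sp$hrf
    )
  })
}

# Smooth random spatial loading for the scanner drift: white noise smoothed
# with a wide Gaussian, standardized, and mapped to a positive field around 1
# (drift amplitude varies smoothly across the field of view rather than being
# spatially uniform). Draws from the current RNG stream.
.driftLoading <- function(grid, smoothSigmaVox = 4, relSd = 0.4) {
  field <- array(stats::rnorm(prod(grid)), grid)
  for (axis in 1:3) {
    K <- .gaussKernelMatrix(grid[axis], smoothSigmaVox)
    perm <- c(axis, setdiff(1:3, axis))
    fp <- aperm(field, perm)
    dp <- dim(fp)
    dim(fp) <- c(dp[1], prod(dp[-1]))
    fp <- K %*% fp
    dim(fp) <- dp
    field <- aperm(fp, order(perm))
  }
  field <- (field - mean(field)) / stats::sd(field)
  pmax(1 + relSd * field, 0.1)
}

# White Gaussian noise low-pass filtered by zeroing FFT bins above the cutoff,
# then variance-normalized (SD 1). Draws from the current RNG stream.
.spontaneousTimecourse <- function(n, tr, cutoff) {
  x <- stats::rnorm(n)
  f <- stats::fft(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided spectrum
  f[freqs > cutoff] <- 0
  y <- Re(stats::fft(f, inverse = TRUE)) / n
  (y - mean(y)) / stats::sd(y)
}

#' Synthesize one subject's BOLD series with known ground truth
#'
#' Signal model, per voxel v and volume t:
#' \deqn{y(v,t) = baseline + \sum_T map_T(v) [c_T x_T(t) + s_T(t)] + d(t) + \epsilon(v,t)}
#' where `x_T` is the template's HRF-convolved task boxcar, `c_T` its signed
#' coupling, `s_T` its spontaneous fluctuation (seeded Gaussian noise low-pass
#' filtered at the template cutoff, variance-normalized, scaled by the
#' template amplitude, and redrawn — up to 100 times — until its correlation
#' with every task regressor is below `decorrelationBound`), `d` a slow cosine
#' drift with seeded random phase whose amplitude varies smoothly across the
#' volume (a seeded smooth positive loading field around 1), and `\epsilon`
#' white Gaussian noise.
#'
#' Templates carrying spontaneous signal are the sources spatial ICA must
#' separate, so their supports must be near-disjoint (pairwise Dice below
#' `overlapBound`); a task-only template may overlap them (overlapping task
#' activation/deactivation is the phenomenon the pipeline studies).
#'
#' @param templates list of [NetworkTemplate-class] on a common grid.
#' @param schedules named list of [EventSchedule-class] covering every
#'   condition any template couples to.
#' @param voxelSize voxel edge lengths (mm).
#' @param tr repetition time (s).
#' @param nVolumes number of volumes.
#' @param noiseSd white noise SD (signal units).
#' @param driftAmplitude cosine drift amplitude (signal units).
#' @param driftPeriod drift period (s), default 128.
#' @param baseline baseline intensity (signal units).
#' @param seed integer seed; fully determines the subject.
#' @param overlapBound maximum pairwise support Dice between
#'   spontaneous-carrying templates (default 0.05).
#' @param decorrelationBound maximum |Pearson r| between a spontaneous
#'   time-course and any task regressor (default 0.1).
#' @return list with elements `series` (a [VolumeSeries-class]) and `truth`
#'   (a [SubjectGroundTruth-class]).
#' @seealso [generateCohort()], [reconstructTruth()]
#' @export
synthesizeSubject <- function(templates, schedules, voxelSize = c(3, 3, 5.5),
                              tr = 1, nVolumes = 360L, noiseSd = 0.5,
                              driftAmplitude = 0.5, driftPeriod = 128,
                              baseline = 100, seed = 1L,
                              overlapBound = 0.05,
                              decorrelationBound = 0.1) {
  stopifnot(length(templates) >= 1)
  grid <- dim(templates[[1]]@spatialMap)
  for (tp in templates) {
    stopifnot(identical(dim(tp@spatialMap), grid))
    if (abs(tp@taskCoupling) > 0 &&
        !tp@taskCondition %in% names(schedules))
      stop("no schedule for condition '", tp@taskCondition,
           "' required by template '", tp@name, "'")
  }
  fc <- which(vapply(templates, function(t) t@spontaneousAmplitude > 0, TRUE))
  if (length(fc) > 1) {
    for (i in seq_along(fc)[-1]) for (j in seq_len(i - 1)) {
      a <- templates[[fc[i]]]@spatialMap > 0
      b <- templates[[fc[j]]]@spatialMap > 0
      d <- .diceSupport(a, b)
      if (is.finite(d) && d > overlapBound)
        stop("spontaneous templates '", templates[[fc[i]]]@name, "' and '",
             templates[[fc[j]]]@name, "' overlap (support Dice ",
             signif(d, 3), " > ", overlapBound, ")")
    }
  }

  k <- length(templates)
  nm <- vapply(templates, function(t) t@name, "")

  # task signals per template (deterministic given schedules)
  taskSignals <- matrix(0, nVolumes, k, dimnames = list(NULL, nm))
  for (i in seq_len(k)) {
    tp <- templates[[i]]
    if (abs(tp@taskCoupling) > 0)
      taskSignals[, i] <- tp@taskCoupling *
        .convolvedRegressor(schedules[[tp@taskCondition]], nVolumes, tr,
                            hrfName = tp@hrf)
  }

  # regressors used for the decorrelation screen: all scheduled conditions
  screen <- vapply(schedules, function(s) {
    if (nEvents(s) > 0) .convolvedRegressor(s, nVolumes, tr)
    else numeric(nVolumes)
  }, numeric(nVolumes))
  screen <- screen[, apply(screen, 2, stats::sd) > 0, drop = FALSE]

  .withSeed(seed, {
    spont <- matrix(0, nVolumes, k, dimnames = list(NULL, nm))
    for (i in seq_len(k)) {
      tp <- templates[[i]]
      if (tp@spontaneousAmplitude > 0) {
        for (draw in seq_len(100)) {
          s <- .spontaneousTimecourse(nVolumes, tr, tp@spontaneousCutoff)
          if (ncol(screen) == 0 ||
              max(abs(stats::cor(s, screen))) < decorrelationBound) break
          if (draw == 100)
            stop("could not decorrelate spontaneous time-course of '",
                 tp@name, "' from the task regressors in 100 draws")
        }
        spont[, i] <- tp@spontaneousAmplitude * s
      }
    }
    phase <- stats::runif(1, 0, 2 * pi)
    drift <- driftAmplitude *
      cos(2 * pi * (seq_len(nVolumes) - 1) * tr / driftPeriod + phase)
    driftMap <- if (driftAmplitude > 0) .driftLoading(grid)
                else array(0, grid)

    nVox <- prod(grid)
    mapMat <- vapply(templates, function(t) .flatten3D(t@spatialMap),
                     numeric(nVox))                     # nVox x k
    signal <- mapMat %*% t(taskSignals + spont)         # nVox x T
    signal <- signal + outer(.flatten3D(driftMap), drift) + baseline
    if (noiseSd > 0)
      signal <- signal + stats::rnorm(length(signal), sd = noiseSd)
    dim(signal) <- c(grid, nVolumes)

    truth <- new("SubjectGroundTruth",
                 templates = templates, spontaneous = spont,
                 taskSignals = taskSignals, drift = drift,
                 driftMap = driftMap,
                 baseline = baseline, schedules = schedules,
                 seed = as.integer(seed))
    list(series = new("VolumeSeries", data = signal,
                      voxelSize = as.numeric(voxelSize), tr = tr),
         truth = truth)
  })
}

#' Reconstruct the noise-free signal recorded in a ground truth
#'
#' Rebuilds `baseline + sum_T map_T (task_T + spont_T) + drift` from the exact
#' time-courses stored in the ground truth. For a subject synthesized with
#' `noiseSd = 0` this reproduces the series exactly.
#'
#' @param truth a [SubjectGroundTruth-class].
#' @return 4D array of the noise-free signal.
#' @export
reconstructTruth <- function(truth) {
  grid <- dim(truth@templates[[1]]@spatialMap)
  nVox <- prod(grid)
  mapMat <- vapply(truth@templates, function(t) .flatten3D(t@spatialMap),
                   numeric(nVox))
  signal <- mapMat %*% t(truth@taskSignals + truth@spontaneous)
  signal <- signal + outer(.flatten3D(truth@driftMap), truth@drift) +
    truth@baseline
  dim(signal) <- c(grid, nrow(truth@spontaneous))
  signal
}

#' Generate a seeded synthetic cohort
#'
#' Each subject receives an independent seed (`masterSeed + index`) and an
#' independently drawn event schedule per condition, so task timing is unique
#' to every subject — the property the cross-subject permutation null relies
#' on. The motor schedule is derived from the subject's visual schedule.
#'
#' @param nSubjects number of subjects (>= 2; the permutation null needs at
#'   least a swap). The study design used 30; tests use smaller cohorts.
#' @param scene scene parameter list, see [defaultScene()].
#' @param masterSeed integer master seed.
#' @return list of per-subject lists, each with `series`, `truth` and
#'   `schedules`.
#' @export
generateCohort <- function(nSubjects = 30L, scene = defaultScene(),
                           masterSeed = 1L) {
  if (nSubjects < 2)
    stop("'nSubjects' must be >= 2 (the permutation null needs a swap)")
  templates <- .sceneTemplates(scene)
  scanDuration <- scene$nVolumes * scene$tr
  ev <- scene$events
  lapply(seq_len(nSubjects), function(i) {
    seed <- as.integer(masterSeed) + i
    visual <- generateEventSchedule(
      ev$nEvents, ev$meanGap, ev$gapRange, ev$meanDuration, ev$durationRange,
      scanDuration, condition = "visual", seed = .childSeed(seed, 1))
    audio <- generateEventSchedule(
      ev$nEvents, ev$meanGap, ev$gapRange, ev$meanDuration, ev$durationRange,
      scanDuration, condition = "audio", seed = .childSeed(seed, 2))
    motor <- deriveMotorSchedule(visual, scene$responseDuration)
    schedules <- list(visual = visual, audio = audio, motor = motor)
    out <- synthesizeSubject(
      templates, schedules,
      voxelSize = scene$voxelSize, tr = scene$tr,
      nVolumes = scene$nVolumes, noiseSd = scene$noiseSd,
      driftAmplitude = scene$driftAmplitude, driftPeriod = scene$driftPeriod,
      baseline = scene$baseline, seed = seed)
    out$schedules <- schedules
    out
  })
}
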