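#' Construct a study configuration
#'
#' All tunable parameters of a simulated study with their defaults. Every
#' stochastic stage derives its seed from the master `seed`, so a
#' configuration fully determines the study output.
#'
#' @param nSubjects cohort size (default 30, the study design; tests use
#'   smaller cohorts).
#' @param seed master integer seed.
#' @param scene scene parameters, see [defaultScene()].
#' @param preprocess list of preprocessing options (highpassHz, fwhmMm,
#'   targetMedian, skipHighpass, skipSmooth, skipNormalize, method).
#' @param glm list of GLM options (hrf).
#' @param ica list of ICA options (nComponents: integer or "auto", mode:
#'   "subject" or "group", restarts, maxIter, tol).
#' @param similarity list of similarity options (zThreshold).
#' @param equivalence list of equivalence options (nRounds, alpha).
#' @param outputDir output directory for TSV tables ("" keeps results in
#'   memory only).
#' @return a [StudyConfig-class].
#' @export
studyConfig <- function(nSubjects = 30L, seed = 1L, scene = defaultScene(),
                        preprocess = list(), glm = list(), ica = list(),
                        similarity = list(), equivalence = list(),
                        outputDir = "") {
  merge <- function(defaults, user) {
    defaults[names(user)] <- user
    defaults
  }
  new("StudyConfig",
      nSubjects = as.integer(nSubjects), seed = as.integer(seed),
      scene = scene,
      preprocess = merge(list(highpassHz = 0.01, fwhmMm = 5,
                              targetMedian = 1e4, skipHighpass = FALSE,
                              skipSmooth = FALSE, skipNormalize = FALSE,
                              method = "gaussian-line"), preprocess),
      glm = merge(list(hrf = "double-gamma"), glm),
      ica = merge(list(nComponents = "auto", mode = "subject",
                       restarts = 5L, maxIter = 1000L, tol = 1e-4), ica),
      similarity = merge(list(zThreshold = 3), similarity),
      equivalence = merge(list(nRounds = 1L, alpha = 0.05), equivalence),
      outputDir = outputDir)
}

.configAsList <- function(config) {
  list(nSubjects = config@nSubjects, seed = config@seed,
       scene = config@scene, preprocess = config@preprocess,
       glm = config@glm, ica = config@ica, similarity = config@similarity,
       equivalence = config@equivalence, outputDir = config@outputDir)
}

#' Write a study configuration as YAML
#' @param config a [StudyConfig-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeStudyConfig <- function(config, path) {
  yaml::write_yaml(.configAsList(config), path)
  invisible(path)
}

#' Read a study configuration from YAML
#' @param path YAML file written by [writeStudyConfig()] (or hand-edited;
#'   missing fields take their defaults).
#' @return a [StudyConfig-class].
#' @export
readStudyConfig <- function(path) {
  x <- yaml::read_yaml(path)
  scene <- if (is.null(x$scene)) defaultScene() else x$scene
  if (!is.null(scene$grid)) scene$grid <- as.integer(scene$grid)
  if (!is.null(scene$nVolumes)) scene$nVolumes <- as.integer(scene$nVolumes)
  studyConfig(
    nSubjects = if (is.null(x$nSubjects)) 30L else x$nSubjects,
    seed = if (is.null(x$seed)) 1L else x$seed,
    scene = scene,
    preprocess = if (is.null(x$preprocess)) list() else x$preprocess,
    glm = if (is.null(x$glm)) list() else x$glm,
    ica = if (is.null(x$ica)) list() else x$ica,
    similarity = if (is.null(x$similarity)) list() else x$similarity,
    equivalence = if (is.null(x$equivalence)) list() else x$equivalence,
    outputDir = if (is.null(x$outputDir)) "" else x$outputDir)
}

# md5 of the serialized configuration, for provenance stamps; the output
# directory is not part of the scientific configuration
.configHash <- function(config) {
  x <- .configAsList(config)
  x$outputDir <- NULL
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(x, tf)
  unname(tools::md5sum(tf))
}

.writeTable <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full study: observed arm, permutation null, equivalence test
#'
#' Executes the complete pipeline on a synthetic cohort:
#' \enumerate{
#'   \item generate the cohort ([generateCohort()]);
#'   \item preprocess every subject ([preprocessSeries()]);
#'   \item observed arm: per subject, decompose the preprocessed data with
#'     spatial ICA, fit the first-level GLM on the subject's own task timing,
#'     residualize, decompose the residualized data with the same model order
#'     and seed, and record the similarity of the matched visual and DMN
#'     components before vs after residualization;
#'   \item null arm: repeat the residualization + ICA + similarity with each
#'     subject assigned a DONOR subject's task timing ([buildNull()]);
#'   \item paired equivalence tests per network and metric
#'     ([equivalenceTable()]).
#' }
#' Subject-wise ICA is the default inference path; `ica$mode = "group"`
#' instead decomposes the temporally concatenated cohort before and after
#' residualization and returns group-level similarity records (no paired
#' test, which needs per-subject pairs).
#'
#' The run is deterministic given the configuration. If `outputDir` is set,
#' the observed, null and equivalence tables are written as TSV with a
#' provenance header (package version, config hash, master seed).
#'
#' @param config a [StudyConfig-class].
#' @param verbose print per-subject progress and stage timings.
#' @return list with elements `observed` (data.frame of similarity records),
#'   `null` (a [NullDistribution-class] or NULL in group mode), `equivalence`
#'   (data.frame or NULL in group mode), `modelOrders` (per-subject ICA model
#'   orders), `provenance` (list: version, configHash, seed), and `config`.
#' @export
runStudy <- function(config = studyConfig(), verbose = FALSE) {
  t0 <- Sys.time()
  scene <- config@scene
  say <- function(...) if (verbose) message(sprintf(...))

  say("generating cohort of %d subjects (seed %d)", config@nSubjects,
      config@seed)
  cohort <- generateCohort(config@nSubjects, scene, masterSeed = config@seed)

  templates <- cohort[[1]]$truth@templates
  labels <- vapply(templates, function(t) t@label, "")
  references <- list()
  for (lab in c("visual", "dmn")) {
    i <- match(lab, labels)
    if (!is.na(i)) references[[lab]] <- templates[[i]]@spatialMap
  }
  if (length(references) == 0)
    stop("scene has no 'visual' or 'dmn' template to match against")

  pp <- config@preprocess
  preprocessed <- lapply(seq_along(cohort), function(i) {
    say("preprocessing subject %d/%d", i, length(cohort))
    preprocessSeries(cohort[[i]]$series,
                     highpassHz = pp$highpassHz, fwhmMm = pp$fwhmMm,
                     targetMedian = pp$targetMedian,
                     skipHighpass = pp$skipHighpass,
                     skipSmooth = pp$skipSmooth,
                     skipNormalize = pp$skipNormalize,
                     highpassMethod = pp$method)
  })

  ica <- config@ica
  zThr <- config@similarity$zThreshold

  if (identical(ica$mode, "group")) {
    say("group mode: concatenating %d subjects", length(cohort))
    concatOrig <- concatenateCohort(preprocessed)
    residualizedList <- lapply(seq_along(cohort), function(i) {
      design <- buildDesignMatrix(cohort[[i]]$schedules,
                                  nVolumes(preprocessed[[i]]),
                                  scene$tr, hrfName = config@glm$hrf)
      residualize(preprocessed[[i]], fitGlm(preprocessed[[i]], design))
    })
    concatRes <- concatenateCohort(residualizedList)
    k <- if (identical(ica$nComponents, "auto"))
      estimateModelOrder(concatenateCohort(lapply(cohort, `[[`, "series")))
    else as.integer(ica$nComponents)
    icaSeed <- .childSeed(config@seed, 7)
    decOrig <- spatialICA(concatOrig, k, seed = icaSeed,
                          restarts = ica$restarts, maxIter = ica$maxIter,
                          tol = ica$tol)
    decRes <- spatialICA(concatRes, k, seed = icaSeed,
                         restarts = ica$restarts, maxIter = ica$maxIter,
                         tol = ica$tol)
    observed <- do.call(rbind, lapply(names(references), function(lab)
      compareNetworks(decOrig, decRes, references[[lab]], lab,
                      zThreshold = zThr, subjectId = "group")))
    result <- list(observed = observed, null = NULL, equivalence = NULL,
                   modelOrders = k,
                   provenance = list(version = .packageVersion(),
                                     configHash = .configHash(config),
                                     seed = config@seed),
                   config = config)
    .writeStudyOutputs(result, config)
    return(result)
  }

  subjects <- vector("list", length(cohort))
  observed <- list()
  for (i in seq_along(cohort)) {
    tS <- Sys.time()
    series <- preprocessed[[i]]
    schedules <- cohort[[i]]$schedules
    design <- buildDesignMatrix(schedules, nVolumes(series), scene$tr,
                                hrfName = config@glm$hrf)
    # model order is estimated on the raw series: smoothing and filtering
    # color the eigenspectrum and inflate evidence-based estimates
    k <- if (identical(ica$nComponents, "auto"))
      estimateModelOrder(cohort[[i]]$series) else as.integer(ica$nComponents)
    icaSeed <- .childSeed(config@seed, 1000 + i)
    decOrig <- spatialICA(series, k, seed = icaSeed,
                          restarts = ica$restarts, maxIter = ica$maxIter,
                          tol = ica$tol)
    fit <- fitGlm(series, design)
    res <- residualize(series, fit)
    decRes <- spatialICA(res, k, seed = icaSeed,
                         restarts = ica$restarts, maxIter = ica$maxIter,
                         tol = ica$tol)
    id <- sprintf("sub-%02d", i)
    for (lab in names(references)) {
      observed[[length(observed) + 1L]] <-
        compareNetworks(decOrig, decRes, references[[lab]], lab,
                        zThreshold = zThr, subjectId = id)
    }
    subjects[[i]] <- list(id = id, preprocessed = series,
                          originalDecomposition = decOrig,
                          nComponents = k, icaSeed = icaSeed,
                          schedules = schedules, references = references)
    say("subject %d/%d done (k = %d, ICA seed %d, %.1f s)", i,
        length(cohort), k, icaSeed,
        as.numeric(difftime(Sys.time(), tS, units = "secs")))
  }
  observed <- do.call(rbind, observed)

  say("building null distribution (%d round(s))",
      config@equivalence$nRounds)
  null <- buildNull(subjects, nRounds = config@equivalence$nRounds,
                    seed = .childSeed(config@seed, 99),
                    hrfName = config@glm$hrf, zThreshold = zThr,
                    restarts = ica$restarts, maxIter = ica$maxIter,
                    tol = ica$tol)
  equivalence <- equivalenceTable(observed, null,
                                  alpha = config@equivalence$alpha)
  say("total %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  result <- list(
    observed = observed, null = null, equivalence = equivalence,
    modelOrders = vapply(subjects, function(s) s$nComponents, 1L),
    provenance = list(version = .packageVersion(),
                      configHash = .configHash(config), seed = config@seed),
    config = config)
  .writeStudyOutputs(result, config)
  result
}

.packageVersion <- function() {
  as.character(utils::packageVersion("fcEquiv"))
}

.writeStudyOutputs <- function(result, config) {
  if (!nzchar(config@outputDir)) return(invisible(NULL))
  dir <- config@outputDir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  header <- sprintf("# fcEquiv %s config=%s seed=%d",
                    result$provenance$version,
                    result$provenance$configHash,
                    result$provenance$seed)
  .writeTable(result$observed, file.path(dir, "observed.tsv"), header)
  if (!is.null(result$null))
    .writeTable(result$null@records, file.path(dir, "null.tsv"), header)
  if (!is.null(result$equivalence))
    .writeTable(result$equivalence, file.path(dir, "equivalence.tsv"),
                header)
  writeStudyConfig(config, file.path(dir, "config.yaml"))
  invisible(NULL)
}
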