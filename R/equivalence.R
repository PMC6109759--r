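#' Seeded random derangements of subjects
#'
#' Each permutation round assigns every subject a DONOR subject whose task
#' timing will be used for residualization. Rounds are uniform random
#' derangements (rejection-sampled): no subject ever keeps its own timing,
#' so the null only ever removes task-irrelevant variance. Distinct rounds
#' are preferred when the subject count permits.
#'
#' @param nSubjects number of subjects (>= 2).
#' @param nRounds number of permutation rounds.
#' @param seed integer seed.
#' @return integer matrix (nRounds x nSubjects) of donor indices.
#' @export
permuteAssignments <- function(nSubjects, nRounds = 1L, seed = 1L) {
  if (nSubjects < 2) stop("at least 2 subjects required")
  .withSeed(seed, {
    rounds <- matrix(0L, nRounds, nSubjects)
    seen <- character(0)
    for (r in seq_len(nRounds)) {
      for (try in seq_len(10000)) {
        p <- sample.int(nSubjects)
        if (any(p == seq_len(nSubjects))) next
        key <- paste(p, collapse = ",")
        # prefer unseen derangements; accept repeats after 50 tries
        if (!key %in% seen || try > 50) {
          rounds[r, ] <- p
          seen <- c(seen, key)
          break
        }
      }
    }
    rounds
  })
}

#' Build the permutation null distribution of network similarity
#'
#' For every round and subject, a design matrix is built from the DONOR
#' subject's schedules, the subject's preprocessed series is residualized
#' against it, subject-wise ICA is rerun with the same number of components
#' and seed as the observed arm, the networks are re-matched, and the
#' similarity against the subject's original-data decomposition is recorded
#' with condition "null". Since the donor timing is unrelated to the
#' subject's data, these records measure the natural alteration produced by
#' removing task-irrelevant variance — the "equivalency interval". ICA
#' non-convergence in a round is recorded as a missing value, not an error.
#'
#' @param subjects list of prepared per-subject states as produced by
#'   [runStudy()]'s observed arm: each element has `id`, `preprocessed`
#'   (a [VolumeSeries-class]), `originalDecomposition`, `nComponents`,
#'   `icaSeed`, `schedules` (named list of [EventSchedule-class]) and
#'   `references` (named list of 3D reference maps, e.g. visual and dmn).
#' @param nRounds number of permutation rounds (default 1, matching a single
#'   permuted re-analysis; more rounds tighten the null).
#' @param seed integer seed for the derangements.
#' @param hrfName HRF used for the donor design.
#' @param zThreshold Dice threshold, see [compareNetworks()].
#' @param restarts,maxIter,tol FastICA options, see [spatialICA()].
#' @return a [NullDistribution-class].
#' @export
buildNull <- function(subjects, nRounds = 1L, seed = 1L,
                      hrfName = "double-gamma", zThreshold = 3,
                      restarts = 5L, maxIter = 1000L, tol = 1e-4) {
  n <- length(subjects)
  if (n < 2) stop("at least 2 subjects required")
  # the null requires unique task timing per subject
  keys <- vapply(subjects, function(s)
    paste(round(s$schedules$visual@onsets, 6), collapse = ","), "")
  if (anyDuplicated(keys))
    stop("subjects with identical task timing detected; the permutation ",
         "null requires unique timing per subject")
  perm <- permuteAssignments(n, nRounds, seed)
  records <- list()
  for (r in seq_len(nRounds)) {
    for (i in seq_len(n)) {
      s <- subjects[[i]]
      donor <- subjects[[perm[r, i]]]
      design <- buildDesignMatrix(donor$schedules,
                                  nVolumes(s$preprocessed),
                                  repetitionTime(s$preprocessed),
                                  hrfName = hrfName)
      fit <- fitGlm(s$preprocessed, design)
      res <- residualize(s$preprocessed, fit)
      dec <- tryCatch(
        spatialICA(res, nComponents = s$nComponents, seed = s$icaSeed,
                   restarts = restarts, maxIter = maxIter, tol = tol),
        error = function(e) e)
      for (lab in names(s$references)) {
        rec <- if (inherits(dec, "error")) {
          data.frame(subject = s$id, network = lab, condition = "null",
                     permutation = r, temporalPcc = NA_real_,
                     spatialPcc = NA_real_, dice = NA_real_,
                     diceReason = conditionMessage(dec),
                     componentOriginal = NA_integer_,
                     componentResidualized = NA_integer_,
                     stringsAsFactors = FALSE)
        } else {
          compareNetworks(s$originalDecomposition, dec, s$references[[lab]],
                          lab, zThreshold = zThreshold, subjectId = s$id,
                          condition = "null", permutationIndex = r)
        }
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  new("NullDistribution",
      records = do.call(rbind, records),
      permutationMap = perm, nRounds = as.integer(nRounds),
      seed = as.integer(seed))
}

#' Paired equivalence test of observed similarity against the null
#'
#' Null records are averaged per subject across permutation rounds, paired
#' with the subject's observed value, and the per-subject differences
#' (observed - null) are tested with a paired Student t test. The alternative
#' of interest is one-sided (observed < null: removing the true task degrades
#' similarity more than removing an unrelated timing); the two-sided p value
#' is also reported. The verdict is "altered" iff the one-sided p is below
#' `alpha` AND the observed mean is below the null mean; otherwise the
#' observed alteration is "within_equivalency" — inside the natural
#' variability of removing task-irrelevant variance. A zero-variance
#' difference is capped at |t| = 40.
#'
#' @param observed data.frame of observed similarity records (from
#'   [compareNetworks()] with condition "observed").
#' @param null a [NullDistribution-class].
#' @param networkLabel network to test ("visual" or "dmn").
#' @param metric one of "temporalPcc", "spatialPcc", "dice".
#' @param alpha significance level, default 0.05.
#' @return one-row data.frame: network, metric, tStat, dof, pValue
#'   (one-sided), pTwoSided, meanObserved, meanNull, nPairs, verdict.
#' @export
equivalenceTest <- function(observed, null, networkLabel, metric,
                            alpha = 0.05) {
  stopifnot(metric %in% c("temporalPcc", "spatialPcc", "dice"))
  obs <- observed[observed$network == networkLabel, c("subject", metric)]
  nul <- null@records[null@records$network == networkLabel,
                      c("subject", metric)]
  if (all(is.na(nul[[metric]])) || all(is.na(obs[[metric]])))
    stop("all values missing for ", networkLabel, "/", metric)
  nulMean <- tapply(nul[[metric]], nul$subject, mean, na.rm = TRUE)
  pairs <- merge(
    stats::aggregate(obs[metric], by = list(subject = obs$subject), mean),
    data.frame(subject = names(nulMean), nullValue = as.numeric(nulMean)),
    by = "subject")
  pairs <- pairs[stats::complete.cases(pairs), ]
  n <- nrow(pairs)
  if (n < 3) stop("fewer than 3 complete subject pairs")
  d <- pairs[[metric]] - pairs$nullValue
  sdD <- stats::sd(d)
  if (sdD == 0) {
    t <- if (mean(d) == 0) 0 else sign(mean(d)) * 40
  } else {
    t <- mean(d) / (sdD / sqrt(n))
  }
  dof <- n - 1
  pOne <- stats::pt(t, dof)                 # alternative: observed < null
  pTwo <- 2 * stats::pt(-abs(t), dof)
  meanObs <- mean(pairs[[metric]])
  meanNull <- mean(pairs$nullValue)
  verdict <- if (pOne < alpha && meanObs < meanNull) "altered"
             else "within_equivalency"
  data.frame(network = networkLabel, metric = metric,
             tStat = t, dof = dof, pValue = pOne, pTwoSided = pTwo,
             meanObserved = meanObs, meanNull = meanNull, nPairs = n,
             verdict = verdict, stringsAsFactors = FALSE)
}

#' Equivalence-test table over all networks and metrics
#'
#' Runs [equivalenceTest()] for every network in the observed records and
#' every similarity metric, and binds the results. No multiple-testing
#' correction is applied across the network x metric grid; all p values are
#' reported side by side.
#'
#' @inheritParams equivalenceTest
#' @param metrics metrics to test.
#' @return data.frame with one row per network x metric.
#' @export
equivalenceTable <- function(observed, null,
                             metrics = c("temporalPcc", "spatialPcc", "dice"),
                             alpha = 0.05) {
  networks <- unique(observed$network)
  rows <- list()
  for (nw in networks) for (m in metrics) {
    rows[[length(rows) + 1L]] <-
      equivalenceTest(observed, null, nw, m, alpha)
  }
  do.call(rbind, rows)
}
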