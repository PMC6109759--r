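#' Construct an event schedule
#'
#' @param condition condition label.
#' @param onsets,durations,amplitudes event vectors (seconds; amplitudes
#'   unitless, default 1).
#' @param scanDuration scan duration in seconds.
#' @return a validated [EventSchedule-class].
#' @export
eventSchedule <- function(condition, onsets, durations,
                          amplitudes = rep(1, length(onsets)),
                          scanDuration) {
  new("EventSchedule",
      condition = condition,
      onsets = as.numeric(onsets),
      durations = as.numeric(durations),
      amplitudes = as.numeric(amplitudes),
      scanDuration = as.numeric(scanDuration))
}

.solverCache <- new.env(parent = emptyenv())

# Rate of a truncated exponential on [0, upper] with a given mean, solved
# numerically (mean is monotone decreasing in the rate); cached per argument.
.truncExpRate <- function(targetMean, upper) {
  stopifnot(targetMean > 0, targetMean < upper / 2)
  key <- paste("exp", targetMean, upper)
  if (!is.null(.solverCache[[key]])) return(.solverCache[[key]])
  f <- function(l) 1 / l - upper / (exp(upper * l) - 1) - targetMean
  .solverCache[[key]] <- stats::uniroot(f, c(1e-6, 50), tol = 1e-10)$root
  .solverCache[[key]]
}

.sampleTruncExp <- function(n, rate, upper) {
  # inverse-CDF sampling of exp(rate) truncated to [0, upper]
  u <- stats::runif(n)
  -log(1 - u * (1 - exp(-rate * upper))) / rate
}

# Log-normal meanlog giving a target mean after truncation to [lo, hi],
# at fixed sdlog (solved numerically); cached per argument.
.truncLnormMeanlog <- function(targetMean, lo, hi, sdlog = 0.45) {
  key <- paste("lnorm", targetMean, lo, hi, sdlog)
  if (!is.null(.solverCache[[key]])) return(.solverCache[[key]])
  m <- function(mu) {
    f <- function(x) x * stats::dlnorm(x, mu, sdlog)
    mass <- stats::plnorm(hi, mu, sdlog) - stats::plnorm(lo, mu, sdlog)
    stats::integrate(f, lo, hi, rel.tol = 1e-9)$value / mass - targetMean
  }
  .solverCache[[key]] <- stats::uniroot(m, log(c(lo, hi)), tol = 1e-10)$root
  .solverCache[[key]]
}

.sampleTruncLnorm <- function(n, meanlog, sdlog, lo, hi) {
  plo <- stats::plnorm(lo, meanlog, sdlog)
  phi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(plo + stats::runif(n) * (phi - plo), meanlog, sdlog)
}

#' Generate a random event schedule with study-design statistics
#'
#' Draws inter-onset spacings from a truncated exponential rescaled to the
#' target mean and durations from a truncated log-normal rescaled to the
#' target mean, matching the skewed jitter of an event-related design while
#' honoring the stated ranges. With the defaults (55+ events, mean spacing
#' 6.2 s in 4-18 s, mean duration 1.2 s in 0.5-3.5 s) the schedule emulates
#' the visual/audio stimulation streams of a 6-minute event-related run.
#' Durations never exceed the minimum spacing, so events cannot overlap.
#'
#' @param nEvents number of events (>= 1).
#' @param meanGap target mean inter-onset spacing (s).
#' @param gapRange length-2 numeric, admissible spacing range (s); must
#'   contain `meanGap`.
#' @param meanDuration target mean event duration (s).
#' @param durationRange length-2 numeric range (s); must contain
#'   `meanDuration` and its maximum must not exceed the minimum spacing.
#' @param scanDuration scan length (s); the schedule is redrawn (up to 100
#'   times) until every event ends before the scan does.
#' @param condition condition label for the schedule.
#' @param seed integer seed; identical arguments and seed give identical
#'   schedules.
#' @return an [EventSchedule-class].
#' @examples
#' sched <- generateEventSchedule(55, 6.2, c(4, 18), 1.2, c(0.5, 3.5), 360,
#'                                condition = "visual", seed = 1)
#' range(diff(onsets(sched)))
#' @export
generateEventSchedule <- function(nEvents, meanGap = 6.2, gapRange = c(4, 18),
                                  meanDuration = 1.2,
                                  durationRange = c(0.5, 3.5),
                                  scanDuration = 360,
                                  condition = "stim", seed = 1L) {
  stopifnot(nEvents >= 1,
            gapRange[1] < meanGap, meanGap < gapRange[2],
            durationRange[1] < meanDuration, meanDuration < durationRange[2],
            durationRange[2] <= gapRange[1])
  if ((nEvents - 1) * gapRange[1] + durationRange[1] > scanDuration)
    stop("infeasible design: ", nEvents, " events cannot fit in ",
         scanDuration, " s at minimum spacing ", gapRange[1], " s")
  gapRate <- .truncExpRate(meanGap - gapRange[1], gapRange[2] - gapRange[1])
  durMeanlog <- .truncLnormMeanlog(meanDuration, durationRange[1],
                                   durationRange[2])
  .withSeed(seed, {
    for (try in seq_len(100)) {
      gaps <- gapRange[1] +
        .sampleTruncExp(nEvents - 1, gapRate, gapRange[2] - gapRange[1])
      durs <- .sampleTruncLnorm(nEvents, durMeanlog, 0.45,
                                durationRange[1], durationRange[2])
      start <- stats::runif(1, 0, min(2, scanDuration / 20))
      ons <- start + c(0, cumsum(gaps))
      if (ons[nEvents] + durs[nEvents] <= scanDuration)
        return(eventSchedule(condition, ons, durs,
                             scanDuration = scanDuration))
    }
    stop("infeasible design: no schedule with ", nEvents,
         " events fit in ", scanDuration, " s after 100 draws")
  })
}

#' Derive the motor-response schedule from a visual schedule
#'
#' One motor event per visual event, at the visual stimulus offset (the
#' subject presses a button at the end of each visual stimulus). Responses
#' that would extend past the scan end are dropped with a warning.
#'
#' @param visual a visual [EventSchedule-class].
#' @param responseDuration duration of each response event (s), default 0.5.
#' @return an [EventSchedule-class] with condition "motor".
#' @export
deriveMotorSchedule <- function(visual, responseDuration = 0.5) {
  ons <- visual@onsets + visual@durations
  keep <- ons + responseDuration <= visual@scanDuration
  if (any(!keep))
    warning(sum(!keep), " motor event(s) clipped at scan end were dropped")
  eventSchedule("motor", ons[keep],
                rep(responseDuration, sum(keep)),
                scanDuration = visual@scanDuration)
}

#' Read an FSL 3-column event file
#'
#' Each line is `onset duration amplitude` (whitespace-separated, seconds).
#'
#' @param path file path.
#' @param condition condition label for the schedule (defaults to the file
#'   name without extension).
#' @param scanDuration scan duration (s) the events must fit into.
#' @return an [EventSchedule-class].
#' @export
readEvents <- function(path, condition = sub("\\.[^.]*$", "", basename(path)),
                       scanDuration) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(eventSchedule(condition, numeric(0), numeric(0), numeric(0),
                         scanDuration = scanDuration))
  parsed <- lapply(seq_along(lines), function(i) {
    fields <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]),
                                                   "[ \t]+")[[1]]))
    if (length(fields) != 3 || any(is.na(fields)))
      stop("malformed event line ", i, " in '", path,
           "': expected 'onset duration amplitude'")
    if (fields[2] <= 0)
      stop("non-positive duration on line ", i, " in '", path, "'")
    fields
  })
  m <- do.call(rbind, parsed)
  eventSchedule(condition, m[, 1], m[, 2], m[, 3],
                scanDuration = scanDuration)
}

#' Write an FSL 3-column event file
#'
#' Inverse of [readEvents()]; the round trip is lossless to 6 decimal places.
#'
#' @param schedule an [EventSchedule-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeEvents <- function(schedule, path) {
  lines <- sprintf("%.6f %.6f %.6f",
                   schedule@onsets, schedule@durations, schedule@amplitudes)
  writeLines(lines, path)
  invisible(path)
}
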