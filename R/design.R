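# Boxcar-convolved task regressor for one schedule, sampled at volume
# acquisition times t = (k-1)*tr. The boxcar is built on a fine grid (dt s),
# convolved with the peak-1 HRF and integrated (multiplied by dt), so a short
# event of duration d approximates d * HRF.
.convolvedRegressor <- function(schedule, nVolumes, tr, hrfName = "double-gamma",
                                dt = 0.1, hrfLength = 32) {
  scanDuration <- nVolumes * tr
  nFine <- ceiling(scanDuration / dt)
  box <- numeric(nFine + 1)
  tFine <- (seq_len(nFine + 1) - 1) * dt
  for (i in seq_along(schedule@onsets)) {
    idx <- tFine >= schedule@onsets[i] &
           tFine < schedule@onsets[i] + schedule@durations[i]
    box[idx] <- box[idx] + schedule@amplitudes[i]
  }
  h <- canonicalHrf(tr = dt, length = hrfLength, name = hrfName)
  conv <- stats::convolve(box, rev(h), type = "open")[seq_len(nFine + 1)] * dt
  acq <- round((seq_len(nVolumes) - 1) * tr / dt) + 1
  conv[acq]
}

#' Build a first-level GLM design matrix
#'
#' Each condition's zero-one boxcar (scaled by event amplitude) is built on a
#' fine time grid, convolved with the chosen canonical HRF, and sampled at
#' volume acquisition times. An explicit intercept column named "constant" is
#' appended; task regressors are not mean-centered.
#'
#' @param schedules named list of [EventSchedule-class] objects, one per
#'   modeled condition. A condition with no events is an error (it would
#'   produce an all-zero regressor).
#' @param nVolumes number of volumes of the series to be modeled.
#' @param tr repetition time (s).
#' @param hrfName "double-gamma" (default) or "boynton", see [canonicalHrf()].
#' @param dt fine-grid resolution for the boxcar convolution (s).
#' @return a [DesignMatrix-class] with one column per condition plus
#'   "constant".
#' @examples
#' v <- generateEventSchedule(10, condition = "visual", scanDuration = 100,
#'                            seed = 2)
#' X <- buildDesignMatrix(list(visual = v), nVolumes = 100, tr = 1)
#' @export
buildDesignMatrix <- function(schedules, nVolumes, tr,
                              hrfName = "double-gamma", dt = 0.1) {
  stopifnot(length(schedules) >= 1, nVolumes >= 1, tr > 0)
  if (is.null(names(schedules)) || any(!nzchar(names(schedules))))
    names(schedules) <- vapply(schedules, function(s) s@condition, "")
  scanDuration <- nVolumes * tr
  cols <- lapply(names(schedules), function(nm) {
    s <- schedules[[nm]]
    if (nEvents(s) == 0)
      stop("condition '", nm, "' has no events: all-zero regressor")
    if (any(s@onsets + s@durations > scanDuration + 1e-9))
      stop("condition '", nm, "' has events beyond the scan end (",
           scanDuration, " s)")
    .convolvedRegressor(s, nVolumes, tr, hrfName, dt)
  })
  values <- cbind(do.call(cbind, cols), 1)
  colnames(values) <- c(names(schedules), "constant")
  new("DesignMatrix", values = values, tr = tr)
}
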