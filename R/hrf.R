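#' Canonical hemodynamic response function
#'
#' Samples an HRF kernel at the repetition time. The default "double-gamma"
#' form is the field-standard canonical HRF: a gamma-density positive lobe
#' peaking near 5 s minus an undershoot gamma (peak delay 6 s, undershoot
#' delay 16 s, dispersions 1 s, undershoot ratio 1/6). The "boynton" variant
#' is the single-gamma response (shape 3, time constant 1.25 s, no
#' undershoot). Both are scaled so the peak value is 1.
#'
#' @param tr sampling interval in seconds (> 0).
#' @param length kernel length in seconds (>= 16).
#' @param name "double-gamma" (default) or "boynton".
#' @param dt optional sampling interval overriding `tr` (used internally to
#'   evaluate the kernel on a fine grid).
#' @return numeric vector of kernel samples at times `seq(0, length, by = tr)`.
#' @examples
#' h <- canonicalHrf(1, 32)
#' which.max(h)  # peak near 5-6 s
#' @export
canonicalHrf <- function(tr, length = 32, name = c("double-gamma", "boynton"),
                         dt = NULL) {
  name <- match.arg(name)
  if (is.null(dt)) dt <- tr
  stopifnot(dt > 0, length >= 16)
  t <- seq(0, length, by = dt)
  h <- switch(name,
    "double-gamma" = {
      # gamma densities with shape a, scale b: peak at (a-1)*b
      peak <- stats::dgamma(t, shape = 6, scale = 1)
      under <- stats::dgamma(t, shape = 16, scale = 1)
      peak - under / 6
    },
    "boynton" = {
      # single gamma, shape n = 3, time constant tau = 1.25 s
      tau <- 1.25; n <- 3
      (t / tau)^(n - 1) * exp(-t / tau) / (tau * factorial(n - 1))
    }
  )
  h / max(h)
}
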