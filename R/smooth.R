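#' Loess smoothing of a measured signal
#'
#' Locally weighted polynomial regression (tricube weights, exact "direct"
#' surface computation) of a signal against time. Used to suppress the
#' shot-to-shot noise of the drop-profile fit before harmonic analysis of
#' the surface tension response.
#'
#' Being a local polynomial fit, the smoother reproduces constants exactly
#' and, for `degree >= 1`, straight lines exactly; a periodic signal is
#' slightly attenuated depending on the span (see [harmonic_decompose()] for
#' how the pipeline compensates that attenuation).
#'
#' @param signal numeric vector to smooth.
#' @param t numeric time vector, same length as `signal`.
#' @param span_fraction fraction of all points in the local window, in
#'   (0, 1]. Must cover at least `degree + 2` points.
#' @param degree local polynomial degree, 0, 1 or 2.
#' @return numeric vector: the smoothed signal, same length as `signal`.
#' @export
#' @examples
#' t <- 0:299
#' y <- sin(2 * pi * 0.01 * t) + rnorm(300, sd = 0.1)
#' ys <- loess_smooth(y, t, span_fraction = 0.1, degree = 2)
loess_smooth <- function(signal, t, span_fraction, degree = 2L) {
  n <- length(signal)
  if (length(t) != n)
    stopf("signal and t must have equal length (got %d and %d)", n, length(t))
  if (!is_number(span_fraction) || span_fraction <= 0 || span_fraction > 1)
    stopf("span_fraction must lie in (0, 1]")
  degree <- as.integer(degree)
  if (!degree %in% 0:2) stopf("degree must be 0, 1 or 2")
  min_pts <- degree + 2L
  if (span_fraction * n < min_pts)
    stopf(
      "local window too small for degree %d: span_fraction %.4g covers %.1f points, need >= %d (minimum span %.4g)",
      degree, span_fraction, span_fraction * n, min_pts, min_pts / n)
  fit <- loess(signal ~ t, data = data.frame(signal = signal, t = t),
               span = span_fraction, degree = degree, family = "gaussian",
               control = loess.control(surface = "direct"))
  as.numeric(predict(fit, newdata = data.frame(t = t)))
}
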