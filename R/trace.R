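#' Oscillating-drop trace
#'
#' Container for one oscillating pendant-drop measurement: drop surface area
#' \eqn{A(t)} and surface tension \eqn{\sigma(t)} sampled at a nominal drop
#' oscillation frequency \eqn{\nu}. This is the raw input of the dilational
#' rheology pipeline; the drop-shape (Young-Laplace) fit that produced the
#' area and tension series is assumed to have been done by the instrument.
#'
#' Invariants enforced: strictly increasing time, positive area and tension,
#' at least three oscillation periods of data and at least four samples per
#' period (so the fundamental is resolvable).
#'
#' @param t numeric vector, time in seconds, strictly increasing.
#' @param area numeric vector, drop surface area in mm^2, positive.
#' @param tension numeric vector, surface tension in mN/m, positive.
#' @param nominal_frequency nominal oscillation frequency in Hz.
#' @param meta named list of free-form condition labels (e.g.
#'   `concentration_mM`, `salt_mM`).
#'
#' @return An object of class `"oscillation_trace"`: a list with elements
#'   `t`, `area`, `tension`, `nominal_frequency`, `meta`.
#' @seealso [dilational_modulus()], [generate_oscillation_trace()],
#'   [read_trace_csv()]
#' @export
#' @examples
#' tr <- generate_oscillation_trace(trace_recipe(modulus = 30 + 10i,
#'   frequency = 0.05, noise_sd = 0))
#' print(tr)
oscillation_trace <- function(t, area, tension, nominal_frequency,
                              meta = list()) {
  t <- as.numeric(t); area <- as.numeric(area); tension <- as.numeric(tension)
  n <- length(t)
  if (length(area) != n || length(tension) != n)
    stopf("t, area and tension must have equal length (got %d, %d, %d)",
          n, length(area), length(tension))
  if (n < 12L) stopf("trace too short: %d samples", n)
  if (anyNA(t) || anyNA(area) || anyNA(tension))
    stopf("trace contains missing values")
  dt <- diff(t)
  if (any(dt <= 0))
    stopf("time must be strictly increasing (first violation at sample %d)",
          which(dt <= 0)[1] + 1L)
  if (any(area <= 0)) stopf("drop area must be positive everywhere")
  if (any(tension <= 0)) stopf("surface tension must be positive everywhere")
  if (!is_number(nominal_frequency) || nominal_frequency <= 0)
    stopf("nominal_frequency must be a positive number")
  duration <- t[n] - t[1]
  if (duration * nominal_frequency < 3)
    stopf("trace must span at least 3 oscillation periods (has %.2f)",
          duration * nominal_frequency)
  fs <- 1 / median(dt)
  if (nominal_frequency > fs / 4)
    stopf(
      "nominal_frequency %.4g Hz needs at least 4 samples per period; sampling rate is %.4g Hz",
      nominal_frequency, fs)
  structure(
    list(t = t, area = area, tension = tension,
         nominal_frequency = nominal_frequency, meta = as.list(meta)),
    class = "oscillation_trace")
}

#' @export
print.oscillation_trace <- function(x, ...) {
  n <- length(x$t)
  cat(sprintf(
    "Oscillating-drop trace: %d samples over %.1f s at nominal %.4g Hz\n",
    n, x$t[n] - x$t[1], x$nominal_frequency))
  cat(sprintf("  area    %.3f-%.3f mm^2 (mean %.3f)\n",
              min(x$area), max(x$area), mean(x$area)))
  cat(sprintf("  tension %.3f-%.3f mN/m\n", min(x$tension), max(x$tension)))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(x$meta), sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.oscillation_trace <- function(x, ...) {
  op <- par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(par(op))
  plot(x$t, x$area, type = "l", xlab = "time (s)", ylab = "area (mm²)", ...)
  plot(x$t, x$tension, type = "l", xlab = "time (s)",
       ylab = "tension (mN/m)", ...)
  invisible(x)
}
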