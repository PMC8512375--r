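#' Complex surface dilational modulus from one oscillating-drop trace
#'
#' Computes the complex dilational viscoelastic modulus
#' \deqn{\varepsilon = \varepsilon_r + i\varepsilon_i = A_0
#'   \frac{\Delta\sigma_1}{\Delta A_1}}
#' where \eqn{A_0} is the mean drop area and \eqn{\Delta\sigma_1},
#' \eqn{\Delta A_1} are the complex first-harmonic (fundamental) Fourier
#' components of the surface tension and drop area variations, obtained by
#' harmonic least-squares regression ([harmonic_decompose()]). The tension
#' signal is Loess-smoothed (gain-compensated, see
#' [harmonic_decompose()]); the imposed area signal is used raw. The phase
#' of the modulus is the tension phase minus the area phase, mapped to
#' (-pi, pi]; positive \eqn{\varepsilon_i} means the tension response lags
#' the area drive (viscous-like), the convention in which both parts of the
#' Lucassen-van den Tempel modulus are non-negative.
#'
#' The second-to-first harmonic amplitude ratio of the tension,
#' `harmonic_ratio`, quantifies the distortion of the response from a pure
#' sinusoid; it is the standard nonlinearity statistic for surfactant layers
#' near and above the CMC, where micellar exchange makes the compression
#' half-cycle asymmetric.
#'
#' Quality handling: if the relative area excitation \eqn{|\Delta A_1|/A_0}
#' is below `excitation_floor` the trace carries no usable drive and an
#' error is raised; if the tension first-harmonic amplitude is below the
#' noise floor (3x the residual standard deviation of the harmonic
#' regression) the modulus is reported as 0 with `quality_flag =
#' "below_noise_floor"`.
#'
#' @param trace an [oscillation_trace()].
#' @param span Loess span for the tension signal, expressed as a fraction of
#'   one oscillation period (default 0.3); internally converted to a
#'   fraction of the number of points and clamped to the minimum window the
#'   polynomial degree requires.
#' @param degree Loess polynomial degree (default 2).
#' @param n_harmonics harmonics estimated for the tension (default 4; the
#'   distortion statistic uses only k = 1, 2). Automatically reduced (with a
#'   warning) if the sampling rate cannot support it.
#' @param smooth logical; Loess-smooth the tension before decomposition.
#' @param compensate logical; compensate the smoother gain (default `TRUE`).
#' @param refine_frequency logical; refine the fundamental within +/-5% of
#'   the nominal frequency by maximising the area first-harmonic amplitude.
#' @param excitation_floor minimum detectable relative area amplitude.
#' @return An object of class `"modulus_point"`: a list with `frequency`
#'   (the analysed fundamental, Hz), `eps_real`, `eps_imag` (mN/m),
#'   `mean_area` (mm^2), `harmonic_ratio`, `eps_se` (propagated standard
#'   error of the complex modulus estimate, mN/m), `rel_area_amplitude`,
#'   `quality_flag` (`"ok"` or `"below_noise_floor"`), `tension_fit`,
#'   `area_fit` (the underlying `"harmonic_fit"` objects) and `meta`.
#' @references Lucassen, J. & van den Tempel, M. (1972). Dynamic measurements
#'   of dilational properties of a liquid interface. Chem. Eng. Sci. 27,
#'   1283-1291.
#' @export
#' @examples
#' tr <- generate_oscillation_trace(trace_recipe(modulus = 30 + 10i,
#'   frequency = 0.05, noise_sd = 0))
#' mp <- dilational_modulus(tr)
#' c(mp$eps_real, mp$eps_imag)
dilational_modulus <- function(trace, span = 0.3, degree = 2L,
                               n_harmonics = 4L, smooth = TRUE,
                               compensate = TRUE, refine_frequency = TRUE,
                               excitation_floor = 1e-4) {
  if (!inherits(trace, "oscillation_trace"))
    stopf("trace must be an oscillation_trace")
  nu0 <- trace$nominal_frequency
  t <- trace$t
  n <- length(t)
  nyquist <- 0.5 / median(diff(t))
  n_h <- as.integer(n_harmonics)
  while (n_h > 2L && n_h * nu0 * 1.05 >= nyquist) n_h <- n_h - 1L
  if (n_h < n_harmonics)
    warnf("n_harmonics reduced from %d to %d: sampling rate supports only %.3g Hz",
          as.integer(n_harmonics), n_h, nyquist)

  # area: raw, imposed signal; refine the realised drive frequency on it
  area_fit <- harmonic_decompose(trace$area, t, nu0, n_harmonics = 1L,
                                 drift = TRUE, refine = refine_frequency)
  nu <- area_fit$fundamental
  # mean drop area from the regression intercept: unlike the arithmetic
  # mean it is unbiased when the trace does not span an integer number of
  # oscillation periods
  A0 <- area_fit$mean
  dA1 <- area_fit$coef_complex[1L]
  rel_amp <- Mod(dA1) / A0
  if (rel_amp < excitation_floor)
    stopf("no excitation: relative area amplitude %.3g is below the detectability floor %.3g",
          rel_amp, excitation_floor)
  if (rel_amp > 0.2)
    stopf("relative area amplitude %.3g exceeds 0.2; outside the small-perturbation regime",
          rel_amp)

  smoother <- NULL
  if (isTRUE(smooth)) {
    # span as fraction of one period -> fraction of all points
    span_frac <- span / (nu * (t[n] - t[1]))
    span_frac <- min(1, max(span_frac, (degree + 2L + 0.5) / n))
    smoother <- list(span_fraction = span_frac, degree = degree)
  }
  tension_fit <- harmonic_decompose(trace$tension, t, nu, n_harmonics = n_h,
                                    drift = TRUE, smoother = smoother,
                                    compensate = compensate, refine = FALSE)
  ds1 <- tension_fit$coef_complex[1L]
  ds2 <- tension_fit$coef_complex[2L]
  noise_floor <- 3 * tension_fit$residual_sd
  eps_se <- A0 / Mod(dA1) * sqrt(2) * tension_fit$coef_se[1L]

  if (Mod(ds1) < noise_floor) {
    eps <- complex(real = 0, imaginary = 0)
    flag <- "below_noise_floor"
    ratio <- NA_real_
  } else {
    eps <- A0 * ds1 / dA1
    flag <- "ok"
    ratio <- Mod(ds2) / Mod(ds1)
  }

  structure(list(
    frequency = nu,
    eps_real = Re(eps),
    eps_imag = Im(eps),
    mean_area = A0,
    harmonic_ratio = ratio,
    eps_se = eps_se,
    rel_area_amplitude = rel_amp,
    quality_flag = flag,
    tension_fit = tension_fit,
    area_fit = area_fit,
    meta = trace$meta), class = "modulus_point")
}

#' @export
print.modulus_point <- function(x, ...) {
  cat(sprintf(
    "Dilational modulus at %.4g Hz: eps = %.3f %+.3fi mN/m (se %.3g), A0 = %.2f mm^2\n",
    x$frequency, x$eps_real, x$eps_imag, x$eps_se, x$mean_area))
  cat(sprintf("  harmonic ratio k2/k1 = %s, quality = %s\n",
              ifelse(is.na(x$harmonic_ratio), "NA",
                     sprintf("%.4f", x$harmonic_ratio)), x$quality_flag))
  invisible(x)
}

#' Assemble a modulus spectrum from analysed traces
#'
#' Bundles [dilational_modulus()] results at several frequencies (one
#' concentration/condition) into a frequency-sorted spectrum, the input of
#' [fit_lvdt()].
#'
#' @param points a list of `"modulus_point"` objects, or a data.frame with
#'   at least columns `frequency` and `eps_real` (optionally `eps_imag`).
#' @param meta named list of condition labels shared by all points.
#' @return A data.frame of class `"modulus_spectrum"` with columns
#'   `frequency`, `eps_real`, `eps_imag`, `mean_area`, `harmonic_ratio`,
#'   `eps_se`, `quality_flag`, sorted by strictly increasing frequency, with
#'   the condition labels in `attr(, "meta")`.
#' @export
modulus_spectrum <- function(points, meta = list()) {
  if (is.data.frame(points)) {
    df <- points
    if (!all(c("frequency", "eps_real") %in% names(df)))
      stopf("data.frame spectrum needs columns 'frequency' and 'eps_real'")
    if (is.null(df$eps_imag)) df$eps_imag <- NA_real_
    if (is.null(df$mean_area)) df$mean_area <- NA_real_
    if (is.null(df$harmonic_ratio)) df$harmonic_ratio <- NA_real_
    if (is.null(df$eps_se)) df$eps_se <- NA_real_
    if (is.null(df$quality_flag)) df$quality_flag <- "ok"
  } else {
    if (!length(points) || !all(vapply(points, inherits, TRUE, "modulus_point")))
      stopf("points must be modulus_point objects or a data.frame")
    df <- do.call(rbind, lapply(points, function(p)
      data.frame(frequency = p$frequency, eps_real = p$eps_real,
                 eps_imag = p$eps_imag, mean_area = p$mean_area,
                 harmonic_ratio = p$harmonic_ratio, eps_se = p$eps_se,
                 quality_flag = p$quality_flag)))
    if (!length(meta)) meta <- points[[1L]]$meta
  }
  df <- df[order(df$frequency), , drop = FALSE]
  if (any(diff(df$frequency) <= 0))
    stopf("spectrum frequencies must be strictly increasing (duplicate frequency present)")
  rownames(df) <- NULL
  structure(df, meta = as.list(meta),
            class = c("modulus_spectrum", "data.frame"))
}

#' @export
plot.modulus_spectrum <- function(x, ...) {
  plot(x$frequency, x$eps_real, log = "x", pch = 16,
       xlab = "frequency (Hz)", ylab = "modulus (mN/m)",
       ylim = range(0, x$eps_real, x$eps_imag, na.rm = TRUE), ...)
  if (any(is.finite(x$eps_imag)))
    points(x$frequency, x$eps_imag, pch = 1)
  legend("topleft", pch = c(16, 1), bty = "n",
         legend = c(expression(epsilon[r]), expression(epsilon[i])))
  invisible(x)
}

#' Analyse a batch of traces into a modulus table
#'
#' Runs [dilational_modulus()] on each trace and collects the results in a
#' flat table, carrying the per-trace condition labels
#' (`concentration_mM`, `salt_mM`) from the trace metadata.
#'
#' @param traces list of [oscillation_trace()] objects.
#' @inheritParams dilational_modulus
#' @return data.frame with columns `concentration_mM`, `frequency_hz`,
#'   `eps_real_mN_m`, `eps_imag_mN_m`, `harmonic_ratio`, `eps_se_mN_m`,
#'   `mean_area_mm2`, `quality_flag`.
#' @export
analyze_traces <- function(traces, span = 0.3, degree = 2L, n_harmonics = 4L,
                           smooth = TRUE, compensate = TRUE,
                           refine_frequency = TRUE) {
  if (inherits(traces, "oscillation_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    mp <- dilational_modulus(tr, span = span, degree = degree,
                             n_harmonics = n_harmonics, smooth = smooth,
                             compensate = compensate,
                             refine_frequency = refine_frequency)
    data.frame(
      concentration_mM = as.numeric(tr$meta$concentration_mM %||% NA_real_),
      frequency_hz = mp$frequency,
      eps_real_mN_m = mp$eps_real,
      eps_imag_mN_m = mp$eps_imag,
      harmonic_ratio = mp$harmonic_ratio,
      eps_se_mN_m = mp$eps_se,
      mean_area_mm2 = mp$mean_area,
      quality_flag = mp$quality_flag)
  })
  do.call(rbind, rows)
}

#' Harmonic-distortion ratio across measurement conditions
#'
#' The second-to-first harmonic amplitude ratio of the surface tension
#' response, \eqn{|F(\Delta\sigma)_2| / |F(\Delta\sigma)_1|}, per trace,
#' with condition labels preserved. A strictly linear surface response gives
#' a ratio of zero up to the noise floor; the onset and growth of the ratio
#' with surfactant concentration marks the nonlinear regime associated with
#' micellisation.
#'
#' @inheritParams analyze_traces
#' @return data.frame with columns `concentration_mM`, `frequency_hz`,
#'   `harmonic_ratio`, `quality_flag`.
#' @export
harmonic_ratio_curve <- function(traces, span = 0.3, degree = 2L,
                                 smooth = TRUE, compensate = TRUE,
                                 refine_frequency = TRUE) {
  tab <- analyze_traces(traces, span = span, degree = degree,
                        n_harmonics = 4L, smooth = smooth,
                        compensate = compensate,
                        refine_frequency = refine_frequency)
  tab[, c("concentration_mM", "frequency_hz", "harmonic_ratio",
          "quality_flag")]
}
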