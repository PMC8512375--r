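#' Lucassen-van den Tempel diffusional viscoelastic modulus
#'
#' Evaluates the diffusion-controlled exchange model for the complex surface
#' dilational modulus of a soluble surfactant layer,
#' \deqn{\varepsilon(\nu) = \varepsilon_0 \frac{1 + \xi + i\xi}
#'   {1 + 2\xi + 2\xi^2}, \qquad \xi = \sqrt{\nu_D / (2\nu)},}
#' where \eqn{\varepsilon_0} is the Gibbs elasticity (the insoluble-layer,
#' high-frequency limit) and \eqn{\nu_D} the characteristic frequency of
#' diffusional exchange between bulk and interface. Both the real (storage)
#' and imaginary (loss) parts are non-negative; \eqn{\varepsilon_r \to
#' \varepsilon_0} and \eqn{\varepsilon_i \to 0} as \eqn{\nu \to \infty},
#' and both vanish as \eqn{\nu \to 0}.
#'
#' @param eps0 Gibbs elasticity \eqn{\varepsilon_0} in mN/m (>= 0).
#' @param nu_d diffusional characteristic frequency \eqn{\nu_D} in Hz (>= 0).
#' @param frequency oscillation frequency(ies) \eqn{\nu} in Hz, > 0;
#'   vectorised.
#' @return complex vector \eqn{\varepsilon_r + i\varepsilon_i} in mN/m.
#' @references Lucassen, J. & van den Tempel, M. (1972). Chem. Eng. Sci. 27,
#'   1283-1291.
#' @export
#' @examples
#' lvdt_modulus(30.1, 0.0032, frequency = c(0.01, 0.1))
#' # xi = 1 when nu = nu_d / 2: eps = eps0 * (2 + 1i) / 5
#' lvdt_modulus(10, 0.2, frequency = 0.1)
lvdt_modulus <- function(eps0, nu_d, frequency) {
  if (!is_number(eps0) || eps0 < 0) stopf("eps0 must be a non-negative number")
  if (!is_number(nu_d) || nu_d < 0) stopf("nu_d must be a non-negative number")
  if (!is.numeric(frequency) || any(!is.finite(frequency)) ||
      any(frequency <= 0))
    stopf("frequency must be positive and finite")
  xi <- sqrt(nu_d / (2 * frequency))
  eps0 * complex(real = 1 + xi, imaginary = xi) / (1 + 2 * xi + 2 * xi^2)
}

# residuals of the model against a spectrum, stacked [real; imag] for the
# complex fit
lvdt_residuals_fun <- function(freq, y_re, y_im, part, w) {
  function(p) {
    eps <- lvdt_modulus(p[1L], p[2L], freq)
    r <- Re(eps) - y_re
    if (part == "complex") r <- c(r, Im(eps) - y_im)
    r * sqrt(w)
  }
}

#' Fit the Lucassen-van den Tempel model to a modulus spectrum
#'
#' Bounded least-squares estimation of the Gibbs elasticity
#' \eqn{\varepsilon_0} and the diffusional characteristic frequency
#' \eqn{\nu_D} from measured dilational moduli over a frequency sweep
#' (Levenberg-Marquardt, multi-start from a log-spaced grid to avoid local
#' minima). By default only the real (storage) part is fitted: for
#' multicomponent surfactant layers the loss part is well described by the
#' single-surfactant diffusional model only at low frequency and low
#' concentration, so the real part is the robust fitting target;
#' `part = "complex"` fits both parts jointly as an extension.
#'
#' @param spectrum a [modulus_spectrum()], or a data.frame with columns
#'   `frequency` and `eps_real` (plus `eps_imag` for `part = "complex"`).
#'   Points flagged other than `"ok"` are dropped with a message.
#' @param part `"real"` (default) or `"complex"`.
#' @param weights optional per-point weights (recycled over the stacked
#'   residual vector for the complex fit); default unweighted.
#' @param starts data.frame of starting values with columns `eps0`, `nu_d`;
#'   default the grid eps0 in \{5, 20, 80\} mN/m x nu_d in \{1e-4, 1e-2, 1\} Hz.
#' @param lower,upper parameter bounds `c(eps0, nu_d)`; defaults
#'   `c(1e-8, 0)` and `c(500, 10)`.
#' @return An object of class `"lvdt_fit"`: list with `coefficients`
#'   (named `eps0`, `nu_d`), `se`, `vcov`, `residual_rms` (mN/m), `sigma`,
#'   `n_points`, `converged`, `part`, `data`, `fitted`, `residuals`.
#' @seealso [lvdt_modulus()], [predict.lvdt_fit()]
#' @export
#' @examples
#' freq <- exp(seq(log(0.005), log(0.2), length.out = 15))
#' sp <- data.frame(frequency = freq,
#'                  eps_real = Re(lvdt_modulus(30.1, 0.0032, freq)))
#' fit <- fit_lvdt(sp)
#' coef(fit)
fit_lvdt <- function(spectrum, part = c("real", "complex"), weights = NULL,
                     starts = NULL, lower = c(1e-8, 0), upper = c(500, 10)) {
  part <- match.arg(part)
  df <- as.data.frame(spectrum)
  if (!all(c("frequency", "eps_real") %in% names(df)))
    stopf("spectrum needs columns 'frequency' and 'eps_real'")
  if (!is.null(df$quality_flag) && any(df$quality_flag != "ok")) {
    message(sum(df$quality_flag != "ok"),
            " point(s) with non-'ok' quality flag dropped from the fit")
    df <- df[df$quality_flag == "ok", , drop = FALSE]
  }
  if (part == "complex" && is.null(df$eps_imag))
    stopf("complex fit needs an 'eps_imag' column")
  if (length(unique(df$frequency)) < 3L)
    stopf("need at least 3 distinct frequencies to fit two parameters, got %d",
          length(unique(df$frequency)))
  n <- nrow(df)
  w <- weights %||% rep(1, n)
  if (length(w) != n) stopf("weights must have one value per spectrum point")
  resid_fun <- lvdt_residuals_fun(df$frequency, df$eps_real,
                                  df$eps_imag %||% rep(NA_real_, n), part,
                                  w)
  if (is.null(starts))
    starts <- expand.grid(eps0 = c(5, 20, 80), nu_d = c(1e-4, 1e-2, 1))

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                     maxiter = 1000)
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(c(starts$eps0[i], starts$nu_d[i]), lower), upper)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fun, lower = lower,
                         upper = upper, control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    cand <- list(par = fit$par, ssr = ssr, ok = fit$info %in% 1:4,
                 info = fit$info)
    if (is.null(best) || (cand$ok && !best$ok) ||
        (cand$ok == best$ok && ssr < best$ssr)) best <- cand
  }
  if (is.null(best))
    stopf("all optimisation starts failed; no converged LvdT fit")

  p <- setNames(best$par, c("eps0", "nu_d"))
  r <- resid_fun(p)
  m <- length(r)
  sigma <- sqrt(best$ssr / max(m - 2L, 1L))
  # linearised covariance from the numeric Jacobian at the optimum
  J <- numeric_jacobian(resid_fun, p)
  vc <- tryCatch(sigma^2 * chol2inv(chol(crossprod(J))),
                 error = function(e) matrix(NA_real_, 2, 2))
  dimnames(vc) <- list(names(p), names(p))
  se <- sqrt(pmax(diag(vc), 0))

  eps_fit <- lvdt_modulus(p[["eps0"]], p[["nu_d"]], df$frequency)
  structure(list(
    coefficients = p,
    se = se,
    vcov = vc,
    residual_rms = sqrt(mean(r^2)),
    sigma = sigma,
    n_points = n,
    converged = best$ok,
    optim_info = best$info,
    part = part,
    data = df,
    fitted = eps_fit,
    residuals = r,
    meta = attr(spectrum, "meta") %||% list()),
    class = "lvdt_fit")
}

numeric_jacobian <- function(fn, p, rel_h = 1e-6) {
  f0 <- fn(p)
  J <- matrix(NA_real_, length(f0), length(p))
  for (j in seq_along(p)) {
    h <- rel_h * max(abs(p[j]), 1e-8)
    pp <- p; pm <- p
    pp[j] <- p[j] + h; pm[j] <- max(p[j] - h, 0)
    J[, j] <- (fn(pp) - fn(pm)) / (pp[j] - pm[j])
  }
  J
}

#' @export
print.lvdt_fit <- function(x, ...) {
  cat(sprintf(
    "Lucassen-van den Tempel fit (%s part, %d frequencies)\n",
    x$part, x$n_points))
  cat(sprintf("  Gibbs elasticity eps0 = %.4g mN/m (se %.3g)\n",
              x$coefficients[["eps0"]], x$se[["eps0"]]))
  cat(sprintf("  diffusional frequency nu_D = %.4g Hz (se %.3g)\n",
              x$coefficients[["nu_d"]], x$se[["nu_d"]]))
  cat(sprintf("  residual rms %.4g mN/m, converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' @export
summary.lvdt_fit <- function(object, ...) {
  tab <- data.frame(
    estimate = object$coefficients,
    std_error = object$se,
    row.names = c("eps0 (mN/m)", "nu_D (Hz)"))
  out <- list(coefficients = tab, residual_rms = object$residual_rms,
              sigma = object$sigma, n_points = object$n_points,
              part = object$part, converged = object$converged)
  class(out) <- "summary.lvdt_fit"
  out
}

#' @export
print.summary.lvdt_fit <- function(x, ...) {
  cat(sprintf("LvdT diffusional model, %s-part fit, n = %d\n",
              x$part, x$n_points))
  print(x$coefficients)
  cat(sprintf("residual rms: %.4g mN/m; residual sd: %.4g mN/m; converged: %s\n",
              x$residual_rms, x$sigma, x$converged))
  invisible(x)
}

#' @export
coef.lvdt_fit <- function(object, ...) object$coefficients

#' @export
vcov.lvdt_fit <- function(object, ...) object$vcov

#' @export
residuals.lvdt_fit <- function(object, ...) object$residuals

#' Predict LvdT moduli from a fitted model
#'
#' @param object an `"lvdt_fit"`.
#' @param frequency frequencies (Hz) at which to evaluate; defaults to the
#'   fitted data's frequencies.
#' @param ... unused.
#' @return data.frame with `frequency`, `eps_real`, `eps_imag`.
#' @export
predict.lvdt_fit <- function(object, frequency = NULL, ...) {
  frequency <- frequency %||% object$data$frequency
  eps <- lvdt_modulus(object$coefficients[["eps0"]],
                      object$coefficients[["nu_d"]], frequency)
  data.frame(frequency = frequency, eps_real = Re(eps), eps_imag = Im(eps))
}

#' @export
plot.lvdt_fit <- function(x, ...) {
  df <- x$data
  fr <- exp(seq(log(min(df$frequency)), log(max(df$frequency)),
                length.out = 200))
  pr <- predict(x, fr)
  plot(df$frequency, df$eps_real, log = "x", pch = 16,
       xlab = "frequency (Hz)", ylab = "modulus (mN/m)",
       ylim = range(0, df$eps_real, df$eps_imag, pr$eps_real, na.rm = TRUE),
       ...)
  lines(fr, pr$eps_real)
  if (x$part == "complex" || any(is.finite(df$eps_imag))) {
    points(df$frequency, df$eps_imag, pch = 1)
    lines(fr, pr$eps_imag, lty = 2)
  }
  invisible(x)
}
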