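# free-parameter plumbing for fit_isotherm: parameters are addressed as
# "b.<name>", "omega.<name>", "a.<name1>.<name2>", or "f"; positive
# quantities are optimised on the log scale, f on the logit scale.

iso_get_param <- function(system, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
  nm <- vapply(system$components, `[[`, "", "name")
  switch(parts[1L],
    f = system$minority_fraction,
    b = system$components[[match(parts[2L], nm)]]$b,
    omega = system$components[[match(parts[2L], nm)]]$omega,
    a = system$interaction[match(parts[2L], nm), match(parts[3L], nm)],
    stopf("unknown free parameter '%s'", id))
}

iso_set_param <- function(system, id, value) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
  nm <- vapply(system$components, `[[`, "", "name")
  if (parts[1L] == "f") {
    system$minority_fraction <- value
  } else if (parts[1L] %in% c("b", "omega")) {
    i <- match(parts[2L], nm)
    if (is.na(i)) stopf("unknown component '%s' in '%s'", parts[2L], id)
    system$components[[i]][[parts[1L]]] <- value
  } else if (parts[1L] == "a") {
    i <- match(parts[2L], nm); j <- match(parts[3L], nm)
    if (is.na(i) || is.na(j)) stopf("unknown component in '%s'", id)
    system$interaction[i, j] <- system$interaction[j, i] <- value
  } else stopf("unknown free parameter '%s'", id)
  system
}

iso_transform <- function(id, value) {
  kind <- strsplit(id, ".", fixed = TRUE)[[1L]][1L]
  switch(kind,
         b = log(value), omega = log(value),
         f = log(value / (1 - value)),
         value)
}

iso_untransform <- function(id, value) {
  kind <- strsplit(id, ".", fixed = TRUE)[[1L]][1L]
  switch(kind,
         b = exp(value), omega = exp(value),
         f = 1 / (1 + exp(-value)),
         value)
}

#' Fit the mixture adsorption model to a surface tension isotherm
#'
#' Least-squares estimation of selected parameters of a
#' [mixture_system()] against measured (concentration, surface tension)
#' pairs. Surface-activity constants and molar areas are optimised on the
#' log scale (guaranteeing positivity), the minority fraction on the logit
#' scale; a small multi-start over scaled starting values protects against
#' local minima (Levenberg-Marquardt refinement at each start).
#'
#' With an empty `free` list, the template is returned unchanged with
#' residuals only (evaluation mode). If the configuration is
#' under-determined (as many or more free parameters than data points, or a
#' badly conditioned Jacobian), a warning reports the covariance condition
#' number.
#'
#' @param data an [isotherm_dataset()] or data.frame with columns `conc`
#'   (mol/dm^3) and `tension` (mN/m).
#' @param system template [mixture_system()]; fixed parameters are taken
#'   from it.
#' @param free character vector of free parameters: `"b.<name>"`,
#'   `"omega.<name>"`, `"a.<name1>.<name2>"`, `"f"`.
#' @param start_scales multiplicative perturbations of the template values
#'   used as optimisation starts (applied on the transformed scale as
#'   offsets for log-parameters).
#' @return object of class `"isotherm_fit"`: list with `system` (fitted),
#'   `coefficients` (named free-parameter estimates), `se`, `vcov`,
#'   `residuals`, `residual_rms`, `fitted`, `data`, `free`, `converged`,
#'   `condition_number`.
#' @export
#' @examples
#' sys <- mixture_system(surfactant_component("C12", 0, b = 50, omega = 2.5e5))
#' d <- generate_isotherm_dataset(sys,
#'   concentrations = 10^seq(-5, -2.5, length.out = 12), noise_sd = 0)
#' f <- fit_isotherm(d, sys, free = "b.C12")
#' coef(f)
fit_isotherm <- function(data, system, free = character(),
                         start_scales = c(0.3, 1, 3)) {
  df <- as.data.frame(data)
  if (!all(c("conc", "tension") %in% names(df)))
    stopf("data needs columns 'conc' and 'tension'")
  n <- nrow(df)
  model_sigma <- function(sys) surface_tension(sys, df$conc)

  if (!length(free)) {
    fitted_vals <- model_sigma(system)
    r <- df$tension - fitted_vals
    return(structure(list(
      system = system, coefficients = numeric(0), se = numeric(0),
      vcov = matrix(numeric(0), 0, 0), residuals = r,
      residual_rms = sqrt(mean(r^2)), fitted = fitted_vals, data = df,
      free = free, converged = TRUE, condition_number = NA_real_),
      class = "isotherm_fit"))
  }
  if (n < 5L)
    stopf("need at least 5 data points to fit, got %d", n)
  if (length(free) >= n)
    warnf("under-determined fit: %d free parameters for %d points",
          length(free), n)

  p0 <- vapply(free, function(id)
    iso_transform(id, iso_get_param(system, id)), numeric(1))
  # a freed minority fraction starting from exactly 0 has no finite logit
  p0[!is.finite(p0)] <- log(1e-3 / (1 - 1e-3))
  apply_par <- function(p) {
    sys <- system
    for (k in seq_along(free))
      sys <- iso_set_param(sys, free[k], iso_untransform(free[k], p[k]))
    sys
  }
  resid_fun <- function(p) {
    sig <- tryCatch(model_sigma(apply_par(p)), error = function(e) NULL)
    if (is.null(sig)) return(rep(1e6, n))
    sig - df$tension
  }

  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-14, ptol = 1e-14,
                                     maxiter = 500)
  best <- NULL
  for (s in start_scales) {
    ps <- p0 + log(s)   # shift log-parameters; a/f starts stay near template
    is_log <- grepl("^(b|omega)\\.", free)
    ps[!is_log] <- p0[!is_log]
    fit <- tryCatch(minpack.lm::nls.lm(par = ps, fn = resid_fun,
                                       control = ctrl),
                    error = function(e) NULL)
    if (is.null(fit)) next
    ssr <- sum(fit$fvec^2)
    ok <- fit$info %in% 1:4
    if (is.null(best) || (ok && !best$ok) ||
        (ok == best$ok && ssr < best$ssr))
      best <- list(par = fit$par, ssr = ssr, ok = ok)
  }
  if (is.null(best)) stopf("all isotherm fit starts failed")

  p <- best$par
  sys_fit <- apply_par(p)
  fitted_vals <- model_sigma(sys_fit)
  r <- df$tension - fitted_vals
  sigma2 <- best$ssr / max(n - length(free), 1L)
  J <- numeric_jacobian(resid_fun, p)
  JtJ <- crossprod(J)
  cond_num <- tryCatch(kappa(JtJ, exact = TRUE), error = function(e) Inf)
  if (!is.finite(cond_num) || cond_num > 1e10)
    warnf("ill-conditioned fit: covariance condition number %.3g", cond_num)
  vc_t <- tryCatch(sigma2 * chol2inv(chol(JtJ)),
                   error = function(e) matrix(NA_real_, length(p), length(p)))
  # delta method back to the natural scale
  est <- vapply(seq_along(free), function(k)
    iso_untransform(free[k], p[k]), numeric(1))
  grad <- vapply(seq_along(free), function(k) {
    kind <- strsplit(free[k], ".", fixed = TRUE)[[1L]][1L]
    switch(kind, b = est[k], omega = est[k],
           f = est[k] * (1 - est[k]), 1)
  }, numeric(1))
  vc <- vc_t * tcrossprod(grad)
  dimnames(vc) <- list(free, free)

  structure(list(
    system = sys_fit, coefficients = setNames(est, free),
    se = setNames(sqrt(pmax(diag(vc), 0)), free), vcov = vc,
    residuals = r, residual_rms = sqrt(mean(r^2)), fitted = fitted_vals,
    data = df, free = free, converged = best$ok,
    condition_number = cond_num), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat(sprintf("Mixture adsorption isotherm fit (%d points, %d free parameter%s)\n",
              nrow(x$data), length(x$free),
              if (length(x$free) == 1L) "" else "s"))
  if (length(x$coefficients)) {
    for (k in seq_along(x$coefficients))
      cat(sprintf("  %-14s %.5g (se %.3g)\n", names(x$coefficients)[k],
                  x$coefficients[k], x$se[k]))
  } else cat("  evaluation mode (no free parameters)\n")
  cat(sprintf("  residual rms %.4g mN/m, converged: %s\n",
              x$residual_rms, x$converged))
  invisible(x)
}

#' @export
coef.isotherm_fit <- function(object, ...) object$coefficients

#' @export
vcov.isotherm_fit <- function(object, ...) object$vcov

#' @export
residuals.isotherm_fit <- function(object, ...) object$residuals

#' @export
fitted.isotherm_fit <- function(object, ...) object$fitted

#' Predict surface tension from a fitted mixture model
#'
#' @param object an `"isotherm_fit"`.
#' @param conc concentrations (mol/dm^3); defaults to 50 log-spaced points
#'   spanning the fitted data.
#' @param ... unused.
#' @return data.frame with `conc` and `tension`.
#' @export
predict.isotherm_fit <- function(object, conc = NULL, ...) {
  conc <- conc %||% 10^seq(log10(min(object$data$conc)),
                           log10(max(object$data$conc)), length.out = 50)
  data.frame(conc = conc, tension = surface_tension(object$system, conc))
}

#' @export
plot.isotherm_fit <- function(x, ...) {
  plot(x$data$conc, x$data$tension, log = "x", pch = 16,
       xlab = "concentration (mol/dm³)", ylab = "surface tension (mN/m)",
       ...)
  pr <- predict(x)
  lines(pr$conc, pr$tension)
  invisible(x)
}

#' @export
summary.isotherm_fit <- function(object, ...) {
  print(object)
  invisible(object)
}
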