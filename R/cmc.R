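#' Detect the critical micelle concentration from an isotherm
#'
#' Classical two-line breakpoint analysis of \eqn{\sigma} versus
#' \eqn{\log_{10} c}: straight lines are fitted to the points below and
#' above every admissible split (at least 4 points on each side), the split
#' minimising the total squared residual is selected, and the CMC is the
#' abscissa of the intersection of the two lines (with the tension at CMC
#' its ordinate). Above the CMC the tension of a micellising surfactant is
#' essentially flat, so the second branch typically has near-zero slope.
#'
#' @param data an [isotherm_dataset()] or data.frame with columns `conc`
#'   (mol/dm^3, strictly increasing) and `tension` (mN/m). Must span the
#'   slope break with at least 4 points on each side (>= 8 points total).
#' @return object of class `"cmc_estimate"`: list with `cmc` (mol/dm^3),
#'   `tension_at_cmc` (mN/m), `split` (index of the last point on the lower
#'   branch), `slopes` (mN/m per decade, lower and upper branch), `sse`.
#' @export
#' @examples
#' conc <- 10^seq(-4.2, -2.5, length.out = 16)
#' tension <- ifelse(conc < 1e-3,
#'   25 - 18 * (log10(conc) - log10(1e-3)), 25)
#' detect_cmc(isotherm_dataset(conc, tension))
detect_cmc <- function(data) {
  df <- as.data.frame(data)
  if (!all(c("conc", "tension") %in% names(df)))
    stopf("data needs columns 'conc' and 'tension'")
  n <- nrow(df)
  if (n < 8L)
    stopf("breakpoint detection needs >= 8 points (4 on each side), got %d", n)
  if (any(diff(df$conc) <= 0))
    stopf("concentrations must be strictly increasing")
  x <- log10(df$conc); y <- df$tension

  line_fit <- function(idx) {
    cf <- unname(stats::lm.fit(cbind(1, x[idx]), y[idx])$coefficients)
    res <- y[idx] - (cf[1L] + cf[2L] * x[idx])
    list(intercept = cf[1L], slope = cf[2L], sse = sum(res^2))
  }
  best <- NULL
  for (k in 4:(n - 4L)) {
    lo <- line_fit(1:k); hi <- line_fit((k + 1L):n)
    sse <- lo$sse + hi$sse
    if (is.null(best) || sse < best$sse)
      best <- list(k = k, lo = lo, hi = hi, sse = sse)
  }
  dslope <- best$lo$slope - best$hi$slope
  scale <- max(abs(c(best$lo$slope, best$hi$slope, 1)))
  if (abs(dslope) < 1e-9 * scale)
    stopf("no admissible split: the two branches have equal slopes (monotone-slope data, no CMC in range)")
  x_star <- (best$hi$intercept - best$lo$intercept) / dslope
  structure(list(
    cmc = 10^x_star,
    tension_at_cmc = best$lo$intercept + best$lo$slope * x_star,
    split = best$k,
    slopes = c(lower = best$lo$slope, upper = best$hi$slope),
    sse = best$sse), class = "cmc_estimate")
}

#' @export
print.cmc_estimate <- function(x, ...) {
  cat(sprintf(
    "CMC estimate: %.4g mol/dm^3 (%.3g mM), sigma(CMC) = %.2f mN/m\n",
    x$cmc, 1000 * x$cmc, x$tension_at_cmc))
  cat(sprintf("  branch slopes %.2f / %.2f mN/m per decade, SSE %.4g\n",
              x$slopes[1L], x$slopes[2L], x$sse))
  invisible(x)
}
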