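# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Map an angle to the interval (-pi, pi]
#' @noRd
wrap_phase <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # %% puts -pi at -pi; convention here is (-pi, pi]
  y[y <= -pi] <- pi
  y
}

# Evaluate expr with a temporary RNG state; leaves the caller's RNG untouched.
# seed = NULL means: use (and advance) the global RNG as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stopf("seed must be a single finite number, got %s", format(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# locale-independent numeric formatting for CSV output (15 significant digits
# keeps round trips stable to >= 12 digits)
fmt_num <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("NA")
    formatC(v, digits = 15, format = "g")
  }, character(1))
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# physical constants (SI)
.const <- list(
  F  = 96485.33212,    # Faraday, C/mol
  R  = 8.31446262,     # gas constant, J/(mol K)
  e0 = 8.8541878128e-12, # vacuum permittivity, F/m
  eps_w = 78.5         # relative permittivity of water near 295 K
)
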