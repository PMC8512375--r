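test_that("an exact sinusoid is decomposed to machine precision", {
  t <- seq(0, 200, by = 1)
  y <- 5 + 2 * sin(2 * pi * 0.05 * t)
  h <- harmonic_decompose(y, t, fundamental = 0.05, n_harmonics = 2)
  expect_equal(h$mean, 5, tolerance = 1e-9)
  expect_equal(h$harmonics$amplitude[1], 2, tolerance = 1e-9)
  expect_lt(h$harmonics$amplitude[2], 1e-9)
})

test_that("constructed harmonic mixtures give the constructed amplitude ratio", {
  nu <- 0.04
  t <- seq(0, 8 / nu, by = 0.5)
  y <- sin(2 * pi * nu * t) + 0.2 * sin(4 * pi * nu * t)
  h <- harmonic_decompose(y, t, nu, n_harmonics = 3)
  expect_equal(h$harmonics$amplitude[2] / h$harmonics$amplitude[1], 0.2,
               tolerance = 1e-9)
  expect_lt(h$harmonics$amplitude[3], 1e-9)
})

test_that("amplitudes are invariant to the time origin; phase differences are preserved", {
  nu <- 0.05
  mk <- function(t0) {
    t <- seq(t0, t0 + 160, by = 0.8)
    y <- 3 * sin(2 * pi * nu * t + 0.4) + 0.6 * cos(4 * pi * nu * t - 1.1)
    harmonic_decompose(y, t, nu, n_harmonics = 2)
  }
  h0 <- mk(0); h1 <- mk(137.3)
  expect_equal(h0$harmonics$amplitude, h1$harmonics$amplitude,
               tolerance = 1e-9)
  # phase of each harmonic in absolute time is identical for the same signal
  expect_equal(h0$harmonics$phase, h1$harmonics$phase, tolerance = 1e-7)
})

test_that("regression amplitudes match dense trapezoidal Fourier integration for a clipped sinusoid", {
  nu <- 0.05; period <- 1 / nu
  wave <- function(tt) pmin(sin(2 * pi * nu * tt), 0.8)
  # 10 periods, densely sampled so that aliasing of the kink's high
  # harmonics is far below the comparison tolerance
  t <- seq(0, 10 * period - period / 2000, by = period / 2000)
  h <- harmonic_decompose(wave(t), t, nu, n_harmonics = 2, drift = FALSE)
  a1 <- trapezoid_harmonic_amplitude(wave, period, 1)
  a2 <- trapezoid_harmonic_amplitude(wave, period, 2)
  expect_equal(h$harmonics$amplitude[1], a1, tolerance = 1e-6)
  expect_equal(h$harmonics$amplitude[2], a2, tolerance = 1e-6)
})

test_that("short traces and unresolvable frequencies are rejected", {
  t <- seq(0, 40, by = 1)
  y <- sin(2 * pi * 0.05 * t)
  expect_error(harmonic_decompose(y, t, 0.05), "3 fundamental periods")
  t2 <- seq(0, 300, by = 1)
  expect_error(harmonic_decompose(sin(2 * pi * 0.7 * t2), t2, 0.7),
               "Nyquist")
  expect_error(harmonic_decompose(sin(2 * pi * 0.2 * t2), t2, 0.2,
                                  n_harmonics = 4), "Nyquist")
})

test_that("gain-compensated smoothing leaves noiseless harmonic amplitudes unbiased", {
  nu <- 0.05
  t <- seq(0, 200, by = 1)
  y <- 40 + 3 * sin(2 * pi * nu * t + 0.7) + 0.9 * sin(4 * pi * nu * t)
  sm <- list(span_fraction = 0.15, degree = 2)
  h <- harmonic_decompose(y, t, nu, n_harmonics = 2, smoother = sm)
  expect_equal(h$harmonics$amplitude, c(3, 0.9), tolerance = 1e-9)
  # the naive decomposition of the smoothed signal is attenuated
  h0 <- harmonic_decompose(y, t, nu, n_harmonics = 2, smoother = sm,
                           compensate = FALSE)
  expect_lt(h0$harmonics$amplitude[2], 0.9 - 1e-4)
})

test_that("frequency refinement recovers a jittered fundamental from noisy data", {
  nu_true <- 0.052
  t <- seq(0, 250, by = 1)
  set.seed(3)
  y <- 2 * sin(2 * pi * nu_true * t + 0.3) + rnorm(length(t), sd = 0.05)
  h <- harmonic_decompose(y, t, fundamental = 0.05, refine = TRUE,
                          n_harmonics = 2)
  expect_equal(h$fundamental, nu_true, tolerance = 1e-3)
  expect_equal(h$harmonics$amplitude[1], 2, tolerance = 0.02)
})
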