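elastic_trace <- function(E = 50, nu = 0.05, a = 0.1, A0 = 24,
                          phase_lag = 0) {
  t <- seq(0, 10 / nu, by = 1 / (20 * nu))
  area <- A0 * (1 + a * sin(2 * pi * nu * t))
  tension <- 45 + E * a * sin(2 * pi * nu * t + phase_lag)
  oscillation_trace(t, area, tension, nu)
}

test_that("a purely elastic in-phase response gives a real modulus", {
  mp <- dilational_modulus(elastic_trace(E = 50))
  expect_equal(mp$eps_real, 50, tolerance = 1e-9)
  expect_equal(mp$eps_imag, 0, tolerance = 1e-9)
  expect_equal(mp$mean_area, 24, tolerance = 1e-6)
  expect_identical(mp$quality_flag, "ok")
})

test_that("a quarter-period lag gives a purely imaginary modulus", {
  # tension = a_t sin(wt + pi/2): modulus phase +pi/2, eps = i * A0 a_t/|dA1|
  mp <- dilational_modulus(elastic_trace(E = 30, phase_lag = pi / 2))
  expect_equal(mp$eps_real, 0, tolerance = 1e-8)
  expect_equal(mp$eps_imag, 30, tolerance = 1e-8)
})

test_that("the analysed modulus round-trips the generator (noiseless) and scales linearly", {
  rec <- trace_recipe(modulus = 30 + 10i, frequency = 0.05, noise_sd = 0)
  mp <- dilational_modulus(generate_oscillation_trace(rec))
  expect_equal(mp$eps_real, 30, tolerance = 1e-9)
  expect_equal(mp$eps_imag, 10, tolerance = 1e-9)
  # scaling the tension oscillation scales |eps|, leaves the ratio alone
  rec2 <- trace_recipe(modulus = 3 * (30 + 10i), frequency = 0.05,
                       noise_sd = 0)
  mp2 <- dilational_modulus(generate_oscillation_trace(rec2))
  expect_equal(c(mp2$eps_real, mp2$eps_imag),
               3 * c(mp$eps_real, mp$eps_imag), tolerance = 1e-9)
})

test_that("noisy traces recover the generating modulus within the propagated uncertainty", {
  rec <- trace_recipe(modulus = 30 + 10i, frequency = 0.05, noise_sd = 0.1,
                      seed = 101)
  mp <- dilational_modulus(generate_oscillation_trace(rec))
  expect_equal(mp$eps_real, 30, tolerance = 0.5 / 30)
  expect_equal(mp$eps_imag, 10, tolerance = 0.5 / 10)
  err <- abs(complex(real = mp$eps_real - 30, imaginary = mp$eps_imag - 10))
  expect_lt(err, 3 * mp$eps_se)
})

test_that("time-origin shifts change neither modulus nor harmonic ratio", {
  beta <- nonlinearity_for_ratio(0.2, 40 + 5i)
  mk <- function(t0) {
    rec <- trace_recipe(modulus = 40 + 5i, frequency = 0.04,
                        nonlinearity = beta, noise_sd = 0)
    tr <- generate_oscillation_trace(rec)
    tr$t <- tr$t + t0
    dilational_modulus(tr)
  }
  m0 <- mk(0); m1 <- mk(987.12)
  expect_equal(m0$eps_real, m1$eps_real, tolerance = 1e-9)
  expect_equal(m0$eps_imag, m1$eps_imag, tolerance = 1e-9)
  expect_equal(m0$harmonic_ratio, m1$harmonic_ratio, tolerance = 1e-9)
})

test_that("harmonic ratio is invariant to a constant tension offset", {
  beta <- nonlinearity_for_ratio(0.15, 25)
  rec <- trace_recipe(modulus = 25 + 0i, frequency = 0.05,
                      nonlinearity = beta, noise_sd = 0)
  tr <- generate_oscillation_trace(rec)
  r0 <- dilational_modulus(tr)$harmonic_ratio
  tr$tension <- tr$tension + 7.5
  r1 <- dilational_modulus(tr)$harmonic_ratio
  expect_equal(r0, r1, tolerance = 1e-9)
})

test_that("a vanishing area drive is reported as missing excitation", {
  tr <- elastic_trace()
  tr$area <- rep(24, length(tr$area)) + 1e-7 * sin(2 * pi * 0.05 * tr$t)
  expect_error(dilational_modulus(tr), "no excitation")
})

test_that("a tension response below the noise floor is flagged, not reported", {
  nu <- 0.05
  t <- seq(0, 10 / nu, by = 1)
  area <- 24 * (1 + 0.1 * sin(2 * pi * nu * t))
  set.seed(5)
  tension <- 45 + rnorm(length(t), sd = 0.1)  # pure noise, no response
  tr <- oscillation_trace(t, area, tension, nu)
  mp <- dilational_modulus(tr)
  expect_identical(mp$quality_flag, "below_noise_floor")
  expect_identical(c(mp$eps_real, mp$eps_imag), c(0, 0))
})

test_that("harmonic_ratio_curve preserves condition labels and detects linearity", {
  recs <- list(
    trace_recipe(modulus = 40, frequency = 0.05, noise_sd = 0,
                 meta = list(concentration_mM = 0.2)),
    trace_recipe(modulus = 20, frequency = 0.05, noise_sd = 0,
                 nonlinearity = nonlinearity_for_ratio(0.3, 20),
                 meta = list(concentration_mM = 1.0)))
  tab <- harmonic_ratio_curve(lapply(recs, generate_oscillation_trace))
  expect_equal(tab$concentration_mM, c(0.2, 1.0))
  expect_lt(tab$harmonic_ratio[1], 1e-9)
  expect_equal(tab$harmonic_ratio[2], 0.3, tolerance = 1e-6)
})
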