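test_that("generated traces are deterministic under a fixed seed", {
  rec <- trace_recipe(modulus = 30 + 10i, frequency = 0.05, noise_sd = 0.1,
                      seed = 17)
  t1 <- generate_oscillation_trace(rec)
  t2 <- generate_oscillation_trace(rec)
  expect_identical(t1$tension, t2$tension)
  expect_identical(t1$area, t2$area)
  # and the generator does not disturb the session RNG
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_oscillation_trace(rec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("every noiseless linear trace round-trips to its generating modulus", {
  set.seed(31)
  for (i in 1:25) {
    eps <- complex(real = runif(1, 5, 120), imaginary = runif(1, 0, 40))
    nu <- runif(1, 0.01, 0.2)
    rec <- trace_recipe(modulus = eps, frequency = nu,
                        amplitude_fraction = runif(1, 0.02, 0.2),
                        noise_sd = 0)
    mp <- dilational_modulus(generate_oscillation_trace(rec))
    expect_equal(mp$eps_real, Re(eps), tolerance = 1e-9)
    expect_equal(mp$eps_imag, Im(eps), tolerance = 1e-9)
  }
})

test_that("an LvdT-sourced recipe carries the model's modulus at its frequency", {
  rec <- trace_recipe(lvdt = c(26.9, 0.03), frequency = 0.1, noise_sd = 0)
  mp <- dilational_modulus(generate_oscillation_trace(rec))
  eps <- lvdt_modulus(26.9, 0.03, 0.1)
  expect_equal(mp$eps_real, Re(eps), tolerance = 1e-9)
  expect_equal(mp$eps_imag, Im(eps), tolerance = 1e-9)
})

test_that("the quadratic distortion produces the designed second-harmonic content", {
  # distortion term d sin^2 has second-harmonic amplitude d/2, so
  # d = 0.6 * (first-harmonic amplitude) gives a ratio of 0.30
  eps <- 30 + 10i
  rec <- trace_recipe(modulus = eps, frequency = 0.05,
                      nonlinearity = nonlinearity_for_ratio(0.30, eps),
                      noise_sd = 0)
  expect_equal(dilational_modulus(generate_oscillation_trace(rec))$harmonic_ratio,
               0.30, tolerance = 1e-9)
})

test_that("the residual noise level of analysed traces matches the recipe", {
  rec <- trace_recipe(modulus = 30 + 10i, frequency = 0.05, noise_sd = 0.1,
                      seed = 23, duration_periods = 30)
  mp <- dilational_modulus(generate_oscillation_trace(rec))
  expect_equal(mp$tension_fit$residual_sd, 0.1, tolerance = 0.15)
})

test_that("the reference condition suite writes analysable files with a monotone distortion schedule", {
  dir <- withr::local_tempdir()
  files <- generate_condition_suite(dir, noise_sd = 0.05, seed = 4)
  expect_length(files, 10L)
  expect_true(all(file.exists(files)))
  traces <- lapply(files, read_trace_csv)
  tab <- harmonic_ratio_curve(traces)
  r_low <- tab$harmonic_ratio[tab$concentration_mM == 0.2]
  r_high <- tab$harmonic_ratio[tab$concentration_mM == 1.5]
  expect_true(all(r_low < r_high))
  # the 1.5 mM condition is marked as an extrapolation
  m <- traces[[which(tab$concentration_mM == 1.5)[1]]]$meta
  expect_identical(m$extrapolated, "true")
  # the below-CMC rows carry the reference LvdT parameters: fitting the
  # 0.2 mM spectrum must get close to them despite noise (only 2
  # frequencies here, so compare the analysed moduli directly)
  eps_ref <- lvdt_modulus(30.1, 0.0032, 0.01)
  sub <- analyze_traces(traces[tab$concentration_mM == 0.2])
  got <- sub$eps_real_mN_m[sub$frequency_hz == 0.01]
  expect_equal(got, Re(eps_ref), tolerance = 0.05)
})

test_that("invalid recipes are rejected", {
  expect_error(trace_recipe(frequency = 0.05), "modulus or lvdt")
  expect_error(trace_recipe(modulus = 30, frequency = 0.05,
                            amplitude_fraction = 0.5), "\\(0, 0.2\\]")
  expect_error(trace_recipe(modulus = 30, frequency = 0.05,
                            duration_periods = 2), ">= 3")
})
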