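test_that("analytic limits of the diffusional modulus hold exactly", {
  # insoluble-monolayer limit: no diffusional exchange
  expect_equal(lvdt_modulus(42, 0, c(0.01, 0.1)), c(42 + 0i, 42 + 0i))
  # zero Gibbs elasticity
  expect_identical(lvdt_modulus(0, 0.05, 0.1), 0 + 0i)
  # xi = 1 at nu = nu_d / 2: eps = eps0 (2 + i) / 5
  eps <- lvdt_modulus(10, 0.2, 0.1)
  expect_equal(Re(eps), 4, tolerance = 1e-12)
  expect_equal(Im(eps), 2, tolerance = 1e-12)
  expect_error(lvdt_modulus(10, 0.1, -0.1), "positive")
})

test_that("storage exceeds loss and both stay below the Gibbs elasticity for all xi > 0", {
  set.seed(42)
  n <- 1e4
  eps0 <- runif(n, 1, 200)
  nu_d <- 10^runif(n, -5, 1)
  nu <- 10^runif(n, -3, 1)
  eps <- mapply(function(e, d, f) lvdt_modulus(e, d, f), eps0, nu_d, nu)
  expect_true(all(Im(eps) > 0))
  expect_true(all(Im(eps) < Re(eps)))
  expect_true(all(Re(eps) < eps0))
  # phase angle below pi/4
  expect_true(all(atan2(Im(eps), Re(eps)) < pi / 4))
})

test_that("the real part increases with frequency and the loss part has one interior maximum", {
  freq <- lvdt_freq_grid(200, 1e-4, 10)
  eps <- lvdt_modulus(50, 0.01, freq)
  expect_true(all(diff(Re(eps)) > 0))
  sign_changes <- sum(diff(sign(diff(Im(eps)))) != 0)
  expect_identical(sign_changes, 1L)
})

test_that("noiseless self-generated spectra are recovered to better than 0.1%", {
  for (row in list(c(30.1, 0.0032), c(73.9, 0.02), c(45.3, 0.0081),
                   c(26.9, 0.03), c(12.6, 0.06))) {
    fit <- fit_lvdt(lvdt_real_spectrum(row[1], row[2]))
    expect_true(fit$converged)
    expect_equal(coef(fit)[["eps0"]], row[1], tolerance = 1e-3)
    expect_equal(coef(fit)[["nu_d"]], row[2], tolerance = 1e-3)
    expect_lt(fit$residual_rms, 1e-6)
  }
})

test_that("a frequency-independent spectrum drives nu_D to its lower bound", {
  sp <- data.frame(frequency = lvdt_freq_grid(10), eps_real = 27.3)
  fit <- fit_lvdt(sp)
  expect_equal(coef(fit)[["eps0"]], 27.3, tolerance = 1e-6)
  expect_lt(coef(fit)[["nu_d"]], 1e-8)
})

test_that("refitting from the fitted optimum is idempotent", {
  sp <- lvdt_real_spectrum(45.3, 0.0081)
  sp$eps_real <- sp$eps_real + rep_len(c(0.3, -0.2), nrow(sp))
  f1 <- fit_lvdt(sp)
  f2 <- fit_lvdt(sp, starts = data.frame(eps0 = coef(f1)[["eps0"]],
                                         nu_d = coef(f1)[["nu_d"]]))
  expect_equal(coef(f2), coef(f1), tolerance = 1e-7)
})

test_that("the complex joint fit recovers generating parameters too", {
  freq <- lvdt_freq_grid()
  eps <- lvdt_modulus(26.9, 0.03, freq)
  sp <- data.frame(frequency = freq, eps_real = Re(eps), eps_imag = Im(eps))
  fit <- fit_lvdt(sp, part = "complex")
  expect_equal(coef(fit)[["eps0"]], 26.9, tolerance = 1e-4)
  expect_equal(coef(fit)[["nu_d"]], 0.03, tolerance = 1e-4)
})

test_that("Monte-Carlo replicates with measurement noise recover parameters on average", {
  freq <- lvdt_freq_grid()
  clean <- Re(lvdt_modulus(45.3, 0.0081, freq))
  set.seed(202)
  est <- t(vapply(1:200, function(i) {
    sp <- data.frame(frequency = freq,
                     eps_real = clean + rnorm(length(freq), sd = 1))
    coef(fit_lvdt(sp))
  }, c(eps0 = 0, nu_d = 0)))
  expect_equal(mean(est[, "eps0"]), 45.3, tolerance = 0.05)
  expect_equal(mean(est[, "nu_d"]), 0.0081, tolerance = 0.05)
})

test_that("degenerate spectra are rejected", {
  expect_error(fit_lvdt(data.frame(frequency = c(0.01, 0.02),
                                   eps_real = c(5, 6))),
               "at least 3 distinct frequencies")
})

test_that("fit methods expose the usual modelling surface", {
  sp <- lvdt_real_spectrum(30.1, 0.0032)
  fit <- fit_lvdt(sp)
  expect_named(coef(fit), c("eps0", "nu_d"))
  expect_identical(dim(vcov(fit)), c(2L, 2L))
  pr <- predict(fit, frequency = c(0.01, 0.1))
  expect_equal(pr$eps_real,
               Re(lvdt_modulus(coef(fit)[["eps0"]], coef(fit)[["nu_d"]],
                               c(0.01, 0.1))))
  expect_output(print(fit), "Gibbs elasticity")
  expect_output(print(summary(fit)), "nu_D")
  expect_identical(length(residuals(fit)), nrow(sp))
})
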