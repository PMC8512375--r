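RT295 <- 8.31446262 * 295

neutral_system <- function(b = 50, omega = 2.5e5, a = 0)
  mixture_system(surfactant_component("C12", 0, b = b, omega = omega),
                 interaction = a)

test_that("bulk speciation splits monomer and dimer and conserves charge", {
  sys <- lae_system(minority_fraction = 0.18, dimer_charge = 1,
                    salt_mM = 10)
  sp <- bulk_speciation(sys, 1e-3)
  expect_equal(sp$surfactant$conc, c(0.82e-3, 0.18e-3))
  # electroneutrality over every ionic species
  expect_equal(sum(sp$ions$charge * sp$ions$conc), 0, tolerance = 1e-15)
  # single-component limit
  sys1 <- mixture_system(surfactant_component("LAE", 1, 250, 2.5e5))
  sp1 <- bulk_speciation(sys1, 5e-4)
  expect_equal(sp1$surfactant$conc, 5e-4)
  expect_equal(sum(sp1$ions$charge * sp1$ions$conc), 0, tolerance = 1e-15)
})

test_that("speciation is electroneutral across compositions and salt levels", {
  for (f in c(0, 0.002, 0.18)) for (salt in c(0, 10, 100)) {
    for (zd in 0:1) {
      sys <- lae_system(minority_fraction = f, dimer_charge = zd,
                        salt_mM = salt)
      sp <- bulk_speciation(sys, 7e-4)
      expect_equal(sum(sp$ions$charge * sp$ions$conc), 0, tolerance = 1e-15)
    }
  }
})

test_that("the clean interface is the zero-concentration solution", {
  st <- equilibrium_coverage(lae_system(), 0)
  expect_equal(unname(st$coverages), c(0, 0))
  expect_identical(st$surface_pressure, 0)
  expect_identical(st$surface_potential, 0)
})

test_that("a single neutral non-interacting component follows the Langmuir isotherm", {
  sys <- neutral_system(b = 10, omega = 2e5)
  for (cc in c(1e-5, 1e-4, 1e-3, 1e-2)) {
    st <- equilibrium_coverage(sys, cc)
    bc <- 10 * cc * 1000  # b [m^3/mol] * c [mol/m^3]
    expect_equal(unname(st$coverages), bc / (1 + bc), tolerance = 1e-10)
  }
})

test_that("two identical neutral components adsorb symmetrically", {
  sys <- mixture_system(
    list(surfactant_component("X", 0, 40, 2.5e5),
         surfactant_component("Y", 0, 40, 2.5e5)),
    minority_fraction = 0.5)
  st <- equilibrium_coverage(sys, 1e-3)
  expect_equal(st$coverages[["X"]], st$coverages[["Y"]], tolerance = 1e-12)
})

test_that("the neutral limit reproduces the Szyszkowski equation over a 50-point grid", {
  sys <- neutral_system(b = 50, omega = 2.5e5)
  grid <- 10^seq(-6, -2, length.out = 50)
  sig <- surface_tension(sys, grid)
  szy <- 72.5 - 1000 * RT295 / 2.5e5 * log(1 + 50 * grid * 1000)
  expect_equal(sig, szy, tolerance = 1e-8)
  expect_true(all(diff(sig) < 0))
})

test_that("model surface excess is Gibbs-consistent with the tension derivative", {
  sys <- neutral_system(b = 50, omega = 2.5e5)
  for (cc in c(5e-5, 2e-4, 1e-3)) {  # mid coverages
    h <- 1e-3
    dsig <- (surface_tension(sys, cc * exp(h)) -
               surface_tension(sys, cc * exp(-h))) / (2 * h)
    gamma_gibbs <- -dsig / 1000 / RT295       # mol/m^2
    gamma_model <- equilibrium_coverage(sys, cc)$coverages[[1]] / 2.5e5
    expect_equal(gamma_gibbs, gamma_model, tolerance = 0.01)
  }
})

test_that("added salt screens the ionic layer and lowers the tension everywhere", {
  mk <- function(salt) mixture_system(
    surfactant_component("LAE", 1, 250, 2.5e5), salt_mM = salt)
  grid <- 10^seq(-5, -3, length.out = 25)
  s_nosalt <- surface_tension(mk(0), grid)
  s_salt <- surface_tension(mk(100), grid)
  expect_true(all(s_salt <= s_nosalt + 1e-9))
  expect_true(all(diff(s_salt) < 0) && all(diff(s_nosalt) < 0))
})

test_that("the tension is clamped at sigma(CMC) above the CMC", {
  sys <- neutral_system(b = 50)
  sys$cmc <- 1e-3
  sig <- surface_tension(sys, c(5e-4, 1e-3, 2e-3, 5e-3))
  expect_equal(sig[2], sig[3])
  expect_equal(sig[3], sig[4])
  expect_gt(sig[1], sig[2])
})

test_that("fitting recovers Szyszkowski parameters from self-generated data", {
  sys <- neutral_system(b = 50, omega = 2.5e5)
  d <- generate_isotherm_dataset(sys, 10^seq(-5, -2.8, length.out = 12),
                                 noise_sd = 0)
  template <- neutral_system(b = 20, omega = 4e5)
  fit <- fit_isotherm(d, template, free = c("b.C12", "omega.C12"))
  expect_equal(coef(fit)[["b.C12"]], 50, tolerance = 0.01)
  expect_equal(coef(fit)[["omega.C12"]], 2.5e5, tolerance = 0.01)
})

test_that("two-component data with the minority fraction frozen recovers both surface activities", {
  sys <- lae_system(minority_fraction = 0.002)
  d <- generate_isotherm_dataset(sys, 10^seq(-5, -3.1, length.out = 12),
                                 noise_sd = 0)
  template <- lae_system(minority_fraction = 0.002)
  template$components[[1]]$b <- 100
  template$components[[2]]$b <- 5e4
  fit <- fit_isotherm(d, template, free = c("b.LAE", "b.dimer"))
  expect_equal(coef(fit)[["b.LAE"]], 250, tolerance = 0.01)
  expect_equal(coef(fit)[["b.dimer"]], 2e4, tolerance = 0.01)
  expect_lt(fit$residual_rms, 1e-4)
})

test_that("an empty free list returns the template unchanged with residuals only", {
  sys <- neutral_system()
  d <- generate_isotherm_dataset(sys, 10^seq(-5, -3, length.out = 8),
                                 noise_sd = 0)
  fit <- fit_isotherm(d, sys, free = character())
  expect_identical(coef(fit), numeric(0))
  expect_lt(max(abs(residuals(fit))), 1e-10)
  expect_identical(fit$system$components[[1]]$b, sys$components[[1]]$b)
})

test_that("generated isotherm datasets are reproducible under a fixed seed", {
  sys <- neutral_system()
  g <- 10^seq(-5, -3, length.out = 8)
  d1 <- generate_isotherm_dataset(sys, g, noise_sd = 0.2, seed = 9)
  d2 <- generate_isotherm_dataset(sys, g, noise_sd = 0.2, seed = 9)
  expect_identical(d1$tension, d2$tension)
  d0 <- generate_isotherm_dataset(sys, g, noise_sd = 0)
  expect_equal(d0$tension, surface_tension(sys, g))
})

test_that("invalid mixture configurations are rejected", {
  expect_error(surfactant_component("X", 3, 10, 2e5), "<= 2")
  expect_error(surfactant_component("X", 0, -1, 2e5), ">= 0")
  expect_error(mixture_system(list(), minority_fraction = 0),
               "surfactant_component")
  expect_error(
    mixture_system(surfactant_component("X", 0, 10, 2e5),
                   minority_fraction = 1.2), "\\[0, 1\\)")
})
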