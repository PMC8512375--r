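# shared fixtures, built in code

# default synthetic frequency sweep used for LvdT spectra: 15 log-spaced
# points bracketing the instrument band
lvdt_freq_grid <- function(n = 15L, lo = 0.005, hi = 0.2) {
  exp(seq(log(lo), log(hi), length.out = n))
}

# noiseless real-part LvdT spectrum for given parameters
lvdt_real_spectrum <- function(eps0, nu_d, freq = lvdt_freq_grid()) {
  data.frame(frequency = freq,
             eps_real = Re(lvdt_modulus(eps0, nu_d, freq)))
}

# dense trapezoidal Fourier-coefficient integration of a periodic waveform
# over one period: independent oracle for harmonic amplitudes
trapezoid_harmonic_amplitude <- function(fun, period, k, n = 200000L) {
  tt <- seq(0, period, length.out = n + 1L)
  s <- fun(tt)
  trap <- function(v) sum(diff(tt) * (head(v, -1L) + tail(v, -1L)) / 2)
  a <- 2 / period * trap(s * cos(2 * pi * k * tt / period))
  b <- 2 / period * trap(s * sin(2 * pi * k * tt / period))
  sqrt(a^2 + b^2)
}

# piecewise-linear isotherm with a slope break (the classical CMC shape)
piecewise_isotherm <- function(cmc = 1e-3, sigma_cmc = 25,
                               slope = -18, n = 16L,
                               lo = 10^-4.2, hi = 10^-2.5) {
  conc <- 10^seq(log10(lo), log10(hi), length.out = n)
  tension <- ifelse(conc < cmc,
                    sigma_cmc + slope * (log10(conc) - log10(cmc)),
                    sigma_cmc)
  list(conc = conc, tension = tension)
}
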