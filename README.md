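# droprheo

Surface dilational rheology and adsorption modelling for oscillating
pendant-drop tensiometry, developed around ethyl lauroyl arginate (LAE) —
a food-grade, amino-acid-based cationic surfactant whose aqueous solutions
are inherently multicomponent: synthesis residues and hydrolysis products
(dodecanoate, Nα-lauroyl-arginine) form highly surface-active heterodimers
with LAE, which shapes both the equilibrium isotherm and the dynamic
surface response.

The package is for interfacial physical chemists who have (or want to
simulate) oscillating-drop measurements — time series of drop area
`A(t)` and surface tension `σ(t)` — and equilibrium surface tension
isotherms `σ(c)`, and who need the standard derived quantities:

* the **complex surface dilational modulus** at the drive frequency ν,

  `ε = ε_r + i ε_i = A0 · Δσ1 / ΔA1`,

  where `Δσ1`, `ΔA1` are the complex fundamental Fourier components of
  the (Loess-smoothed) tension and the raw area, and `A0` the mean drop
  area;
* the **harmonic-distortion ratio** `|F(Δσ)₂| / |F(Δσ)₁|`, a nonlinearity
  statistic that grows when micellar exchange distorts the compression
  half-cycle near and above the CMC;
* **Lucassen–van den Tempel (LvdT) fits** of the modulus spectrum,

  `ε(ν) = ε₀ (1 + ξ + iξ) / (1 + 2ξ + 2ξ²)`, `ξ = √(ν_D / 2ν)`,

  estimating the Gibbs elasticity `ε₀` and the diffusional characteristic
  frequency `ν_D`;
* **mixed ionic surfactant adsorption isotherms** (monomer + heterodimer +
  salt) from a quasi-two-dimensional electrolyte model — mixed Frumkin
  isotherm, Boltzmann subsurface concentrations, Gouy–Chapman double
  layer — with least-squares fitting and **CMC breakpoint detection**.

A synthetic-data generator emulates the tensiometer (sinusoidal area
drive, linear viscoelastic response, optional second-harmonic distortion,
0.1 mN/m Gaussian noise), so the whole pipeline is testable end to end
without instrument data.

## Worked example

Simulate a frequency sweep at the 0.5 mM condition (LvdT parameters
ε₀ = 45.3 mN/m, ν_D = 0.0081 Hz), analyse each trace, and refit the model:

```r
library(droprheo)

freqs <- c(0.01, 0.02, 0.05, 0.1, 0.2)
traces <- lapply(seq_along(freqs), function(i)
  generate_oscillation_trace(trace_recipe(
    lvdt = c(45.3, 0.0081), frequency = freqs[i],
    noise_sd = 0.1, seed = 40 + i,
    meta = list(concentration_mM = 0.5))))

tab <- analyze_traces(traces)
tab[, 1:5]
#>   concentration_mM frequency_hz eps_real_mN_m eps_imag_mN_m harmonic_ratio
#> 1              0.5         0.01         23.99         9.393       0.002063
#> 2              0.5         0.02         28.47         8.919       0.002547
#> 3              0.5         0.05         33.40         7.371       0.003040
#> 4              0.5         0.10         36.73         6.081       0.005457
#> 5              0.5         0.20         38.95         4.866       0.003230

fit <- fit_lvdt(data.frame(frequency = tab$frequency_hz,
                           eps_real = tab$eps_real_mN_m))
fit
#> Lucassen-van den Tempel fit (real part, 5 frequencies)
#>   Gibbs elasticity eps0 = 45.24 mN/m (se 0.163)
#>   diffusional frequency nu_D = 0.008138 Hz (se 0.000188)
#>   residual rms 0.08585 mN/m, converged: TRUE
```

The storage modulus rises with frequency (surfactant exchange with the
bulk cannot follow fast compressions, so the layer behaves more like an
insoluble film), the loss modulus falls, and the fit recovers the
generating parameters within the noise-propagated uncertainty. The tiny
harmonic ratios (~0.003) are the noise floor of a perfectly linear
response; a micellising solution produces ratios of 0.1–0.3.

Isotherm side, in three lines:

```r
sys <- lae_system(minority_fraction = 0.002)   # LAE + 0.2% heterodimer
d   <- generate_isotherm_dataset(sys, 10^seq(-5, -3.1, length.out = 12))
fit_isotherm(d, sys, free = c("b.LAE", "b.dimer"))
```

and `detect_cmc()` locates the slope break of σ vs log₁₀(c).

A thin command-line interface (`inst/cli/droprheo.R`) exposes
`simulate`, `analyze-trace`, `fit-lvdt`, `fit-isotherm`, `detect-cmc`
and `run` (a YAML-configured pipeline with a JSON run manifest).

## Documentation

The methods vignette (`vignettes/droprheo-methods.Rmd`) describes the
estimators, the adsorption model, all numerical choices and the
limitations of the synthetic data; every exported function has a help
page.
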