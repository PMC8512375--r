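---
title: "Methods: dilational rheology and mixed-surfactant adsorption in droprheo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilational rheology and mixed-surfactant adsorption in droprheo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droprheo)
```

# The measurement and its model

An oscillating pendant-drop tensiometer imposes small periodic changes on
the surface area $A(t)$ of a drop and records the surface tension
$\sigma(t)$ obtained from the drop profile (one profile per second, with
a precision of about 0.1 mN/m). For a soluble surfactant layer in the
linear regime the tension response at the drive frequency $\nu$ defines
the complex surface dilational modulus

$$\varepsilon = \varepsilon_r + i\,\varepsilon_i
  = A_0\,\frac{\Delta\sigma_1}{\Delta A_1},$$

with $A_0$ the mean drop area and $\Delta\sigma_1$, $\Delta A_1$ the
complex fundamental Fourier components of tension and area. The storage
part $\varepsilon_r$ measures the elastic resistance of the layer to
compression; the loss part $\varepsilon_i$ measures the dissipation
caused by surfactant exchange with the bulk.

`droprheo` implements this pipeline for the cationic surfactant ethyl
lauroyl arginate (LAE), whose aqueous solutions are inherently mixtures:
residues from synthesis and hydrolysis (dodecanoate, Nα-lauroyl-arginine,
"LAS") associate with LAE into highly surface-active heterodimers. The
package therefore couples the rheological analysis with a
mixed-surfactant adsorption model and a synthetic-data generator that
emulates the instrument.

# Harmonic analysis

## Estimator

The paper-and-pencil route to $\Delta\sigma_1$ is an FFT bin. Recorded
traces, however, rarely contain an integer number of oscillation periods,
and FFT binning then leaks power between bins. `harmonic_decompose()`
instead regresses the signal onto the basis
$\{1,\ t,\ \cos 2\pi k\nu t,\ \sin 2\pi k\nu t\}_{k=1..K}$
(default $K = 4$). This estimator is unbiased for arbitrary trace
lengths, estimates a linear equilibration drift jointly with the
harmonics, and its residual standard deviation estimates the measurement
noise. The mean drop area $A_0$ is taken from the regression intercept
for the same reason: the arithmetic mean of a sinusoid over a non-integer
number of periods is biased by up to $a/2\pi N$ of the amplitude, which
is visible at the $10^{-5}$ relative level the round-trip contracts
require.

Phases follow the convention $A_k\cos(2\pi k\nu t + \phi_k)$, phasor
$C_k = A_k e^{i\phi_k}$. The modulus phase is
$\arg\Delta\sigma_1 - \arg\Delta A_1$, mapped to $(-\pi, \pi]$; positive
$\varepsilon_i$ means the tension lags the area drive (viscous-like),
the convention in which both parts of the diffusional model below are
non-negative.

## Smoothing without attenuation

The raw tension is Loess-smoothed before harmonic extraction (tricube
weights, local degree 2, span 0.3 of one oscillation period expressed as
a fraction of points). A smoother is a low-pass filter: it attenuates the
fundamental by $\sim 10^{-3}$–$10^{-2}$ and the second harmonic more,
which would bias both the modulus and the distortion ratio. Because
gaussian-family loess is a *linear* operator, the package regresses the
smoothed signal on the **identically smoothed basis functions**. For any
noiseless signal inside the model space the coefficients are then exact
(the smoothing cancels), while measurement noise is still filtered. The
switch `compensate = FALSE` restores the naive decomposition of the
smoothed signal; the difference between the two is a direct measurement
of the smoother's gain at each harmonic. The imposed area signal is
analysed raw.

## Frequency refinement

Drive hardware has frequency jitter, so the fundamental is refined within
±5% of the nominal frequency. The objective is the residual sum of
squares of the full harmonic fit, *not* the fitted $k=1$ amplitude: off
the true frequency, leakage into the intercept and drift columns can
inflate the fitted amplitude, making it an unreliable objective. The
nominal value is kept unless refinement improves the fit by more than a
relative margin of $10^{-8}$ *and* an absolute floor of $10^{-14}$ times
the signal power — without the floor, the rounding-level residuals of
exact synthetic traces (SSE $\sim 10^{-25}$) would accept meaningless
"refinements". Refinement uses the area signal, which carries essentially
no noise.

## Quality flags

Two failure modes are flagged rather than silently reported: a relative
area amplitude below $10^{-4}$ raises an error (no excitation — nothing
to analyse), and a tension fundamental below three residual standard
deviations of the harmonic regression returns
$\varepsilon_r = \varepsilon_i = 0$ with
`quality_flag = "below_noise_floor"`. The propagated standard error of
the complex modulus (`eps_se`) comes from the regression covariance of
the two quadratures of $\Delta\sigma_1$.

## Nonlinearity statistic

`harmonic_ratio_curve()` reports
$|F(\Delta\sigma)_2| / |F(\Delta\sigma)_1|$ per trace. A strictly linear
response gives zero up to the noise floor. Near and above the CMC the
compression half-cycle is distorted — the oversaturated layer sheds
surfactant into micelles, so tension rises even while the area still
shrinks — and the ratio grows to order 0.1–0.3. Whether the ratio should
be computed on the smoothed or the raw tension is immaterial under gain
compensation (both give the unbiased value); `compensate = FALSE`
exposes the difference.

# The Lucassen–van den Tempel model

For a single surfactant whose adsorption is diffusion-controlled,

$$\varepsilon(\nu) = \varepsilon_0\,
  \frac{1 + \xi + i\xi}{1 + 2\xi + 2\xi^2},
  \qquad \xi = \sqrt{\frac{\nu_D}{2\nu}},$$

with $\varepsilon_0$ the Gibbs elasticity (insoluble-film limit) and
$\nu_D$ the characteristic frequency of diffusional exchange. Structure
worth testing against: $\varepsilon_r \to \varepsilon_0$,
$\varepsilon_i \to 0$ as $\nu \to \infty$; both vanish as $\nu \to 0$;
$0 < \varepsilon_i < \varepsilon_r < \varepsilon_0$ for every finite
$\xi > 0$; at $\xi = 1$, $(\varepsilon_r, \varepsilon_i) = (0.4,
0.2)\,\varepsilon_0$; the phase angle stays below $\pi/4$. A measured
loss part *exceeding* the storage part is therefore a model-violation
diagnostic — for LAE it appears near and above the CMC, where micellar
kinetics and layer reorganisation invalidate single-surfactant diffusion.

`fit_lvdt()` fits $(\varepsilon_0, \nu_D)$ by bounded Levenberg–Marquardt
least squares, multi-started from the grid
$\varepsilon_0 \in \{5, 20, 80\}$ mN/m $\times$
$\nu_D \in \{10^{-4}, 10^{-2}, 1\}$ Hz, bounds
$\varepsilon_0 \in (0, 500]$, $\nu_D \in [0, 10]$. The default target is
the **real part only**: for a multicomponent layer the loss part deviates
from the single-surfactant model except at low frequency and
concentration, so the storage part is the robust target; the joint
complex fit is available as an extension (`part = "complex"`). The
objective is unweighted (no per-point uncertainties are available from
single sweeps); per-point weights are accepted. Parameter uncertainties
come from the linearised covariance $\hat\sigma^2 (J^\top J)^{-1}$ at the
optimum. Synthetic sweeps default to 15 log-spaced frequencies in
0.005–0.2 Hz, bracketing the instrument band; noiseless recovery is
insensitive to the grid.

`lae_lvdt_params()` carries the reference $(\varepsilon_0, \nu_D)$ pairs
for fresh aqueous LAE at 0.2–1.0 mM; they parameterise the synthetic
reference conditions and the acceptance script.

# The mixed-surfactant adsorption model

## Equations

The isotherm module implements the standard realisation of the
quasi-two-dimensional electrolyte family for ionic surfactant mixtures.
Adsorbing species $i$ (charge $z_i$, surface activity $b_i$ in
m³/mol, molar area $\omega_i$) obey, with
$\theta_T = \sum_j \theta_j$ and reduced potential
$y = F\psi_s / 2RT$:

1. **Boltzmann subsurface**: $c_i^s = c_i \exp(-2 z_i y)$;
2. **mixed Frumkin isotherm**:
   $b_i c_i^s = \dfrac{\theta_i}{1 - \theta_T}
   \exp\!\big(-2\textstyle\sum_j a_{ij}\theta_j\big)$;
3. **Gouy–Chapman closure**:
   $F \sum_i z_i \theta_i / \omega_{\mathrm{ref}}
   = \sqrt{8\epsilon\epsilon_0 RT I}\,\sinh y$;
4. **equation of state**:
   $\Pi = -\dfrac{RT}{\omega_{\mathrm{ref}}}
   \big[\ln(1-\theta_T) + \sum_{ij} a_{ij}\theta_i\theta_j\big]
   + \dfrac{8RTI}{\kappa}\,(\cosh y - 1)$,

and $\sigma(c) = \sigma_0 - \Pi$. A single reference molar area (the
majority component's) is used in the equation of state. Composition
enters through the minority fraction $f$: the heterodimer concentration
is $f\,c_{\mathrm{total}}$, the monomer $(1-f)\,c_{\mathrm{total}}$ (the
minority species is assumed fully dimerised). Counterions enforcing
electroneutrality plus added 1:1 salt set the ionic strength.
Temperature is fixed at 295 K (a thermostated 22 °C cell);
$\sigma_0 = 72.5$ mN/m by default. Concentrations are mol/dm³ at the
interface and SI internally. Above a configured CMC, $\sigma$ is clamped
at $\sigma(\mathrm{CMC})$; micellar equilibria are not modelled.

These equations collapse to closed forms used as test oracles: with one
neutral, non-interacting component they reduce to the Langmuir isotherm
$\theta = bc/(1+bc)$ and the Szyszkowski equation
$\sigma_0 - \sigma = (RT/\omega)\ln(1+bc)$; the surface excess
$\theta/\omega$ must satisfy the Gibbs adsorption equation
$\Gamma = -\mathrm{d}\sigma / \mathrm{d}(RT\ln c)$; and added salt can
only lower $\sigma$ of a net-charged layer (screening).

## Numerics

The coupled system in $(\theta_1..\theta_m, y)$ is solved by damped
Newton iteration (step halving, feasibility guard $\theta_T < 1$) to a
residual infinity-norm below $10^{-12}$, with the charge equation scaled
by the Gouy–Chapman prefactor for conditioning. Starting points come
from the dilute limit, where the scalar charge balance is solved by
bisection — at low ionic strength the double-layer term dominates and a
Newton start from $y = 0$ fails. Concentration sweeps are solved in
ascending order with warm starts (continuation); a fresh ladder from
$10^{-4}\,c$ is the fallback. The solver is deterministic.

`fit_isotherm()` estimates any subset of $\{b_i, \omega_i, a_{ij}, f\}$
by Levenberg–Marquardt on transformed scales (log for $b$, $\omega$;
logit for $f$), multi-started from scaled template values. An empty free
list gives evaluation mode (residuals only); an under-determined
configuration warns and reports the covariance condition number. Whether
$f$ should be fitted or fixed from composition knowledge is a judgement
call; the package default follows the fixed-$f$ reading (0.002 for fresh
solutions, 0.18 for stored ones), fitting only the $b_i$.

## CMC detection

`detect_cmc()` uses the classical two-line construction on $\sigma$ vs
$\log_{10} c$: all splits with at least four points per branch are
scored by total squared residual, and the best split's line intersection
gives the CMC and $\sigma_{\mathrm{CMC}}$. Equal branch slopes (within
$10^{-9}$ relative) are reported as monotone-slope data with no CMC in
range rather than returning an unstable intersection.

# The synthetic tensiometer

`generate_oscillation_trace()` realises
$$A(t) = A_0(1 + a\sin 2\pi\nu t), \qquad
\sigma(t) = \sigma_{\mathrm{base}}
  + |\varepsilon|\,a\sin(2\pi\nu t + \phi)
  + \beta\,(a\sin 2\pi\nu t)^2 + \mathcal{N}(0, s^2),$$
with $\phi = \operatorname{atan2}(\varepsilon_i, \varepsilon_r)$.
Defaults are the instrument's conditions: $a = 0.1$ (drop oscillations
below 10% of the volume; for a near-spherical drop the area amplitude is
about 2/3 of the volume amplitude, and the area amplitude is the
controlled quantity here), noise $s = 0.1$ mN/m, $A_0 = 24$ mm² (an
11 µL drop), 10 periods per trace, and a sampling rate of
$\max(1, 20\nu)$ Hz — the instrument records once per second, which at
0.2 Hz would leave only five samples per period, so faster oscillations
are oversampled to keep $K$ harmonics below Nyquist.

The nonlinearity is a quadratic ($\sin^2$) tension distortion, not a
mechanistic micelle-exchange model: the physical asymmetry is known only
qualitatively, while $\sin^2 x = (1 - \cos 2x)/2$ gives *exactly*
analysable second-harmonic content — a distortion coefficient $\beta$
contributes amplitude $\beta a^2/2$ at $2\nu$, so
`nonlinearity_for_ratio()` can target any harmonic ratio in closed form.
The waveform shape is not claimed to match real above-CMC traces, only
to produce a controllable distortion statistic.

`generate_condition_suite()` writes the reference campaign: 0.2, 0.5,
0.8, 1.0, 1.5 mM × 0.01, 0.1 Hz, with moduli from `lae_lvdt_params()`
(the 1.5 mM pair is an explicit extrapolation above the CMC, flagged in
the file metadata) and a distortion schedule with onset at 0.5 mM rising
to a ratio of 0.3 at the CMC and level above it. Noise uses per-file
seeds derived from one master seed; the generator saves and restores the
session RNG state, so fixed-seed outputs are reproducible to the last
bit and independent of platform at the $10^{-12}$ level for the
noiseless part.

# What the tests do and do not show

The test suite (and the acceptance script) validate the pipeline against
*self-generated* data and closed-form oracles: exact sinusoids, clipped
waveforms integrated by dense trapezoidal quadrature, Langmuir/
Szyszkowski limits, Gibbs consistency, generator round trips at $10^{-9}$
(noiseless) and at the propagated uncertainty (noisy), and recovery of
the reference LvdT parameter pairs to 0.1% from noiseless spectra.
Passing them shows the estimators are unbiased and the solvers correct
*under the generator's assumptions*: perfectly sinusoidal drive,
stationary baseline, white Gaussian noise, and a linear (or
$\sin^2$-distorted) response. Real traces add drop-shape fitting
artefacts, correlated noise, slow surfactant depletion and genuinely
asymmetric nonlinearity; the linear-drift term and the quality flags
absorb some of this, but fitted values from real instruments should be
inspected through the residuals and `eps_se`, not taken on faith. The
mixture model's exact appendix-level parameterisation for LAE is not
publicly tabulated; the package's `lae_system()` values are physically
plausible templates for fitting, not measured constants.

# Problem sizes and runtimes

Default problem sizes keep every analysis interactive on one CPU: traces
of 10–30 periods at 20 samples per period (200–600 points), 15-point
frequency sweeps, 12–50-point isotherm grids, 100–200-replicate
Monte-Carlo checks. The full test suite runs in under a minute; the
acceptance script in about a second.
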