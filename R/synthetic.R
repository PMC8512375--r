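#' Recipe for a synthetic oscillating-drop trace
#'
#' Parameterises the synthetic tensiometer: a sinusoidal drop-area drive
#' with a linear viscoelastic tension response set by a complex modulus
#' (given explicitly or through Lucassen-van den Tempel parameters), an
#' optional quadratic (second-harmonic-generating) distortion mimicking
#' micellar desorption near the CMC, and additive Gaussian measurement
#' noise at the instrument's precision.
#'
#' Defaults emulate the measurement conditions of a pendant-drop
#' tensiometer run on aqueous LAE: area amplitude 10% (drop oscillations
#' are kept below 10% of the drop volume; for a near-spherical drop the
#' area amplitude is about 2/3 of the volume amplitude, and the area
#' amplitude is the quantity controlled here), measurement noise 0.1 mN/m,
#' mean drop area 24 mm^2 (an 11 uL drop), and a sampling rate of at least
#' 20 samples per oscillation period (the instrument records once per
#' second, which is ample below 0.05 Hz; faster oscillations are
#' oversampled so that the harmonics stay well below Nyquist).
#'
#' @param frequency oscillation frequency in Hz (0.01-0.2 is the
#'   instrument's band).
#' @param modulus complex dilational modulus in mN/m (e.g. `30 + 10i`), or
#'   `NULL` if `lvdt` is given.
#' @param lvdt length-2 numeric `c(eps0, nu_d)`; the modulus is then
#'   `lvdt_modulus(eps0, nu_d, frequency)`.
#' @param amplitude_fraction relative area amplitude |dA1|/A0 in (0, 0.2].
#' @param mean_area mean drop area A0 in mm^2.
#' @param baseline_tension equilibrium surface tension in mN/m.
#' @param nonlinearity quadratic distortion coefficient beta (mN/m): the
#'   tension gains a term `beta * (amplitude_fraction * sin(2 pi nu t))^2`,
#'   whose second-harmonic amplitude is `beta * amplitude_fraction^2 / 2`.
#'   Default 0 (linear response).
#' @param noise_sd Gaussian tension noise sd in mN/m (default 0.1, the
#'   drop-profile fit precision).
#' @param duration_periods trace length in oscillation periods (>= 3).
#' @param sample_rate sampling rate in Hz; default
#'   `max(1, 20 * frequency)`.
#' @param seed integer RNG seed for the noise (`NULL`: use the session RNG).
#' @param meta named list of condition labels copied to the trace.
#' @return list of class `"trace_recipe"`.
#' @seealso [generate_oscillation_trace()], [nonlinearity_for_ratio()]
#' @export
trace_recipe <- function(frequency, modulus = NULL, lvdt = NULL,
                         amplitude_fraction = 0.1, mean_area = 24,
                         baseline_tension = 45, nonlinearity = 0,
                         noise_sd = 0.1, duration_periods = 10L,
                         sample_rate = NULL, seed = NULL, meta = list()) {
  if (!is_number(frequency) || frequency <= 0)
    stopf("frequency must be positive")
  if (is.null(modulus) && is.null(lvdt))
    stopf("give either modulus or lvdt = c(eps0, nu_d)")
  if (!is.null(lvdt)) {
    if (length(lvdt) != 2L) stopf("lvdt must be c(eps0, nu_d)")
    modulus <- lvdt_modulus(lvdt[1L], lvdt[2L], frequency)
  }
  modulus <- as.complex(modulus)
  if (length(modulus) != 1L || !is.finite(Re(modulus)))
    stopf("modulus must be a single complex number")
  if (!is_number(amplitude_fraction) || amplitude_fraction <= 0 ||
      amplitude_fraction > 0.2)
    stopf("amplitude_fraction must lie in (0, 0.2]")
  if (!is_number(noise_sd) || noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is_number(duration_periods) || duration_periods < 3)
    stopf("duration_periods must be >= 3")
  sample_rate <- sample_rate %||% max(1, 20 * frequency)
  if (sample_rate < 4 * frequency)
    stopf("sample_rate must give at least 4 samples per period")
  structure(list(
    frequency = frequency, modulus = modulus,
    amplitude_fraction = amplitude_fraction, mean_area = mean_area,
    baseline_tension = baseline_tension, nonlinearity = nonlinearity,
    noise_sd = noise_sd, duration_periods = duration_periods,
    sample_rate = sample_rate, seed = seed, meta = as.list(meta)),
    class = "trace_recipe")
}

#' Distortion coefficient producing a target harmonic ratio
#'
#' The quadratic distortion term `beta * (a sin(2 pi nu t))^2` contributes a
#' second harmonic of amplitude `beta a^2 / 2` (since
#' `sin^2 x = (1 - cos 2x)/2`), while the linear response's first harmonic
#' has amplitude `|modulus| a`. This helper returns the `nonlinearity`
#' value that makes the tension second-to-first harmonic amplitude ratio
#' equal `ratio`.
#'
#' @param ratio target |F2|/|F1| of the tension signal.
#' @param modulus complex modulus of the linear response (mN/m).
#' @param amplitude_fraction relative area amplitude a.
#' @return the `nonlinearity` coefficient (mN/m) for [trace_recipe()].
#' @export
nonlinearity_for_ratio <- function(ratio, modulus, amplitude_fraction = 0.1) {
  2 * ratio * Mod(as.complex(modulus)) / amplitude_fraction
}

#' Generate a synthetic oscillating-drop trace
#'
#' Realises a [trace_recipe()]:
#' \deqn{A(t) = A_0 (1 + a \sin 2\pi\nu t)}
#' \deqn{\sigma(t) = \sigma_{base} + |\varepsilon| a \sin(2\pi\nu t + \phi)
#'   + \beta (a \sin 2\pi\nu t)^2 + noise, \quad
#'   \phi = \mathrm{atan2}(\varepsilon_i, \varepsilon_r).}
#' Analysing a noise-free, linear (`nonlinearity = 0`) trace with
#' [dilational_modulus()] recovers the generating modulus to numerical
#' precision (generator/analyser adjointness); this is the main testing
#' contract of the synthetic module.
#'
#' @param recipe a [trace_recipe()].
#' @return an [oscillation_trace()]. The recipe's key parameters are stored
#'   in the trace `meta`.
#' @export
#' @examples
#' tr <- generate_oscillation_trace(trace_recipe(modulus = 30 + 10i,
#'   frequency = 0.05, noise_sd = 0, seed = 1))
#' dilational_modulus(tr)
generate_oscillation_trace <- function(recipe) {
  if (!inherits(recipe, "trace_recipe")) stopf("recipe must be a trace_recipe")
  nu <- recipe$frequency
  dt <- 1 / recipe$sample_rate
  t <- seq(0, recipe$duration_periods / nu, by = dt)
  a <- recipe$amplitude_fraction
  A0 <- recipe$mean_area
  u <- a * sin(2 * pi * nu * t)
  area <- A0 * (1 + u)
  eps <- recipe$modulus
  phi <- atan2(Im(eps), Re(eps))
  tension <- recipe$baseline_tension +
    Mod(eps) * a * sin(2 * pi * nu * t + phi) +
    recipe$nonlinearity * u^2
  if (recipe$noise_sd > 0)
    tension <- tension +
      with_seed(recipe$seed, rnorm(length(t), sd = recipe$noise_sd))
  meta <- modifyList(
    list(frequency_hz = nu, eps_real = Re(eps), eps_imag = Im(eps),
         noise_sd = recipe$noise_sd, nonlinearity = recipe$nonlinearity),
    recipe$meta)
  oscillation_trace(t, area, tension, nominal_frequency = nu, meta = meta)
}

#' Generate a synthetic surface tension isotherm dataset
#'
#' Evaluates [surface_tension()] of a [mixture_system()] on a concentration
#' grid and adds Gaussian measurement noise; reproducible under a fixed
#' seed.
#'
#' @param system a [mixture_system()].
#' @param concentrations grid in mol/dm^3, strictly increasing.
#' @param noise_sd tension noise sd in mN/m.
#' @param seed integer seed (`NULL`: session RNG).
#' @return an [isotherm_dataset()].
#' @export
generate_isotherm_dataset <- function(system, concentrations, noise_sd = 0,
                                      seed = NULL) {
  sig <- surface_tension(system, concentrations)
  if (noise_sd > 0)
    sig <- sig + with_seed(seed, rnorm(length(sig), sd = noise_sd))
  isotherm_dataset(concentrations, sig, salt_mM = system$salt_mM,
                   meta = list(noise_sd = noise_sd, seed = seed))
}

#' Diffusional viscoelasticity parameters of aqueous LAE
#'
#' Fitted Lucassen-van den Tempel parameters (Gibbs elasticity
#' \eqn{\varepsilon_0}, diffusional characteristic frequency \eqn{\nu_D})
#' describing the real part of the dilational modulus of fresh aqueous LAE
#' solutions below the CMC, per concentration. These parameterise the
#' package's reference synthetic conditions.
#'
#' @return data.frame with columns `concentration_mM`, `eps0_mN_m`,
#'   `nu_d_hz`.
#' @export
#' @examples
#' lae_lvdt_params()
lae_lvdt_params <- function() {
  data.frame(
    concentration_mM = c(0.2, 0.3, 0.5, 0.8, 1.0),
    eps0_mN_m = c(30.1, 73.9, 45.3, 26.9, 12.6),
    nu_d_hz = c(0.0032, 0.02, 0.0081, 0.03, 0.06))
}

#' Reference LAE mixture system
#'
#' A ready-made [mixture_system()] for aqueous LAE: the cationic LAE
#' monomer plus a highly surface-active heterodimer (LAE-dodecanoate,
#' neutral, for fresh solutions at minority fraction 0.002; LAE-LAS,
#' cationic, for stored solutions at 0.18). Parameter values are
#' order-of-magnitude physical choices giving surface activity onset near
#' 1e-4 mol/dm^3 and a CMC near 1e-3 mol/dm^3; they are meant as template
#' and starting values for [fit_isotherm()], not as measured constants.
#'
#' @param minority_fraction molar fraction of the heterodimer (default
#'   0.002, fresh solution).
#' @param dimer_charge 0 (LAE-dodecanoate, default) or 1 (LAE-LAS).
#' @param salt_mM added NaCl in mmol/dm^3.
#' @param cmc critical micelle concentration, mol/dm^3 (default 1.05e-3).
#' @return a [mixture_system()].
#' @export
lae_system <- function(minority_fraction = 0.002, dimer_charge = 0,
                       salt_mM = 0, cmc = 1.05e-3) {
  mixture_system(
    components = list(
      surfactant_component("LAE", charge = 1, b = 250, omega = 2.5e5),
      surfactant_component("dimer", charge = dimer_charge, b = 2e4,
                           omega = 4.0e5)),
    interaction = matrix(c(0.8, 0.5, 0.5, 0.5), 2, 2),
    minority_fraction = minority_fraction,
    salt_mM = salt_mM, cmc = cmc)
}

#' Write the reference synthetic measurement suite
#'
#' Emits one trace CSV per condition of the reference oscillating-drop
#' campaign on aqueous LAE: concentrations 0.2, 0.5, 0.8, 1.0 and 1.5 mM at
#' oscillation frequencies 0.01 and 0.1 Hz (10 files). Linear moduli come
#' from [lae_lvdt_params()] where available; the 1.5 mM condition (above
#' the CMC, where the diffusional model no longer applies) uses an
#' extrapolated parameter pair and is flagged `extrapolated=TRUE` in its
#' metadata. The quadratic distortion ramps up with concentration above
#' 0.5 mM — the onset of the nonlinear response — so the second-to-first
#' harmonic ratio grows towards the CMC and levels off above it.
#'
#' @param out_dir directory to write into (created if needed).
#' @param frequencies oscillation frequencies in Hz.
#' @param noise_sd tension noise sd in mN/m.
#' @param seed integer seed; per-file seeds are derived from it.
#' @return (invisibly) character vector of the files written.
#' @export
generate_condition_suite <- function(out_dir, frequencies = c(0.01, 0.1),
                                     noise_sd = 0.1, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  params <- lae_lvdt_params()
  # extrapolation beyond the diffusional regime, above the CMC
  params <- rbind(params, data.frame(concentration_mM = 1.5,
                                     eps0_mN_m = 8, nu_d_hz = 0.09))
  extrapolated <- c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE)
  keep <- params$concentration_mM %in% c(0.2, 0.5, 0.8, 1.0, 1.5)
  params <- params[keep, ]; extrapolated <- extrapolated[keep]
  # second-harmonic distortion schedule: onset at 0.5 mM, growth to the
  # CMC (1 mM), level above it
  ratio_target <- c(`0.2` = 0, `0.5` = 0.05, `0.8` = 0.15, `1` = 0.3,
                    `1.5` = 0.3)
  files <- character(0)
  idx <- 0L
  for (i in seq_len(nrow(params))) {
    cc <- params$concentration_mM[i]
    for (nu in frequencies) {
      idx <- idx + 1L
      eps <- lvdt_modulus(params$eps0_mN_m[i], params$nu_d_hz[i], nu)
      rt <- ratio_target[[as.character(cc)]]
      beta <- if (rt > 0) nonlinearity_for_ratio(rt, eps) else 0
      rec <- trace_recipe(
        frequency = nu, modulus = eps, nonlinearity = beta,
        noise_sd = noise_sd,
        seed = if (is.null(seed)) NULL else as.integer(seed) + idx,
        meta = list(concentration_mM = cc,
                    extrapolated = tolower(as.character(extrapolated[i]))))
      tr <- generate_oscillation_trace(rec)
      path <- file.path(out_dir,
                        sprintf("lae_%gmM_%gHz.csv", cc, nu))
      write_trace_csv(tr, path)
      files <- c(files, path)
    }
  }
  invisible(files)
}
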