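#' Surfactant component of an adsorption mixture
#'
#' One adsorbing species of the mixed-surfactant model: the surfactant
#' monomer (e.g. the LAE cation), a heterodimer (e.g. LAE-dodecanoate,
#' neutral, or LAE-LAS, cationic), etc.
#'
#' @param name label.
#' @param charge integer charge z in elementary units, |z| <= 2.
#' @param b surface activity (adsorption equilibrium constant) in m^3/mol,
#'   >= 0.
#' @param omega partial molar surface area in m^2/mol, > 0.
#' @return list of class `"surfactant_component"`.
#' @export
#' @examples
#' surfactant_component("LAE", charge = 1, b = 60, omega = 2.5e5)
surfactant_component <- function(name, charge, b, omega) {
  if (!is_number(charge) || abs(charge) > 2 || charge != round(charge))
    stopf("charge must be an integer with |z| <= 2")
  if (!is_number(b) || b < 0) stopf("surface activity b must be >= 0")
  if (!is_number(omega) || omega <= 0) stopf("molar area omega must be > 0")
  structure(list(name = as.character(name), charge = as.integer(charge),
                 b = b, omega = omega), class = "surfactant_component")
}

#' Mixed ionic surfactant system
#'
#' Declares the components, composition and solution conditions of the
#' quasi-two-dimensional electrolyte adsorption model: a majority surfactant
#' monomer plus (optionally) a highly surface-active heterodimer present at
#' molar fraction `minority_fraction`, with added 1:1 salt. The model
#' couples a mixed Frumkin adsorption isotherm for the surface coverages
#' with a Boltzmann factor for the subsurface concentrations of charged
#' species and a Gouy-Chapman diffuse double layer (see
#' [equilibrium_coverage()]).
#'
#' @param components list of [surfactant_component()]s (1 or 2 supported;
#'   with 2, the second is the minority dimer species).
#' @param interaction Frumkin lateral interaction matrix `a_ij`
#'   (dimensionless, symmetric, one row/column per component); scalar 0
#'   expands to the zero matrix. Positive values mean attraction.
#' @param minority_fraction molar fraction f in [0, 1) of total surfactant
#'   present as the second (dimer) component; ignored for one component.
#' @param salt_mM added 1:1 salt concentration in mmol/dm^3.
#' @param temperature absolute temperature in K (default 295, i.e. 22 C).
#' @param solvent_tension pure-solvent surface tension sigma0 in mN/m
#'   (default 72.5, water at 295 K).
#' @param cmc optional critical micelle concentration in mol/dm^3; above it
#'   [surface_tension()] is clamped at sigma(CMC).
#' @return list of class `"mixture_system"`.
#' @seealso [lae_system()] for a ready-made LAE parameterisation.
#' @export
mixture_system <- function(components, interaction = 0,
                           minority_fraction = 0, salt_mM = 0,
                           temperature = 295, solvent_tension = 72.5,
                           cmc = NULL) {
  if (inherits(components, "surfactant_component"))
    components <- list(components)
  if (!length(components) ||
      !all(vapply(components, inherits, TRUE, "surfactant_component")))
    stopf("components must be surfactant_component objects")
  m <- length(components)
  if (m > 2L) stopf("at most two components (monomer + dimer) are supported")
  if (is_number(interaction)) interaction <- matrix(interaction, m, m)
  interaction <- as.matrix(interaction)
  if (!all(dim(interaction) == m) ||
      max(abs(interaction - t(interaction))) > 1e-12)
    stopf("interaction must be a symmetric %d x %d matrix", m, m)
  if (!is_number(minority_fraction) || minority_fraction < 0 ||
      minority_fraction >= 1)
    stopf("minority_fraction must lie in [0, 1)")
  if (!is_number(salt_mM) || salt_mM < 0) stopf("salt_mM must be >= 0")
  if (!is_number(solvent_tension) || solvent_tension <= 20 ||
      solvent_tension >= 80)
    stopf("solvent_tension must lie in (20, 80) mN/m")
  if (!is.null(cmc) && (!is_number(cmc) || cmc <= 0))
    stopf("cmc must be a positive concentration in mol/dm^3 or NULL")
  structure(list(components = components, interaction = interaction,
                 minority_fraction = if (m == 2L) minority_fraction else 0,
                 salt_mM = salt_mM, temperature = temperature,
                 solvent_tension = solvent_tension, cmc = cmc),
            class = "mixture_system")
}

#' @export
print.mixture_system <- function(x, ...) {
  cat(sprintf("Mixed surfactant system (%d component%s), T = %g K, salt = %g mM\n",
              length(x$components), if (length(x$components) > 1) "s" else "",
              x$temperature, x$salt_mM))
  for (cp in x$components)
    cat(sprintf("  %-12s z=%+d  b=%.4g m^3/mol  omega=%.4g m^2/mol\n",
                cp$name, cp$charge, cp$b, cp$omega))
  if (length(x$components) == 2L)
    cat(sprintf("  minority (dimer) fraction f = %g\n", x$minority_fraction))
  if (!is.null(x$cmc)) cat(sprintf("  CMC = %g mol/dm^3\n", x$cmc))
  invisible(x)
}

#' Bulk speciation of the surfactant mixture
#'
#' Splits the total surfactant concentration between the monomer and the
#' dimer species (the minority component is assumed fully dimerised:
#' dimer = f * c_total, monomer = (1 - f) * c_total), adds the counterions
#' required for electroneutrality plus the 1:1 salt ions, and computes the
#' ionic strength.
#'
#' @param system a [mixture_system()].
#' @param c_total total surfactant concentration in mol/dm^3, > 0.
#' @return list with `surfactant` (data.frame `name`, `charge`,
#'   `conc` mol/dm^3 for the adsorbing species), `ions` (all ionic species
#'   incl. counterions and salt), `ionic_strength` (mol/dm^3).
#' @export
#' @examples
#' sys <- lae_system(minority_fraction = 0.18)
#' bulk_speciation(sys, 1e-3)
bulk_speciation <- function(system, c_total) {
  if (!inherits(system, "mixture_system")) stopf("system must be a mixture_system")
  if (!is_number(c_total) || c_total <= 0)
    stopf("c_total must be a positive concentration in mol/dm^3")
  m <- length(system$components)
  f <- if (m == 2L) system$minority_fraction else 0
  conc <- if (m == 2L) c(1 - f, f) * c_total else c_total
  surf <- data.frame(
    name = vapply(system$components, `[[`, "", "name"),
    charge = vapply(system$components, `[[`, 0L, "charge"),
    conc = conc)
  ions <- surf[surf$charge != 0L, c("name", "charge", "conc")]
  # counterions accompany each charged surfactant species (e.g. Cl- for LAE+)
  if (nrow(ions)) {
    q <- sum(ions$charge * ions$conc)
    if (abs(q) > 0)
      ions <- rbind(ions, data.frame(name = "counterion",
                                     charge = -sign(q),
                                     conc = abs(q)))
  }
  if (system$salt_mM > 0) {
    cs <- system$salt_mM / 1000
    ions <- rbind(ions,
                  data.frame(name = c("salt+", "salt-"),
                             charge = c(1L, -1L), conc = c(cs, cs)))
  }
  ionic_strength <- if (nrow(ions)) sum(ions$charge^2 * ions$conc) / 2 else 0
  list(surfactant = surf, ions = ions, ionic_strength = ionic_strength)
}

# Gouy-Chapman charge density (C/m^2) at reduced potential y = F psi / (2RT)
gc_charge <- function(y, ionic_strength_SI, temperature) {
  sqrt(8 * .const$e0 * .const$eps_w * .const$R * temperature *
         ionic_strength_SI) * sinh(y)
}

#' Equilibrium surface state of the mixture
#'
#' Solves the coupled adsorption/double-layer system for the surface
#' coverages \eqn{\theta_i} and the surface potential \eqn{\psi_s}:
#'
#' 1. Boltzmann subsurface concentrations
#'    \eqn{c_i^s = c_i \exp(-z_i F \psi_s / RT)};
#' 2. mixed Frumkin isotherm
#'    \eqn{b_i c_i^s = \theta_i / (1 - \Sigma_j\theta_j)\,
#'    \exp(-2\Sigma_j a_{ij}\theta_j)};
#' 3. Gouy-Chapman closure equating the adsorbed charge
#'    \eqn{F \Sigma_i z_i\theta_i/\omega_{ref}} to the diffuse-layer charge
#'    \eqn{\sqrt{8\epsilon\epsilon_0 RT I}\,\sinh(F\psi_s/2RT)}.
#'
#' The surface pressure combines the Frumkin equation of state with the
#' electrostatic film contribution:
#' \deqn{\Pi = -\frac{RT}{\omega_{ref}}\left[\ln(1-\Sigma\theta_j) +
#'   \Sigma_{ij} a_{ij}\theta_i\theta_j\right] +
#'   \frac{8RTI}{\kappa}\left[\cosh(F\psi_s/2RT) - 1\right].}
#' A single reference molar area (the first, majority component's) is used
#' in the equation of state.
#'
#' The solver is a damped Newton iteration with concentration continuation
#' from the dilute limit; it is deterministic and converges to residual
#' < 1e-12 on the physical branch (\eqn{\Sigma\theta < 1}).
#'
#' @param system a [mixture_system()].
#' @param c_total total surfactant concentration, mol/dm^3 (>= 0; 0 returns
#'   the clean interface).
#' @param tol residual infinity-norm tolerance.
#' @return list of class `"surface_state"`: `coverages` (named theta_i),
#'   `surface_potential` (V), `surface_pressure` (mN/m),
#'   `ionic_strength` (mol/dm^3), `residual_norm`.
#' @export
#' @examples
#' sys <- mixture_system(surfactant_component("C12", 0, b = 10, omega = 2e5))
#' st <- equilibrium_coverage(sys, 1e-3)
#' st$coverages  # Langmuir: b*c/(1 + b*c) with b*c = 10 * 1 (mol/m^3)
equilibrium_coverage <- function(system, c_total, tol = 1e-12) {
  iso_solve_path(system, c_total, tol = tol)[[1L]]
}

# Solve the adsorption/double-layer system along an ascending concentration
# path, warm-starting each point from the previous solution (continuation).
# Returns one "surface_state" per requested concentration, in input order.
iso_solve_path <- function(system, c_path, tol = 1e-12) {
  if (!inherits(system, "mixture_system")) stopf("system must be a mixture_system")
  c_path <- as.numeric(c_path)
  if (any(!is.finite(c_path)) || any(c_path < 0))
    stopf("concentrations must be finite and >= 0")
  m <- length(system$components)
  names_m <- vapply(system$components, `[[`, "", "name")
  omega_ref <- system$components[[1L]]$omega
  RT <- .const$R * system$temperature
  z <- vapply(system$components, `[[`, 0L, "charge")
  b <- vapply(system$components, `[[`, 0, "b")
  A <- system$interaction
  charged <- any(z != 0L)
  nunk <- m + as.integer(charged)

  clean_state <- structure(list(
    coverages = setNames(rep(0, m), names_m),
    surface_potential = 0, surface_pressure = 0,
    ionic_strength = system$salt_mM / 1000, residual_norm = 0),
    class = "surface_state")

  # per-concentration quantities, updated as the path is walked
  c_SI <- I_SI <- gc_scale <- NULL
  set_conc <- function(cl) {
    sp <- bulk_speciation(system, cl)
    c_SI <<- sp$surfactant$conc * 1000   # mol/m^3
    I_SI <<- sp$ionic_strength * 1000
    gc_scale <<- if (charged)
      sqrt(8 * .const$e0 * .const$eps_w * RT * I_SI) else 1
  }
  resid <- function(u) {
    th <- u[seq_len(m)]
    y <- if (charged) u[m + 1L] else 0
    thT <- sum(th)
    cs <- c_SI * exp(-2 * z * y)
    r <- b * cs * (1 - thT) * exp(2 * as.numeric(A %*% th)) - th
    if (charged) {
      q_surf <- .const$F * sum(z * th) / omega_ref
      r <- c(r, (q_surf - gc_charge(y, I_SI, system$temperature)) / gc_scale)
    }
    r
  }
  solve_from <- function(u0) {
    u <- u0
    r <- resid(u)
    for (it in 1:100) {
      if (max(abs(r)) < tol) break
      J <- matrix(0, nunk, nunk)
      for (j in seq_len(nunk)) {
        h <- max(abs(u[j]), 1e-6) * 1e-7
        up <- u; up[j] <- u[j] + h
        J[, j] <- (resid(up) - r) / h
      }
      step <- tryCatch(solve(J, -r), error = function(e) NULL)
      if (is.null(step)) return(NULL)
      lambda <- 1
      repeat {
        un <- u + lambda * step
        ok <- all(un[seq_len(m)] > -1e-14) && sum(un[seq_len(m)]) < 1 - 1e-12
        if (ok) {
          rn <- resid(un)
          if (max(abs(rn)) < max(abs(r)) || lambda < 1e-6) {
            u <- un; r <- rn; break
          }
        }
        lambda <- lambda / 2
        if (lambda < 1e-10) return(NULL)
      }
    }
    if (max(abs(r)) < tol) list(u = u, rnorm = max(abs(r))) else NULL
  }
  # dilute-limit starting point: theta_i ~ b_i c_i^s with the surface
  # potential from the scalar charge balance (bisection is robust when the
  # double layer dominates at low ionic strength)
  dilute_guess <- function() {
    if (!charged) return(pmin(b * c_SI / (1 + sum(b * c_SI)), 0.5 / m))
    bal <- function(y) {
      th <- pmin(b * c_SI * exp(-2 * z * y), 0.9 / m)
      .const$F * sum(z * th) / omega_ref -
        gc_charge(y, I_SI, system$temperature)
    }
    y0 <- tryCatch(stats::uniroot(bal, c(-60, 60), tol = 1e-12)$root,
                   error = function(e) 0)
    c(pmin(b * c_SI * exp(-2 * z * y0), 0.9 / m), y0)
  }
  solve_at <- function(cl, u_warm) {
    set_conc(cl)
    sol <- if (!is.null(u_warm)) solve_from(u_warm) else NULL
    if (is.null(sol)) sol <- solve_from(dilute_guess())
    if (is.null(sol)) {
      # fall back to a fresh continuation ladder up to this concentration
      u <- NULL
      for (cr in cl * 10^seq(-4, 0, length.out = 9L)) {
        set_conc(cr)
        s <- if (!is.null(u)) solve_from(u) else NULL
        if (is.null(s)) s <- solve_from(dilute_guess())
        if (is.null(s))
          stopf("adsorption solver failed to converge at c = %.4g mol/dm^3 (damped Newton with continuation)", cr)
        u <- s$u
      }
      sol <- s
    }
    sol
  }
  state_of <- function(sol) {
    u <- sol$u
    th <- u[seq_len(m)]
    y <- if (charged) u[m + 1L] else 0
    thT <- sum(th)
    kappa <- if (charged)
      sqrt(2 * .const$F^2 * I_SI / (.const$e0 * .const$eps_w * RT)) else Inf
    Pi_el <- if (charged) (8 * RT * I_SI / kappa) * (cosh(y) - 1) else 0
    Pi <- -(RT / omega_ref) *
      (log(1 - thT) + as.numeric(t(th) %*% A %*% th)) + Pi_el
    structure(list(
      coverages = setNames(th, names_m),
      surface_potential = 2 * RT * y / .const$F,
      surface_pressure = Pi * 1000,  # J/m^2 -> mN/m
      ionic_strength = I_SI / 1000,
      residual_norm = sol$rnorm), class = "surface_state")
  }

  ord <- order(c_path)
  out <- vector("list", length(c_path))
  u_warm <- NULL
  first <- TRUE
  for (i in ord) {
    cl <- c_path[i]
    if (cl == 0) { out[[i]] <- clean_state; next }
    if (first) {
      # approach the first nonzero concentration through a short ladder
      u <- NULL
      for (cr in cl * 10^seq(-4, -0.5, length.out = 8L)) {
        set_conc(cr)
        s <- if (!is.null(u)) solve_from(u) else solve_from(dilute_guess())
        if (is.null(s)) s <- solve_from(dilute_guess())
        if (!is.null(s)) u <- s$u
      }
      u_warm <- u
      first <- FALSE
    }
    sol <- solve_at(cl, u_warm)
    u_warm <- sol$u
    out[[i]] <- state_of(sol)
  }
  out
}

#' @export
print.surface_state <- function(x, ...) {
  cat("Equilibrium surface state\n")
  cat("  coverages:", paste(sprintf("%s=%.4g", names(x$coverages),
                                    x$coverages), collapse = ", "), "\n")
  cat(sprintf("  surface potential %.4g mV, surface pressure %.3f mN/m\n",
              1000 * x$surface_potential, x$surface_pressure))
  invisible(x)
}

#' Equilibrium surface tension of the mixture
#'
#' \eqn{\sigma(c) = \sigma_0 - \Pi(c)} from [equilibrium_coverage()],
#' clamped at \eqn{\sigma(\mathrm{CMC})} above the critical micelle
#' concentration (micellar equilibria themselves are not modelled; above
#' the CMC the monomer activity is pinned). Vectorised over `c_total`.
#'
#' @param system a [mixture_system()].
#' @param c_total total surfactant concentration(s), mol/dm^3 (>= 0).
#' @param cmc override of `system$cmc` (mol/dm^3), or `NULL`.
#' @return numeric vector of surface tensions in mN/m.
#' @export
#' @examples
#' sys <- mixture_system(surfactant_component("C12", 0, b = 50, omega = 2.5e5))
#' surface_tension(sys, c(0, 1e-4, 1e-3))
surface_tension <- function(system, c_total, cmc = NULL) {
  cmc <- cmc %||% system$cmc
  cc <- as.numeric(c_total)
  if (!is.null(cmc)) cc <- pmin(cc, cmc)
  states <- iso_solve_path(system, cc)
  system$solvent_tension -
    vapply(states, `[[`, numeric(1), "surface_pressure")
}

#' Isotherm dataset
#'
#' (concentration, surface tension) pairs measured or generated at one salt
#' condition.
#'
#' @param conc concentrations in mol/dm^3, strictly increasing.
#' @param tension surface tensions in mN/m, within (15, 80).
#' @param salt_mM added salt in mmol/dm^3.
#' @param meta named list of extra labels.
#' @return data.frame of class `"isotherm_dataset"` with columns `conc`,
#'   `tension` and attributes `salt_mM`, `meta`.
#' @export
isotherm_dataset <- function(conc, tension, salt_mM = 0, meta = list()) {
  conc <- as.numeric(conc); tension <- as.numeric(tension)
  if (length(conc) != length(tension))
    stopf("conc and tension must have equal length")
  if (any(diff(conc) <= 0))
    stopf("concentrations must be strictly increasing")
  if (any(tension <= 15 | tension >= 80))
    stopf("tensions must lie within (15, 80) mN/m")
  structure(data.frame(conc = conc, tension = tension),
            salt_mM = salt_mM, meta = as.list(meta),
            class = c("isotherm_dataset", "data.frame"))
}
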