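#' Electrode specification
#'
#' Describes one electrode of the two-electrode cell. The working electrode
#' (anode) carries chloride oxidation, written as the reduction
#' HOCl + H+ + 2e- = Cl- + H2O; the counter electrode (cathode) carries the
#' hydrogen evolution reaction 2 H+ + 2e- = H2. Both transfer two
#' electrons. Potentials are relative to a quasi Ag/AgCl reference; the
#' electrolyte potential is taken as zero everywhere (high-conductivity
#' saline), so the overpotential is eta = phi_applied - E_nernst.
#'
#' @param role `"working"` or `"counter"`; selects default thermodynamic
#'   and kinetic parameters and the reaction stoichiometry.
#' @param E0 standard reduction potential, V vs Ag/AgCl. Defaults: 1.297
#'   (working), -0.197 (counter).
#' @param i0 exchange current density, A/m2. Defaults: 0.032 (working),
#'   0.003 (counter).
#' @param alpha charge-transfer coefficient in (0, 1). Defaults: 0.95
#'   (working), 0.05 (counter).
#' @param potential applied electrode potential, V vs Ag/AgCl. Defaults:
#'   1.5 (working), -0.6 (counter).
#' @param c_ref reference concentration for Nernst ratios, mol/m3
#'   (1 M standard state).
#' @return list of class `electrode_spec`.
#' @export
electrode_spec <- function(role = c("working", "counter"),
                           E0 = NULL, i0 = NULL, alpha = NULL,
                           potential = NULL, c_ref = .CREF) {
  role <- match.arg(role)
  def <- if (role == "working")
    list(E0 = 1.297, i0 = 0.032, alpha = 0.95, potential = 1.5)
  else
    list(E0 = -0.197, i0 = 0.003, alpha = 0.05, potential = -0.6)
  spec <- list(
    role = role,
    E0 = if (is.null(E0)) def$E0 else E0,
    i0 = if (is.null(i0)) def$i0 else i0,
    alpha = if (is.null(alpha)) def$alpha else alpha,
    potential = if (is.null(potential)) def$potential else potential,
    n_electrons = 2,
    c_ref = c_ref
  )
  if (spec$alpha <= 0 || spec$alpha >= 1) stop("alpha must lie in (0, 1)")
  if (spec$i0 <= 0) stop("i0 must be positive")
  # stoichiometry of the reduction direction (nu < 0: consumed on reduction)
  nm <- species_names()
  nu <- stats::setNames(numeric(10), nm)
  if (role == "working") {
    nu[c("HOCl", "H", "Cl")] <- c(-1, -1, 1)
  } else {
    nu[c("H", "H2")] <- c(-2, 1)
  }
  spec$nu_red <- nu
  class(spec) <- "electrode_spec"
  spec
}

#' Nernst potential from local composition
#'
#' Working electrode:
#' E = E0 - (RT/2F) ln\[(c_H/c_ref)^-1 (c_HOCl/c_ref)^-1 (c_Cl/c_ref)\];
#' counter electrode: E = E0 - (RT/2F) ln\[(c_H/c_ref)^-2 (c_H2/c_ref)\].
#' Concentrations are floored at 1e-12 mol/m3 inside the logarithms, which
#' regularizes the initially product-free state (large but finite driving
#' force).
#'
#' @param spec an [electrode_spec()].
#' @param c composition, named vector of length 10 or 10 x K matrix
#'   (mol/m3).
#' @param T absolute temperature, K.
#' @return Nernst potential(s), V vs Ag/AgCl (one per column of `c`).
#' @export
nernst_potential <- function(spec, c, T) {
  cm <- .as_cmat(c)
  cl <- pmax(cm, .EPS_C) / spec$c_ref
  pref <- .RGAS * T / (spec$n_electrons * .FARADAY)
  if (spec$role == "working") {
    lnQ <- -log(cl["H", ]) - log(cl["HOCl", ]) + log(cl["Cl", ])
  } else {
    lnQ <- -2 * log(cl["H", ]) + log(cl["H2", ])
  }
  unname(spec$E0 - pref * lnQ)
}

#' Butler-Volmer current density
#'
#' i = i0 (exp((1-alpha) F eta / RT) - exp(-alpha F eta / RT)), anodic
#' positive. Exponent arguments are capped at +/-50 to guard against
#' overflow; the cap never binds at the device's operating potentials.
#'
#' @param spec an [electrode_spec()].
#' @param eta overpotential, V (vectorized).
#' @param T absolute temperature, K.
#' @return current density, A/m2.
#' @examples
#' we <- electrode_spec("working")
#' butler_volmer(we, 0.2, 298.15)
#' @export
butler_volmer <- function(spec, eta, T) {
  f <- .FARADAY / (.RGAS * T)
  a1 <- pmin(pmax((1 - spec$alpha) * f * eta, -.EXP_CAP), .EXP_CAP)
  a2 <- pmin(pmax(-spec$alpha * f * eta, -.EXP_CAP), .EXP_CAP)
  spec$i0 * (exp(a1) - exp(a2))
}

#' Full electrode state: Nernst potential, overpotential, current, fluxes
#'
#' Chains Nernst -> overpotential -> Butler-Volmer -> Faraday's law. The
#' reduction-direction area rate is r_e = -i/(2F); per-species surface
#' fluxes are nu_red * r_e, so positive anodic current at the working
#' electrode consumes Cl- and releases HOCl and H+, and cathodic current
#' at the counter electrode consumes H+ and releases H2.
#'
#' @inheritParams nernst_potential
#' @param polarized logical; `FALSE` models open circuit (zero current and
#'   fluxes regardless of composition).
#' @return list of class `electrode_state` with elements `E`, `eta`, `i`
#'   (A/m2), `r_e` (mol/(m2 s), reduction direction) and `flux` (10 x K
#'   matrix of per-species surface fluxes, mol/(m2 s), positive into
#'   solution).
#' @export
electrode_state <- function(spec, c, T, polarized = TRUE) {
  E <- nernst_potential(spec, c, T)
  if (!polarized) {
    K <- length(E)
    st <- list(E = E, eta = rep(0, K), i = rep(0, K), r_e = rep(0, K),
               flux = matrix(0, 10, K, dimnames = list(species_names(), NULL)))
    class(st) <- "electrode_state"
    return(st)
  }
  eta <- spec$potential - E
  i <- butler_volmer(spec, eta, T)
  r_e <- -i / (spec$n_electrons * .FARADAY)
  flux <- outer(spec$nu_red, r_e)
  rownames(flux) <- species_names()
  st <- list(E = E, eta = eta, i = i, r_e = r_e, flux = flux)
  class(st) <- "electrode_state"
  st
}
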