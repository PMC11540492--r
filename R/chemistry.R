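#' Homogeneous chemistry parameters
#'
#' Assembles the rate and equilibrium constants of the homogeneous
#' chemistry: the two kinetically-relaxed acid-base equilibria (HOCl
#' dissociation and water autoionization) and the four-reaction HOCl
#' degradation network
#' \itemize{
#'   \item K0: HOCl -> H+ + Cl- + 1/2 O2 (first order)
#'   \item K1: 2 HOCl -> 2 H+ + Cl- + ClO2- (second order in HOCl)
#'   \item K2: HOCl + ClO2- -> H+ + Cl- + ClO3-
#'   \item K3: HOCl + ClO- -> H+ + Cl- + ClO2-
#' }
#' The chlorite/chlorate products are treated as fully dissociated strong
#' acids, so every degradation step releases H+ into the unbuffered
#' electrolyte. Tabulated constants are given at their literature reference
#' temperatures (K0-K2 at 30 C, K3 at 60 C) and moved to the local cell
#' temperature with [arrhenius_adjust()].
#'
#' @param overrides named list overriding any default. Rate constants are
#'   accepted in their tabulated units: `K0` in 1/min, `K1`..`K3` in
#'   L/(mol min), `ka` in 1/s, `ka_star` in mol/(m3 s), equilibrium
#'   constants in mol/m3 (`Ka_HOCl`) and mol2/m6 (`Ka_H2O`), activation
#'   energies `Ea_K0`..`Ea_K3` in kcal/mol.
#' @return list of class `chem_params` with all constants converted to SI
#'   (1/s, m3/(mol s)) plus the stoichiometry matrices used by the rate
#'   assembly.
#' @export
chem_params <- function(overrides = list()) {
  p <- list(
    ka       = 1000,      # 1/s, arbitrarily large: equilibria treated kinetically
    ka_star  = 1000,      # mol/(m3 s)
    Ka_HOCl  = 3.16e-5,   # mol/m3
    Ka_H2O   = 1e-8,      # mol2/m6
    K0 = 4.65e-4,         # 1/min at 30 C
    K1 = 4.5e-1,          # L/(mol min) at 30 C
    K2 = 3e-3,            # L/(mol min) at 30 C
    K3 = 7.5e-6,          # L/(mol min) at 60 C
    Ea_K0 = 19, Ea_K1 = 15, Ea_K2 = 15, Ea_K3 = 15,  # kcal/mol
    Tref_K0 = 303.15, Tref_K1 = 303.15, Tref_K2 = 303.15, Tref_K3 = 333.15,
    # speciation rate constants tabulated alongside the network but not tied
    # to any modelled reaction; parsed and stored, unused by the default model
    k_HOCl = 3.4, k_ClO = 44000, Ea_HOCl = 7.7, Ea_ClO = 11.6
  )
  unknown <- setdiff(names(overrides), names(p))
  if (length(unknown)) stop("unknown chemistry parameters: ",
                            paste(unknown, collapse = ", "))
  p[names(overrides)] <- overrides
  for (nm in c("ka", "ka_star", "Ka_HOCl", "Ka_H2O", "K0", "K1", "K2", "K3"))
    if (p[[nm]] <= 0) stop(nm, " must be positive")

  # SI conversions, done once at load time
  p$K0_SI <- per_min_to_per_s(p$K0)
  p$K1_SI <- L_per_mol_min_to_SI(p$K1)
  p$K2_SI <- L_per_mol_min_to_SI(p$K2)
  p$K3_SI <- L_per_mol_min_to_SI(p$K3)

  nm <- species_names()
  # stoichiometry: columns are reactions, rows species (signed product counts)
  Seq <- matrix(0, 10, 2, dimnames = list(nm, c("HOCl_diss", "water")))
  Seq[c("HOCl", "ClO", "H"), "HOCl_diss"] <- c(-1, 1, 1)
  Seq[c("OH", "H"), "water"] <- c(1, 1)
  Sdeg <- matrix(0, 10, 4, dimnames = list(nm, c("K0", "K1", "K2", "K3")))
  Sdeg[c("HOCl", "H", "Cl", "O2"),         "K0"] <- c(-1, 1, 1, 0.5)
  Sdeg[c("HOCl", "H", "Cl", "ClO2"),       "K1"] <- c(-2, 2, 1, 1)
  Sdeg[c("HOCl", "ClO2", "H", "Cl", "ClO3"), "K2"] <- c(-1, -1, 1, 1, 1)
  Sdeg[c("HOCl", "ClO", "H", "Cl", "ClO2"),  "K3"] <- c(-1, -1, 1, 1, 1)
  p$S_eq <- Seq
  p$S_deg <- Sdeg
  class(p) <- "chem_params"
  p
}

#' Arrhenius temperature correction of a rate constant
#'
#' Moves a rate constant from its reference temperature to the local
#' temperature: k(T) = k(T_ref) * exp(-(Ea/R) * (1/T - 1/T_ref)), with Ea
#' in kcal/mol and R = 1.9872e-3 kcal/(mol K).
#'
#' @param k_ref rate constant at `T_ref` (any units; returned in the same).
#' @param Ea activation energy, kcal/mol.
#' @param T_ref,T reference and target absolute temperatures, K. Both must
#'   lie in (250, 400).
#' @return rate constant at `T`.
#' @examples
#' arrhenius_adjust(4.65e-4, 19, 303.15, 298.15)
#' @export
arrhenius_adjust <- function(k_ref, Ea, T_ref, T) {
  if (any(!is.finite(c(T, T_ref))) || any(c(T, T_ref) <= 250) || any(c(T, T_ref) >= 400))
    stop("temperatures must lie in (250, 400) K")
  if (any(k_ref <= 0)) stop("k_ref must be positive")
  k_ref * exp(-(Ea / .RGAS_KCAL) * (1 / T - 1 / T_ref))
}

# degradation rate constants (SI) adjusted to temperature(s) T; returns a
# 4 x length(T) matrix
.deg_constants_at <- function(chem, T) {
  rbind(
    K0 = arrhenius_adjust(chem$K0_SI, chem$Ea_K0, chem$Tref_K0, T),
    K1 = arrhenius_adjust(chem$K1_SI, chem$Ea_K1, chem$Tref_K1, T),
    K2 = arrhenius_adjust(chem$K2_SI, chem$Ea_K2, chem$Tref_K2, T),
    K3 = arrhenius_adjust(chem$K3_SI, chem$Ea_K3, chem$Tref_K3, T)
  )
}

# coerce a composition to a 10 x K matrix
.as_cmat <- function(c) {
  if (is.matrix(c)) {
    if (nrow(c) != 10) stop("composition matrix must have 10 rows (species)")
    c
  } else {
    if (length(c) != 10) stop("composition must have 10 entries")
    matrix(c, nrow = 10, dimnames = list(species_names(), NULL))
  }
}

#' Per-species rates of the kinetically-relaxed equilibria
#'
#' HOCl dissociation proceeds at r = ka (c_HOCl - c_ClO c_H / Ka_HOCl) and
#' water autoionization at r = ka* (1 - c_OH c_H / Ka_H2O); both vanish
#' exactly when the mass-action quotients equal their equilibrium
#' constants.
#'
#' @param c composition: named vector of length 10 or a 10 x K matrix
#'   (mol/m3).
#' @param chem a [chem_params()] object.
#' @return per-species rates, same shape as `c`, mol/(m3 s).
#' @export
equilibrium_rates <- function(c, chem = chem_params()) {
  cm <- .as_cmat(c)
  r1 <- chem$ka * (cm["HOCl", ] - cm["ClO", ] * cm["H", ] / chem$Ka_HOCl)
  r2 <- chem$ka_star * (1 - cm["OH", ] * cm["H", ] / chem$Ka_H2O)
  out <- chem$S_eq %*% rbind(r1, r2)
  if (is.matrix(c)) out else stats::setNames(drop(out), species_names())
}

#' Per-species rates of the HOCl degradation network
#'
#' Applies the four degradation reactions at rate constants
#' Arrhenius-adjusted to `T`. The stoichiometry conserves chlorine atoms
#' exactly and every step produces H+.
#'
#' @inheritParams equilibrium_rates
#' @param T absolute temperature, K (scalar or one per column of `c`).
#' @return per-species rates, same shape as `c`, mol/(m3 s).
#' @export
degradation_rates <- function(c, T, chem = chem_params()) {
  cm <- .as_cmat(c)
  kd <- .deg_constants_at(chem, T)  # 4 x length(T)
  hocl <- cm["HOCl", ]
  r <- rbind(
    kd["K0", ] * hocl,
    kd["K1", ] * hocl^2,
    kd["K2", ] * hocl * cm["ClO2", ],
    kd["K3", ] * hocl * cm["ClO", ]
  )
  out <- chem$S_deg %*% r
  if (is.matrix(c)) out else stats::setNames(drop(out), species_names())
}

#' Net homogeneous chemistry rates (equilibria + degradation)
#' @inheritParams degradation_rates
#' @return per-species net rates, same shape as `c`, mol/(m3 s).
#' @export
chemistry_rates <- function(c, T, chem = chem_params()) {
  equilibrium_rates(c, chem) + degradation_rates(c, T, chem)
}
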