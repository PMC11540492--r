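# Physical constants (SI unless noted)
.FARADAY <- 96485.33212    # C/mol
.RGAS    <- 8.31446        # J/(mol K)
.RGAS_KCAL <- 1.9872e-3    # kcal/(mol K), for activation energies printed in kcal/mol
.CREF    <- 1000           # mol/m3; 1 M standard state for Nernst concentration ratios
.EPS_C   <- 1e-12          # mol/m3 concentration floor, applied inside logarithms only
.EXP_CAP <- 50             # cap on Butler-Volmer exponent arguments

#' Unit conversion helpers used when loading tabulated rate constants
#'
#' Degradation rate constants are tabulated per minute (first order) or in
#' L/(mol min) (second order); internally everything runs in SI:
#' 1/s and m3/(mol s).
#'
#' @param k rate constant in tabulated units
#' @return rate constant in SI units
#' @keywords internal
#' @name unit-conversions
NULL

#' @rdname unit-conversions
per_min_to_per_s <- function(k) k / 60

#' @rdname unit-conversions
L_per_mol_min_to_SI <- function(k) k * 1e-3 / 60
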