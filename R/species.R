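#' The tracked chemical species
#'
#' Ten species are tracked: HOCl, ClO-, ClO2-, ClO3-, O2, H+, H2, OH-,
#' Cl-, Na+. Each carries a signed charge (elementary units), a chlorine
#' atom count (for conservation audits) and a diffusion coefficient in
#' water at 298 K. All concentrations throughout the package are molar
#' concentrations in mol/m3 (numerically equal to mM).
#'
#' Default diffusivities are for dilute aqueous solution at 25 C. ClO-,
#' ClO2- and ClO3- share a generic 1e-9 m2/s value; O2 uses the standard
#' literature value 2.1e-9 m2/s.
#'
#' @param D298 optional named numeric vector overriding diffusion
#'   coefficients (m2/s) for a subset of species.
#' @return a data.frame with columns `name`, `charge`, `cl_atoms`, `D298`,
#'   one row per species, class `species_set`.
#' @examples
#' sp <- species_set()
#' sp$D298[sp$name == "HOCl"]
#' @export
species_set <- function(D298 = NULL) {
  sp <- data.frame(
    name     = c("HOCl", "ClO", "ClO2", "ClO3", "O2", "H", "H2", "OH", "Cl", "Na"),
    charge   = c(0L, -1L, -1L, -1L, 0L, 1L, 0L, -1L, -1L, 1L),
    cl_atoms = c(1L, 1L, 1L, 1L, 0L, 0L, 0L, 0L, 1L, 0L),
    D298     = c(1.14e-9, 1e-9, 1e-9, 1e-9, 2.1e-9,
                 9.31e-9, 6.30e-9, 5.27e-9, 1.032e-9, 1.334e-9),
    stringsAsFactors = FALSE
  )
  if (!is.null(D298)) {
    if (is.null(names(D298)) || !all(names(D298) %in% sp$name))
      stop("D298 overrides must be named with species among: ",
           paste(sp$name, collapse = ", "))
    if (any(D298 <= 0)) stop("diffusion coefficients must be positive")
    sp$D298[match(names(D298), sp$name)] <- unname(D298)
  }
  class(sp) <- c("species_set", "data.frame")
  sp
}

#' Species names in canonical order
#' @return character vector of length 10
#' @export
species_names <- function() species_set()$name

# index lookup with validation
.sp_idx <- function(species) {
  i <- match(species, species_names())
  if (anyNA(i)) stop("unknown species: ", paste(species[is.na(i)], collapse = ", "))
  i
}

#' Initial electrolyte composition from pH and NaCl content
#'
#' The catheter is filled with unbuffered saline whose pH has been adjusted
#' with a strong acid (HCl). Given the initial pH and the NaCl
#' concentration, the ionic composition follows in closed form from the
#' water autoionization mass action law and the charge balance:
#' c_H = 1000 * 10^(-pH0), c_OH = Ka_H2O / c_H, c_Na = C_NaCl and
#' c_Cl = c_Na + c_H - c_OH. All other species start at zero.
#'
#' @param pH0 initial pH (0 < pH0 < 14). Default 5.5.
#' @param C_NaCl NaCl concentration in mol/m3. Default 154.04 (0.9% saline).
#' @param Ka_H2O water autoionization constant, mol2/m6.
#' @return named numeric vector of length 10, mol/m3.
#' @examples
#' c0 <- initial_composition(5.5, 154.04)
#' sum(c0 * species_set()$charge)  # electroneutral by construction
#' @export
initial_composition <- function(pH0 = 5.5, C_NaCl = 154.04, Ka_H2O = 1e-8) {
  if (!is.finite(pH0) || pH0 <= 0 || pH0 >= 14)
    stop("pH0 must lie in (0, 14), got ", pH0)
  if (!is.finite(C_NaCl) || C_NaCl <= 0)
    stop("C_NaCl must be positive, got ", C_NaCl)
  cH  <- 1000 * 10^(-pH0)
  cOH <- Ka_H2O / cH
  cCl <- C_NaCl + cH - cOH
  c0 <- stats::setNames(numeric(10), species_names())
  c0["H"]  <- cH
  c0["OH"] <- cOH
  c0["Na"] <- C_NaCl
  c0["Cl"] <- cCl
  c0
}
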