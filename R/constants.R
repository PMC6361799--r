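# Global unit system: Angstrom, kcal/mol, elementary charge e, Kelvin, femtosecond.

#' Physical constants used throughout bindscope
#'
#' All energies are in kcal/mol, distances in Angstrom, charges in units of the
#' elementary charge e, temperatures in Kelvin.
#'
#' @return A named list with elements:
#'   \describe{
#'     \item{kB}{Boltzmann constant, 0.0019872041 kcal mol^-1 K^-1.}
#'     \item{coulomb}{Coulomb conversion factor, 332.0637 kcal A mol^-1 e^-2.}
#'     \item{temperature}{Default temperature, 300 K.}
#'     \item{probe_radius}{Default solvent probe radius, 1.4 A.}
#'   }
#' @examples
#' bindscope_constants()$kB * 300  # KT at 300 K, kcal/mol
#' @export
bindscope_constants <- function() {
  list(
    kB = 0.0019872041,
    coulomb = 332.0637,
    temperature = 300,
    probe_radius = 1.4
  )
}

.kB <- 0.0019872041
.kCoulomb <- 332.0637
.default_temperature <- 300

# Bondi-style van der Waals radii (A) by element, used for SASA and as the basis
# of GB intrinsic radii. Overridable wherever radii enter a computation.
.element_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
.default_element_radius <- 1.70

# Hawkins-Cramer-Truhlar descreening scale factors by element and the radius
# offset subtracted from the vdW radius to form GB intrinsic radii.
.gb_scale_factors <- c(H = 0.85, C = 0.72, N = 0.79, O = 0.85, S = 0.96, P = 0.86)
.default_gb_scale <- 0.80
.gb_radius_offset <- 0.09

#' Per-element van der Waals radii
#'
#' Look up the van der Waals radius for each element symbol, falling back to a
#' carbon-like default for unknown elements.
#'
#' @param element Character vector of element symbols (case-insensitive).
#' @return Numeric vector of radii in Angstrom.
#' @examples
#' element_radii(c("C", "O", "H"))
#' @export
element_radii <- function(element) {
  r <- .element_radii[toupper(element)]
  r[is.na(r)] <- .default_element_radius
  unname(r)
}
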