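#' Physical constants used in mass arithmetic
#'
#' Monoisotopic masses (Da) of the particles and small molecules that enter
#' every fragment-mass equation, derived from CODATA/IUPAC isotopic atomic
#' masses.
#'
#' @format A named list with elements `proton_mass`, `water_mass`,
#'   `ammonia_mass`, `hydrogen_mass` and `isotope_spacing` (the 13C-12C mass
#'   difference used for isotope-cluster spacing), all in Da.
#' @export
#' @examples
#' physical_constants$proton_mass
physical_constants <- list(
  proton_mass     = 1.00727646688,
  water_mass      = 18.0105646863,
  ammonia_mass    = 17.0265491015,
  hydrogen_mass   = 1.00782503207,
  isotope_spacing = 1.0033548378
)

# Monoisotopic atomic masses of the lightest isotopes (Da).
.atomic_mass <- c(
  H = 1.00782503207,
  C = 12.0,
  N = 14.0030740048,
  O = 15.9949146196,
  S = 31.97207100
)

# Elemental composition of the 20 canonical amino-acid residues
# (i.e. the in-chain residue: amino acid minus water).
.residue_composition <- list(
  G = c(C = 2,  H = 3,  N = 1, O = 1),
  A = c(C = 3,  H = 5,  N = 1, O = 1),
  S = c(C = 3,  H = 5,  N = 1, O = 2),
  P = c(C = 5,  H = 7,  N = 1, O = 1),
  V = c(C = 5,  H = 9,  N = 1, O = 1),
  T = c(C = 4,  H = 7,  N = 1, O = 2),
  C = c(C = 3,  H = 5,  N = 1, O = 1, S = 1),
  L = c(C = 6,  H = 11, N = 1, O = 1),
  I = c(C = 6,  H = 11, N = 1, O = 1),
  N = c(C = 4,  H = 6,  N = 2, O = 2),
  D = c(C = 4,  H = 5,  N = 1, O = 3),
  Q = c(C = 5,  H = 8,  N = 2, O = 2),
  K = c(C = 6,  H = 12, N = 2, O = 1),
  E = c(C = 5,  H = 7,  N = 1, O = 3),
  M = c(C = 5,  H = 9,  N = 1, O = 1, S = 1),
  H = c(C = 6,  H = 7,  N = 3, O = 1),
  F = c(C = 9,  H = 9,  N = 1, O = 1),
  R = c(C = 6,  H = 12, N = 4, O = 1),
  Y = c(C = 9,  H = 9,  N = 1, O = 2),
  W = c(C = 11, H = 10, N = 2, O = 1)
)

.composition_mass <- function(comp) {
  sum(.atomic_mass[names(comp)] * comp)
}

#' Monoisotopic residue mass table
#'
#' Masses of the 20 canonical amino-acid residues (the in-chain residue, i.e.
#' amino acid minus water), computed from their elemental composition and the
#' monoisotopic atomic masses of the lightest isotopes. Ambiguity codes
#' (B/Z/X) are deliberately absent: annotation requires exact masses.
#'
#' @return Named numeric vector of 20 monoisotopic residue masses in Da.
#' @export
#' @examples
#' residue_masses()[["G"]]  # 57.02146
residue_masses <- function() {
  vapply(.residue_composition, .composition_mass, numeric(1))
}

#' Elemental compositions of the canonical residues
#'
#' @return Named list mapping one-letter residue codes to named integer
#'   vectors of element counts (in-chain residue composition).
#' @export
residue_compositions <- function() {
  .residue_composition
}
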