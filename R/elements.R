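# Element reference data.
#
# Covalent radii: Cordero et al. single-bond radii (Angstrom). For Mn/Fe/Co
# the low-spin values are used. These feed the distance criterion
# d < r_i + r_j + tolerance with the default 0.45 A tolerance.
.covalentRadii <- c(
  H = 0.31, He = 0.28,
  Li = 1.28, Be = 0.96, B = 0.84, C = 0.76, N = 0.71, O = 0.66, F = 0.57,
  Ne = 0.58,
  Na = 1.66, Mg = 1.41, Al = 1.21, Si = 1.11, P = 1.07, S = 1.05, Cl = 1.02,
  Ar = 1.06,
  K = 2.03, Ca = 1.76,
  Sc = 1.70, Ti = 1.60, V = 1.53, Cr = 1.39, Mn = 1.39, Fe = 1.32, Co = 1.26,
  Ni = 1.24, Cu = 1.32, Zn = 1.22,
  Ga = 1.22, Ge = 1.20, As = 1.19, Se = 1.20, Br = 1.20, Kr = 1.16,
  Rb = 2.20, Sr = 1.95,
  Y = 1.90, Zr = 1.75, Nb = 1.64, Mo = 1.54, Tc = 1.47, Ru = 1.46, Rh = 1.42,
  Pd = 1.39, Ag = 1.45, Cd = 1.44,
  In = 1.42, Sn = 1.39, Sb = 1.39, Te = 1.38, I = 1.39, Xe = 1.40,
  Cs = 2.44, Ba = 2.15, La = 2.07,
  Hf = 1.75, Ta = 1.70, W = 1.62, Re = 1.51, Os = 1.44, Ir = 1.41, Pt = 1.36,
  Au = 1.36, Hg = 1.32,
  Tl = 1.45, Pb = 1.46, Bi = 1.48)

# d-block element symbols (groups 3-12, periods 4-6); a complex must contain
# exactly one of these to be treated as mononuclear.
.dBlock <- c("Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
             "Y", "Zr", "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd",
             "La", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg")

# Valence electron counts V_i (main-group s+p; d-block s+d) used in the
# occupancy formula q = sum(V_i) - 2 * #(doubly occupied MOs).
.valenceElectrons <- c(
  H = 1, He = 2,
  Li = 1, Be = 2, B = 3, C = 4, N = 5, O = 6, F = 7, Ne = 8,
  Na = 1, Mg = 2, Al = 3, Si = 4, P = 5, S = 6, Cl = 7, Ar = 8,
  K = 1, Ca = 2,
  Sc = 3, Ti = 4, V = 5, Cr = 6, Mn = 7, Fe = 8, Co = 9, Ni = 10, Cu = 11,
  Zn = 12,
  Ga = 3, Ge = 4, As = 5, Se = 6, Br = 7, Kr = 8,
  Rb = 1, Sr = 2,
  Y = 3, Zr = 4, Nb = 5, Mo = 6, Tc = 7, Ru = 8, Rh = 9, Pd = 10, Ag = 11,
  Cd = 12,
  In = 3, Sn = 4, Sb = 5, Te = 6, I = 7, Xe = 8,
  Cs = 1, Ba = 2, La = 3,
  Hf = 4, Ta = 5, W = 6, Re = 7, Os = 8, Ir = 9, Pt = 10, Au = 11, Hg = 12,
  Tl = 3, Pb = 4, Bi = 5)

# Maximum neighbor counts enforced on non-metal atoms when trimming the
# perceived connectivity. Halogens are capped at one neighbor: a halogen
# with more perceived neighbors (the perchlorate case) has its excess bonds
# cut, which is the documented source of stranded O atoms and artificially
# high oxidation states. Metals are exempt.
.maxValence <- c(
  H = 1, B = 4, C = 4, N = 4, O = 3, F = 1, Si = 4, P = 6, S = 6, Cl = 1,
  Br = 1, I = 1, Se = 6, As = 5, Ge = 4, Sn = 4, Sb = 5, Te = 6, Al = 4,
  Ga = 4, In = 4, Tl = 4, Pb = 4, Bi = 5)

.maxValenceFor <- function(el, config = tmcConfig()) {
  out <- unname(config$maxValence[el])
  out[is.na(out)] <- 6L  # permissive fallback for rarely seen elements
  as.integer(out)
}

# Allowed Lewis valence states: per element, admissible (bond-order sum,
# formal charge) pairs tried in listed order during enumeration. The carbene
# state for carbon (two single bonds, charge 0, one lone pair) is appended
# only when carbenes are allowed and the carbon has exactly two sigma
# neighbors in the fragment.
.lewisStates <- list(
  H  = list(c(1L, 0L), c(0L, -1L)),  # hydride: a bare H fragment is H-
  B  = list(c(3L, 0L), c(4L, -1L)),
  C  = list(c(4L, 0L), c(3L, -1L), c(3L, 1L)),
  N  = list(c(3L, 0L), c(4L, 1L), c(2L, -1L), c(0L, -3L)),  # incl. nitride
  O  = list(c(2L, 0L), c(1L, -1L), c(3L, 1L), c(0L, -2L)),
  F  = list(c(1L, 0L), c(0L, -1L)),
  Cl = list(c(1L, 0L), c(0L, -1L)),
  Br = list(c(1L, 0L), c(0L, -1L)),
  I  = list(c(1L, 0L), c(0L, -1L)),
  Si = list(c(4L, 0L)),
  P  = list(c(3L, 0L), c(5L, 0L), c(4L, 1L)),
  S  = list(c(2L, 0L), c(4L, 0L), c(6L, 0L), c(1L, -1L), c(3L, 1L),
            c(0L, -2L)),
  Se = list(c(2L, 0L), c(4L, 0L), c(6L, 0L), c(1L, -1L)),
  As = list(c(3L, 0L), c(5L, 0L), c(4L, 1L)),
  Te = list(c(2L, 0L), c(4L, 0L), c(6L, 0L), c(1L, -1L)))

# Extended Hueckel valence-shell parameters: H_ii (eV, negative of the VSIP)
# and Slater exponents (bohr^-1) of the classic Hoffmann table; one s and
# one p shell per main-group element (H: s only).
.ehtParams <- list(
  H  = list(shells = data.frame(l = 0L, n = 1L, hii = -13.6, zeta = 1.300)),
  B  = list(shells = data.frame(l = c(0L, 1L), n = c(2L, 2L),
                                hii = c(-15.2, -8.5), zeta = c(1.300, 1.300))),
  C  = list(shells = data.frame(l = c(0L, 1L), n = c(2L, 2L),
                                hii = c(-21.4, -11.4), zeta = c(1.625, 1.625))),
  N  = list(shells = data.frame(l = c(0L, 1L), n = c(2L, 2L),
                                hii = c(-26.0, -13.4), zeta = c(1.950, 1.950))),
  O  = list(shells = data.frame(l = c(0L, 1L), n = c(2L, 2L),
                                hii = c(-32.3, -14.8), zeta = c(2.275, 2.275))),
  F  = list(shells = data.frame(l = c(0L, 1L), n = c(2L, 2L),
                                hii = c(-40.0, -18.1), zeta = c(2.425, 2.425))),
  Si = list(shells = data.frame(l = c(0L, 1L), n = c(3L, 3L),
                                hii = c(-17.3, -9.2), zeta = c(1.383, 1.383))),
  P  = list(shells = data.frame(l = c(0L, 1L), n = c(3L, 3L),
                                hii = c(-18.6, -14.0), zeta = c(1.750, 1.300))),
  S  = list(shells = data.frame(l = c(0L, 1L), n = c(3L, 3L),
                                hii = c(-20.0, -11.0), zeta = c(2.122, 1.827))),
  Cl = list(shells = data.frame(l = c(0L, 1L), n = c(3L, 3L),
                                hii = c(-26.3, -14.2), zeta = c(2.183, 1.733))),
  Br = list(shells = data.frame(l = c(0L, 1L), n = c(4L, 4L),
                                hii = c(-22.07, -13.1), zeta = c(2.588, 2.131))),
  I  = list(shells = data.frame(l = c(0L, 1L), n = c(5L, 5L),
                                hii = c(-18.0, -12.7), zeta = c(2.679, 2.322))))

#' Element reference tables
#'
#' Returns the package's element tables: covalent radii (Angstrom), maximum
#' neighbor counts used for valence trimming, and valence electron counts.
#'
#' @return a list with components \code{covalentRadius}, \code{maxValence}
#'   and \code{nValenceElectrons}, each a named numeric vector.
#' @examples
#' elementTables()$covalentRadius[["C"]]
#' @export
elementTables <- function() {
  list(covalentRadius = .covalentRadii,
       maxValence = .maxValence,
       nValenceElectrons = .valenceElectrons)
}

#' Test whether element symbols are d-block (transition) metals
#'
#' @param elements character vector of element symbols.
#' @return logical vector.
#' @examples
#' isDBlock(c("Fe", "C", "Pt"))
#' @export
isDBlock <- function(elements) elements %in% .dBlock
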