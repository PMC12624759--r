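# Element and residue reference tables shared across modules.

# Bondi-style van der Waals radii (Angstrom); unknown elements fall back to
# 1.70 with a warning at assignment time.
.VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
.VDW_DEFAULT <- 1.70

# Standard atomic weights (amu) for mass-weighted fits and centers of mass.
.ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904
)
.MASS_DEFAULT <- 12.011

# Monoisotopic element masses (amu).
.MONO_H <- 1.0078250319
.MONO_O <- 15.9949146221

# Monoisotopic amino-acid residue masses (amu), residue = amino acid - water.
.RESIDUE_MASSES <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

.WATER_MASS <- 18.0105646
# C-terminal amidation: -OH +NH2
.AMIDE_DELTA <- -0.9840156

.HYDROPHOBIC_RESIDUES <- c("A", "V", "L", "I", "M", "F", "W", "P")
.AROMATIC_RESIDUES <- c("F", "W", "Y", "H")

.AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)
.AA1 <- setNames(names(.AA3), .AA3)

.BACKBONE_NAMES <- c("N", "CA", "C", "O")

#' Look up van der Waals radii for element symbols
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of radii in Angstrom; unknown elements get 1.70
#'   with a one-time warning.
#' @export
vdw_radius <- function(elements) {
  key <- toupper(elements)
  r <- .VDW_RADII[key]
  if (anyNA(r)) {
    unknown <- unique(key[is.na(r)])
    warning("unknown element(s) ", paste(unknown, collapse = ", "),
            "; using default vdW radius ", .VDW_DEFAULT, " A")
    r[is.na(r)] <- .VDW_DEFAULT
  }
  unname(r)
}

#' Look up standard atomic masses for element symbols
#'
#' @param elements character vector of element symbols.
#' @return numeric vector of masses in amu (unknown elements get carbon mass).
#' @export
atomic_mass <- function(elements) {
  key <- toupper(elements)
  m <- .ATOMIC_MASSES[key]
  m[is.na(m)] <- .MASS_DEFAULT
  unname(m)
}
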