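#' Kyte-Doolittle hydropathy scale
#'
#' Hydropathy values for the 20 canonical amino acids (dimensionless;
#' positive = hydrophobic). Used to order reachable amino-acid sets and
#' substitution reports "decreasing hydrophobicity, left to right".
#'
#' @format Named numeric vector of length 20 (names are one-letter codes).
#' @export
KD_HYDROPATHY <- c(
  I =  4.5, V =  4.2, L =  3.8, F =  2.8, C =  2.5, M =  1.9, A =  1.8,
  G = -0.4, T = -0.7, S = -0.8, W = -0.9, Y = -1.3, P = -1.6, H = -3.2,
  E = -3.5, Q = -3.5, D = -3.5, N = -3.5, K = -3.9, R = -4.5
)

#' Hydropathy rank order with fixed tie-break
#'
#' Total order over the 20 amino acids: decreasing Kyte-Doolittle value,
#' with the single tied group (E, Q, D, N, all at -3.5) broken by the fixed
#' priority E < Q < D < N. All hydropathy-ordered strings produced by the
#' package follow this order.
#'
#' @format Character vector of length 20, most hydrophobic first.
#' @export
KD_ORDER <- c("I", "V", "L", "F", "C", "M", "A", "G", "T", "S",
              "W", "Y", "P", "H", "E", "Q", "D", "N", "K", "R")

# stop sentinel used in translated sequences
STOP_CHAR <- "*"

DNA_BASES <- c("A", "C", "G", "T")

AA_CODES <- names(KD_HYDROPATHY)

#' Maximum residue solvent-accessible areas (Miller et al.)
#'
#' Maximum possible solvent-accessible surface area per residue type
#' (Angstrom^2), from the Gly-X-Gly tripeptide survey of Miller et al.
#' (1987, J Mol Biol 196:641). Denominators for relative surface
#' accessibility (RSA).
#'
#' @format Named numeric vector (three-letter residue names, upper case).
#' @export
MILLER_MAX_ASA <- c(
  ALA = 113, ARG = 241, ASN = 158, ASP = 151, CYS = 140,
  GLN = 189, GLU = 183, GLY =  85, HIS = 194, ILE = 182,
  LEU = 180, LYS = 211, MET = 204, PHE = 218, PRO = 143,
  SER = 122, THR = 146, TRP = 259, TYR = 229, VAL = 160
)

# heavy-atom van der Waals radii (Angstrom), Bondi-style set keyed by element
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, SE = 1.90)
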