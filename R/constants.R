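#' Average residue masses and pKa values used for protein properties
#'
#' Monoisotopic ambiguity does not matter at screen scale; masses are the
#' standard average residue masses (Da). The pKa set is the EMBOSS set
#' (N-terminus 8.6, C-terminus 3.6, Cys 8.5, Asp 3.9, Glu 4.1, His 6.5,
#' Lys 10.8, Arg 12.5, Tyr 10.1), frozen here so that reported pI values are
#' reproducible; other programs use other sets and give slightly different pI.
#'
#' @name tbysim-constants
#' @keywords internal
NULL

# average residue masses, Da (residue = amino acid minus water)
.RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.WATER_MASS <- 18.01524

# EMBOSS pKa set
.PKA_POSITIVE <- c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5)
.PKA_NEGATIVE <- c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1)

.DNA_BASES <- c("A", "C", "G", "T")

# the 12 directed substitution classes, in fixed order
.SUB_CLASSES <- c(
  "A>C", "A>G", "A>T",
  "C>A", "C>G", "C>T",
  "G>A", "G>C", "G>T",
  "T>A", "T>C", "T>G"
)

#' Conserved sucrose synthase motifs
#'
#' Residue motifs conserved across plant sucrose synthase enzymes (GT-BC and
#' GT-BN domains of the GT-4 glycosyltransferase fold), used as the default
#' motif set for [scan_conserved_motifs()].
#'
#' @return Character vector of amino-acid motifs.
#' @export
#' @examples
#' tbys_conserved_motifs()
tbys_conserved_motifs <- function() {
  c("PDTGGQ", "VYILDQV", "DFII", "GQYE", "FDPKFNI", "FGLTV")
}
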