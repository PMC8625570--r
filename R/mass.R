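# Average residue masses (Da) for the 20 standard amino acids, i.e. the
# monomer mass minus one water; summing residues and adding back one water
# gives the average chain mass.
RESIDUE_MASS_DA <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)

WATER_MASS_DA <- 18.01528

# Mass of the GppNHp nucleotide (kDa) added to a GTPase chain mass when the
# complex under study is nucleotide-bound.
GPPNHP_MASS_KDA <- 0.52

#' Average molecular mass of a protein construct
#'
#' Sum of average residue masses plus one water, in kDa.
#'
#' @param record A [sequence_record()].
#' @param nucleotide_kda Additional bound-ligand mass in kDa (e.g.
#'   `gppnhp_mass()` for a GppNHp-loaded GTPase); default 0.
#' @return Mass in kDa (numeric scalar).
#' @examples
#' molecular_mass(sequence_record("g", "G"))  # ~0.0751 kDa
#' @export
molecular_mass <- function(record, nucleotide_kda = 0) {
  stopifnot(inherits(record, "SequenceRecord"))
  chars <- strsplit(record$residues, "")[[1]]
  (sum(RESIDUE_MASS_DA[chars]) + WATER_MASS_DA) / 1000 + nucleotide_kda
}

#' Mass of the non-hydrolysable nucleotide analog GppNHp
#' @return Mass in kDa.
#' @export
gppnhp_mass <- function() GPPNHP_MASS_KDA
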