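#' Pairwise percent identity by global alignment
#'
#' Globally aligns two constructs (Needleman-Wunsch with affine gaps,
#' BLOSUM62 scores, gap opening 10, gap extension 0.5) and reports the
#' percentage of identical aligned residue pairs over all alignment
#' columns excluding terminal-gap columns.
#'
#' @param a,b [sequence_record()] objects.
#' @param gap_opening,gap_extension Affine gap penalties.
#' @param substitution_matrix Name of the substitution matrix shipped
#'   with Biostrings.
#' @return Percent identity in `[0, 100]`.
#' @examples
#' a <- sequence_record("a", "ACDE"); b <- sequence_record("b", "ACDF")
#' percent_identity(a, b)  # 75
#' @export
percent_identity <- function(a, b, gap_opening = 10, gap_extension = 0.5,
                             substitution_matrix = "BLOSUM62") {
  stopifnot(inherits(a, "SequenceRecord"), inherits(b, "SequenceRecord"))
  if (!nzchar(a$residues) || !nzchar(b$residues)) {
    stop("cannot align empty sequences", call. = FALSE)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a$residues), Biostrings::AAString(b$residues),
    type = "global", substitutionMatrix = substitution_matrix,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  ps <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  # drop terminal-gap columns (overhangs of a global alignment)
  res_a <- pa != "-"; res_b <- ps != "-"
  core <- seq(max(which(res_a)[1L], which(res_b)[1L]),
              min(rev(which(res_a))[1L], rev(which(res_b))[1L]))
  identical_pairs <- sum(pa[core] == ps[core] & pa[core] != "-")
  100 * identical_pairs / length(core)
}
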