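#' Load the bundled transcribed core sequences
#'
#' Returns the three construct sequences shipped with the package (RAC1
#' aa 1-179, CDC42 aa 1-178, RHOA aa 1-181). These are hand-transcribed
#' canonical sequences cross-checked against published residue landmarks
#' (hotspot residues, substitution wild types, G-domain net charges),
#' not database downloads; verify against UniProt before scientific use.
#'
#' @return Named list of [sequence_record()] objects.
#' @export
core_sequences <- function() {
  path <- system.file("extdata", "rho_core_transcribed.fasta",
                      package = "rhoiq", mustWork = TRUE)
  records <- read_fasta(path)
  names(records) <- vapply(records, function(r) r$id, character(1))
  records
}

# Same-class residue swap used to add realistic neutral variation to
# derived panel rows without creating class-level deviations.
same_class_swap <- function(residue, rng_draw) {
  pool <- list(
    hydrophobic = c("A", "V", "L", "I", "M"),
    polar = c("S", "T", "N", "Q"),
    positive = c("K", "R"),
    negative = c("D", "E")
  )[[residue_class(residue)]]
  pool <- setdiff(pool, residue)
  if (length(pool) == 0L) return(residue)
  pool[1L + (rng_draw %% length(pool))]
}

#' Synthetic 14-member RHO GTPase G-domain panel
#'
#' A labelled, collinear G-domain alignment (CDC42 numbering 1-178)
#' emulating the 14-GTPase study set: 5 IQGAP binders (RAC1, RAC2, RAC3,
#' RHOG, CDC42) and 9 nonbinders (RHOA, RHOB, RHOC, TC10, RND1, RND2,
#' RND3, RHOD, RIF). RAC1, CDC42 and RHOA rows are the bundled
#' transcribed sequences; all other rows (marked `_SYN`) are synthetic
#' stand-ins derived from those backbones. The stand-ins encode the
#' documented family features: nonbinders carry the RHOA-type residues
#' at the seven selectivity loci (reference positions 25, 26, 45, 52,
#' 74, 85, 88), the RAC2 stand-in carries its published distinguishing
#' residues (S48, Y90, D150), and every derived row receives seeded
#' same-class substitutions elsewhere as neutral sequence variation. A
#' discriminating column is also planted inside switch I (position 33)
#' as a negative control for the region exclusion.
#'
#' Because the rows are partly synthetic, analyses of this panel
#' exercise the algorithms end-to-end on realistic input but do not
#' substitute for the database sequences.
#'
#' @param seed Seed for the same-class variation.
#' @param n_variation Number of same-class substitutions per derived
#'   row.
#' @return An [alignment_set()] with reference row CDC42.
#' @export
synthetic_rho_panel <- function(seed = 7L, n_variation = 12L) {
  core <- core_sequences()
  trim <- function(rec, from, to) {
    sequence_record(rec$id, substring(rec$residues,
                                      from - rec$range_start + 1L,
                                      to - rec$range_start + 1L),
                    range_start = from, range_end = to,
                    accession = rec$accession, label = rec$label)
  }
  rac1 <- trim(core$RAC1, 1L, 178L)
  cdc42 <- trim(core$CDC42, 1L, 178L)
  rhoa <- trim(core$RHOA, 3L, 180L)   # collinear with CDC42 1-178
  # RHOA-type residues at the selectivity loci, in CDC42/RAC numbering
  loci <- c(25L, 26L, 45L, 52L, 74L, 85L, 88L)
  rhoa_chars <- strsplit(rhoa$residues, "")[[1]]
  nonbinder_loci <- rhoa_chars[loci + 2L - rhoa$range_start + 1L]
  switch_control <- 33L               # planted inside switch I
  set.seed(as.integer(seed))
  protected <- c(loci, switch_control)
  derive <- function(backbone, id, label, planted = NULL) {
    chars <- strsplit(backbone, "")[[1]]
    if (!is.null(planted)) {
      chars[as.integer(names(planted))] <- planted
    }
    free <- setdiff(seq_along(chars), protected)
    hit <- sample(free, n_variation)
    draws <- sample.int(1000L, n_variation)
    for (k in seq_along(hit)) {
      chars[hit[k]] <- same_class_swap(chars[hit[k]], draws[k])
    }
    sequence_record(id, paste(chars, collapse = ""), range_start = 1L,
                    range_end = 178L, label = label)
  }
  rac1_bb <- rac1$residues
  rhoa_bb <- rhoa$residues
  nb_planted <- setNames(c(nonbinder_loci, "E"),
                         c(loci, switch_control))
  rac2_planted <- setNames(c("S", "Y", "D"), c(48L, 90L, 150L))
  records <- list(
    rac1,
    derive(rac1_bb, "RAC2_SYN", "binder", rac2_planted),
    derive(rac1_bb, "RAC3_SYN", "binder"),
    derive(rac1_bb, "RHOG_SYN", "binder"),
    cdc42,
    rhoa,
    derive(rhoa_bb, "RHOB_SYN", "nonbinder",
           setNames("E", switch_control)),
    derive(rhoa_bb, "RHOC_SYN", "nonbinder",
           setNames("E", switch_control)),
    derive(rac1_bb, "TC10_SYN", "nonbinder", nb_planted),
    derive(rac1_bb, "RND1_SYN", "nonbinder", nb_planted),
    derive(rac1_bb, "RND2_SYN", "nonbinder", nb_planted),
    derive(rac1_bb, "RND3_SYN", "nonbinder", nb_planted),
    derive(rac1_bb, "RHOD_SYN", "nonbinder", nb_planted),
    derive(rac1_bb, "RIF_SYN", "nonbinder", nb_planted)
  )
  gapped <- vapply(records, function(r) r$residues, character(1))
  alignment_set(records, gapped, reference_id = "CDC42")
}
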