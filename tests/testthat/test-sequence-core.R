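test_that("FASTA records parse with the header dialect and defaults", {
  path <- write_temp_fasta(c(">x 1-3", "ACD"))
  recs <- read_fasta(path)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "x")
  expect_equal(recs[[1]]$residues, "ACD")
  expect_equal(c(recs[[1]]$range_start, recs[[1]]$range_end), c(1L, 3L))
  expect_equal(recs[[1]]$label, "unknown")

  full <- write_temp_fasta(c(
    ">RAC1 accession=P63000 range=1-6 label=binder some note", "MQAIKC"))
  rec <- read_fasta(full)[[1]]
  expect_equal(rec$accession, "P63000")
  expect_equal(rec$label, "binder")
  expect_equal(rec$description, "some note")
})

test_that("empty FASTA gives an empty list and bad residues error", {
  empty <- tempfile(fileext = ".fasta"); file.create(empty)
  expect_identical(read_fasta(empty), list())
  bad <- write_temp_fasta(c(">y", "ABD"))
  expect_error(read_fasta(bad), "non-standard residue")
  expect_error(read_fasta(tempfile()), "no such file")
})

test_that("FASTA write/read round-trips records", {
  recs <- list(
    sequence_record("a", "MKDE", range_start = 5, accession = "P1",
                    label = "binder"),
    sequence_record("b", "GGG", label = "nonbinder")
  )
  path <- tempfile(fileext = ".fasta")
  write_fasta(recs, path)
  back <- read_fasta(path)
  for (i in seq_along(recs)) {
    expect_equal(back[[i]]$id, recs[[i]]$id)
    expect_equal(back[[i]]$residues, recs[[i]]$residues)
    expect_equal(back[[i]]$range_start, recs[[i]]$range_start)
    expect_equal(back[[i]]$label, recs[[i]]$label)
    expect_equal(back[[i]]$accession, recs[[i]]$accession)
  }
})

test_that("net charge follows the K/R plus, D/E minus rule", {
  expect_equal(net_charge(sequence_record("g", "GGGG"))$net_charge, 0)
  expect_equal(net_charge(sequence_record("x", "KKRDE"))$net_charge, 1)
  # histidine is not counted as charged
  expect_equal(net_charge(sequence_record("h", "HHHH"))$net_charge, 0)
  rep <- net_charge(sequence_record("y", "KRDEKA"))
  expect_equal(rep$n_K, 2); expect_equal(rep$n_R, 1)
  expect_equal(rep$n_D, 1); expect_equal(rep$n_E, 1)
})

test_that("net charge restricts to a domain and checks bounds", {
  rec <- sequence_record("z", "KKKDDD", range_start = 10)
  expect_equal(net_charge(rec, c(10, 12))$net_charge, 3)
  expect_equal(net_charge(rec, c(13, 15))$net_charge, -3)
  expect_error(net_charge(rec, c(9, 12)), "outside record range")
  expect_error(net_charge(rec, c(10, 16)), "outside record range")
})

test_that("net charge is additive over concatenation", {
  for (seed in 1:5) {
    s1 <- random_sequence(40, seed); s2 <- random_sequence(25, seed + 100)
    q1 <- net_charge(sequence_record("a", s1))$net_charge
    q2 <- net_charge(sequence_record("b", s2))$net_charge
    q12 <- net_charge(sequence_record("ab", paste0(s1, s2)))$net_charge
    expect_equal(q12, q1 + q2)
    expect_equal(q1, oracle_net_charge(s1))
  }
})

test_that("charged locus columns report the requested polarity", {
  mk <- function(seqs) {
    recs <- lapply(seq_along(seqs), function(i) {
      sequence_record(paste0("s", i), gsub("-", "", seqs[i]),
                      label = "unknown")
    })
    alignment_set(recs, seqs, reference_id = "s1")
  }
  aln <- mk(c("AKG", "AEG"))
  expect_equal(charged_locus_columns(aln, "either"), 2L)
  expect_equal(charged_locus_columns(mk(c("AAA", "AAA")), "either"),
               integer())
  aln2 <- mk(c("KAD", "RAE"))
  expect_equal(charged_locus_columns(aln2, "negative"), 3L)
  expect_equal(charged_locus_columns(aln2, "positive"), 1L)
  # either = union of positive and negative
  for (seed in 1:3) {
    rows <- vapply(1:4, function(i) random_sequence(30, seed * 10 + i),
                   character(1))
    aln3 <- mk(rows)
    expect_equal(charged_locus_columns(aln3, "either"),
                 sort(union(charged_locus_columns(aln3, "positive"),
                            charged_locus_columns(aln3, "negative"))))
  }
})

test_that("percent identity handles exact examples and symmetry", {
  a <- sequence_record("a", "ACDE"); b <- sequence_record("b", "ACDF")
  expect_equal(percent_identity(a, a), 100)
  expect_equal(percent_identity(a, b), 75)
  for (seed in 1:3) {
    x <- sequence_record("x", random_sequence(60, seed))
    y <- sequence_record("y", random_sequence(55, seed + 50))
    expect_equal(percent_identity(x, y), percent_identity(y, x))
    expect_lt(percent_identity(x, y), 100)
  }
})

test_that("substitutions apply with wild-type guarding and invert", {
  rec <- sequence_record("m", "MKD")
  out <- apply_substitutions(rec, "K2T")
  expect_equal(out$residues, "MTD")
  expect_equal(out$id, "m_K2T")
  expect_error(apply_substitutions(sequence_record("m", "MAD"), "K2T"),
               "wild-type mismatch")
  expect_error(apply_substitutions(rec, "K9T"), "outside range")
  # applying the inverse substitutions restores the original residues
  rec2 <- sequence_record("r", "MKDEQ")
  fwd <- apply_substitutions(rec2, c("K2T", "E4N"))
  back <- apply_substitutions(fwd, c("T2K", "N4E"))
  expect_equal(back$residues, rec2$residues)
})

test_that("the RHOA-to-RAC1 five-residue swap hits exactly five sites", {
  rhoa <- core_sequences()$RHOA
  var <- apply_substitutions(rhoa,
                             c("K27T", "D28N", "E47M", "E54N", "D76Q"))
  diffs <- which(strsplit(var$residues, "")[[1]] !=
                   strsplit(rhoa$residues, "")[[1]])
  expect_equal(diffs, c(27L, 28L, 47L, 54L, 76L))
})

test_that("molecular mass matches residue-table summation", {
  expect_equal(molecular_mass(sequence_record("g", "G")), 0.0751,
               tolerance = 1e-3)
  # independent oracle: seqinr's protein molecular weight
  rac1 <- core_sequences()$RAC1
  oracle <- seqinr::pmw(strsplit(rac1$residues, "")[[1]]) / 1000
  expect_equal(molecular_mass(rac1), oracle, tolerance = 1e-3)
  expect_equal(molecular_mass(rac1, nucleotide_kda = gppnhp_mass()),
               molecular_mass(rac1) + 0.52)
})

test_that("reference position mapping handles gaps", {
  recs <- list(sequence_record("ref", "ACD"),
               sequence_record("other", "ACWD"))
  aln <- alignment_set(recs, c("AC-D", "ACWD"), "ref")
  expect_equal(unname(map_reference_positions(aln, 3L)), 4L)
  expect_equal(unname(map_reference_positions(aln, c(1L, 2L))),
               c(1L, 2L))
  expect_error(map_reference_positions(aln, 9L), "not covered")
  # gapless reference gives the identity map
  aln2 <- alignment_set(list(sequence_record("r", "MKDE")), "MKDE", "r")
  expect_equal(unname(map_reference_positions(aln2, 1:4)), 1:4)
  # random gapped alignments agree with a cumulative-count scan
  for (seed in 1:3) {
    set.seed(seed)
    seq <- random_sequence(20, seed)
    gapped_chars <- character()
    for (ch in strsplit(seq, "")[[1]]) {
      if (runif(1) < 0.3) gapped_chars <- c(gapped_chars, "-")
      gapped_chars <- c(gapped_chars, ch)
    }
    gapped <- paste(gapped_chars, collapse = "")
    partner <- paste(rep("A", nchar(gapped)), collapse = "")
    aln3 <- alignment_set(list(sequence_record("ref", seq),
                               sequence_record("p", partner)),
                          c(gapped, partner), "ref")
    # oracle: nth non-gap character
    non_gap <- which(gapped_chars != "-")
    for (pos in c(1L, 7L, 20L)) {
      expect_equal(unname(map_reference_positions(aln3, pos)),
                   non_gap[pos])
    }
  }
})

test_that("alignment construction validates its invariants", {
  recs <- list(sequence_record("a", "AC"), sequence_record("b", "AG"))
  expect_error(alignment_set(recs, c("A-C", "AG"), "a"),
               "differ in length")
  expect_error(alignment_set(recs, c("A-C", "AG-"), "c"),
               "not present")
  expect_error(alignment_set(recs, c("AC-", "A-C"), "a"),
               "does not reproduce")
})

test_that("alignment files round-trip through aligned FASTA", {
  recs <- list(sequence_record("ref", "MKDE", label = "binder"),
               sequence_record("row2", "MKE", label = "nonbinder"))
  aln <- alignment_set(recs, c("MKDE", "MK-E"), "ref")
  path <- tempfile(fileext = ".afa")
  write_alignment(aln, path)
  back <- read_alignment(path, reference_id = "ref")
  expect_equal(back$gapped, aln$gapped)
  expect_equal(row_labels <- vapply(back$records, `[[`, "", "label"),
               c("binder", "nonbinder"))
  expect_equal(back$column_to_ref, aln$column_to_ref)
})
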