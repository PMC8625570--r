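pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element, altloc = " ", icode = " ") {
  sprintf("ATOM  %5d %-4s%s%-3s %s%4d%s   %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          serial, name, altloc, resname, chain, resno, icode, x, y, z,
          element)
}

test_that("PDB files parse to exact coordinates and skip junk", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "REMARK test structure",
    pdb_line(1, "CA", "GLY", "A", 1, 1.5, 2.25, -3.125, "C"),
    pdb_line(2, "CA", "ALA", "B", 2, 4.0, 2.25, -3.125, "C"),
    "CONECT    1    2",
    "END"), path)
  atoms <- read_structure(path)
  expect_equal(nrow(atoms), 2L)
  expect_equal(atoms$x, c(1.5, 4.0))
  expect_equal(atoms$z, c(-3.125, -3.125))
  expect_equal(atoms$chain, c("A", "B"))
  expect_equal(atoms$element, c("C", "C"))
})

test_that("alternate locations keep only A and insertion codes reject", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C", altloc = "A"),
    pdb_line(2, "CA", "GLY", "A", 1, 9, 9, 9, "C", altloc = "B"),
    "END"), path)
  atoms <- read_structure(path)
  expect_equal(nrow(atoms), 1L)
  expect_equal(atoms$x, 0)

  path2 <- tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0, "C", icode = "A"),
    "END"), path2)
  expect_error(read_structure(path2), "insertion codes")
})

test_that("interface membership follows the distance cutoff exactly", {
  close_pair <- data.frame(
    chain = c("A", "B"), resno = c(1L, 2L), resid = "GLY", atom = "CA",
    x = c(0, 4), y = 0, z = 0, element = "C",
    stringsAsFactors = FALSE)
  rep <- interface_residues(close_pair, "A", "B", cutoff = 4.5)
  expect_equal(nrow(rep$residues), 2L)
  far_pair <- close_pair; far_pair$x <- c(0, 5)
  rep2 <- interface_residues(far_pair, "A", "B", cutoff = 4.5)
  expect_equal(nrow(rep2$residues), 0L)
  # exactly at the cutoff is included
  at_pair <- close_pair; at_pair$x <- c(0, 4.5)
  expect_equal(nrow(interface_residues(at_pair, "A", "B")$residues), 2L)
})

test_that("group validation and hydrogen exclusion", {
  atoms <- data.frame(
    chain = c("A", "B", "B"), resno = c(1L, 1L, 1L), resid = "GLY",
    atom = c("CA", "H", "CA"), x = c(0, 2, 30), y = 0, z = 0,
    element = c("C", "H", "C"), stringsAsFactors = FALSE)
  # the only nearby partner atom is a hydrogen, so no interface
  rep <- interface_residues(atoms, "A", "B")
  expect_equal(nrow(rep$residues), 0L)
  expect_error(interface_residues(atoms, character(), "B"), "non-empty")
  expect_error(interface_residues(atoms, c("A", "B"), "B"), "overlap")
})

test_that("interface analysis is symmetric and monotone in the cutoff", {
  atoms <- generate_toy_complex(4, separation = 4.2, n_far = 3,
                                seed = 11)
  ab <- interface_residues(atoms, "A", "B")
  ba <- interface_residues(atoms, "B", "A")
  key <- function(rep) sort(paste(rep$residues$chain,
                                  rep$residues$resno))
  expect_equal(key(ab), key(ba))
  sizes <- vapply(c(3, 4.5, 9, 25), function(cut) {
    nrow(interface_residues(atoms, "A", "B", cutoff = cut)$residues)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})

test_that("interface matches the all-pairs oracle on random structures", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- 120
    atoms <- data.frame(
      chain = sample(c("A", "B"), n, replace = TRUE),
      resno = sample(1:40, n, replace = TRUE), resid = "ALA",
      atom = "CA",
      x = runif(n, 0, 25), y = runif(n, 0, 25), z = runif(n, 0, 25),
      element = sample(c("C", "N", "O", "H"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    got <- interface_residues(atoms, "A", "B", cutoff = 5)
    want <- oracle_interface(atoms, "A", "B", 5)
    expect_equal(sort(paste(got$residues$chain[got$residues$group == "A"],
                            got$residues$resno[got$residues$group == "A"])),
                 want$A)
    expect_equal(sort(paste(got$residues$chain[got$residues$group == "B"],
                            got$residues$resno[got$residues$group == "B"])),
                 want$B)
  }
})

test_that("hotspot proximity classifies by distance bands", {
  atoms <- rbind(
    data.frame(chain = "A", resno = 1L, resid = "GLY", atom = "CA",
               x = 0, y = 0, z = 0, element = "C"),
    data.frame(chain = "A", resno = 2L, resid = "GLY", atom = "CA",
               x = 0, y = 6, z = 0, element = "C"),
    data.frame(chain = "A", resno = 3L, resid = "GLY", atom = "CA",
               x = 0, y = 30, z = 0, element = "C"),
    data.frame(chain = "B", resno = 9L, resid = "GLY", atom = "CA",
               x = 4, y = 0, z = 0, element = "C"))
  rep <- interface_residues(atoms, "A", "B")
  prox <- hotspot_proximity(rep, c(1L, 2L, 3L, 99L))
  expect_equal(prox$class,
               c("interface", "proximal", "distal", "unresolved"))
})

test_that("toy complexes give the requested contact count and round-trip", {
  atoms <- generate_toy_complex(3)
  rep <- interface_residues(atoms, "A", "B")
  expect_equal(sum(rep$residues$group == "A"), 3L)
  expect_equal(sum(rep$residues$group == "B"), 3L)
  none <- generate_toy_complex(0, n_far = 2)
  expect_equal(nrow(interface_residues(none, "A", "B")$residues), 0L)
  expect_identical(generate_toy_complex(3, seed = 5),
                   generate_toy_complex(3, seed = 5))
  expect_error(generate_toy_complex(2, separation = 5), "infeasible")
  # PDB round trip preserves coordinates and chains
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(atoms, path)
  back <- read_structure(path)
  expect_equal(nrow(back), nrow(atoms))
  expect_equal(back$x, atoms$x, tolerance = 1e-3)
  expect_equal(back$chain, atoms$chain)
})
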