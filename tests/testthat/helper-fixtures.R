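# Shared helpers for the test suite: tiny builders and brute-force
# oracles kept deliberately independent of the implementation paths they
# check.

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}

random_sequence <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# independent charge count (simple loop, no vectorised trickery)
oracle_net_charge <- function(seq) {
  q <- 0
  for (ch in strsplit(seq, "")[[1]]) {
    if (ch %in% c("K", "R")) q <- q + 1
    if (ch %in% c("D", "E")) q <- q - 1
  }
  q
}

# brute-force stoichiometry search
oracle_stoichiometry <- function(observed, m1, m2, max_copies = 4L) {
  best <- NULL
  for (a in seq_len(max_copies)) {
    for (b in seq_len(max_copies)) {
      err <- abs(a * m1 + b * m2 - observed)
      if (is.null(best) || err < best$err - 1e-12 ||
          (abs(err - best$err) <= 1e-12 &&
           (a + b < best$a + best$b ||
            (a + b == best$a + best$b && a < best$a)))) {
        best <- list(a = a, b = b, err = err)
      }
    }
  }
  best
}

# all-pairs interface oracle on an atom data.frame
oracle_interface <- function(atoms, chainsA, chainsB, cutoff) {
  heavy <- atoms[atoms$element != "H", ]
  a <- heavy[heavy$chain %in% chainsA, ]
  b <- heavy[heavy$chain %in% chainsB, ]
  resA <- character(); resB <- character()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      d <- sqrt(sum((as.numeric(a[i, c("x", "y", "z")]) -
                       as.numeric(b[j, c("x", "y", "z")]))^2))
      if (d <= cutoff) {
        resA <- union(resA, paste(a$chain[i], a$resno[i]))
        resB <- union(resB, paste(b$chain[j], b$resno[j]))
      }
    }
  }
  list(A = sort(resA), B = sort(resB))
}
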