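#' Read atomic coordinates from a PDB file
#'
#' Parses ATOM records via [bio3d::read.pdb()]. HETATM records are
#' skipped unless `keep_hetatm = TRUE`; for alternate locations only
#' altloc `'A'` or blank is kept; hydrogens are retained here and
#' excluded later by the distance analysis. Insertion codes are rejected
#' (author numbering is preserved as-is and must be unambiguous).
#'
#' @param path Path to a PDB-format file.
#' @param keep_hetatm Keep HETATM records as well.
#' @return A data.frame of atom records with columns `chain`, `resno`,
#'   `resid`, `atom`, `x`, `y`, `z`, `element`.
#' @export
read_structure <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("cannot parse PDB file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  atoms <- pdb$atom
  if (!keep_hetatm) atoms <- atoms[atoms$type == "ATOM", , drop = FALSE]
  atoms <- atoms[is.na(atoms$alt) | atoms$alt %in% c("", "A"), ,
                 drop = FALSE]
  if (any(!is.na(atoms$insert) & nzchar(atoms$insert))) {
    stop("insertion codes present: renumber the structure before ",
         "interface analysis", call. = FALSE)
  }
  element <- atoms$elesy
  missing_el <- is.na(element) | !nzchar(trimws(element))
  # fall back on the first letter of the atom name
  element[missing_el] <- substring(gsub("[0-9]", "",
                                        atoms$elety[missing_el]), 1L, 1L)
  data.frame(chain = atoms$chain, resno = atoms$resno,
             resid = atoms$resid, atom = atoms$elety,
             x = atoms$x, y = atoms$y, z = atoms$z,
             element = toupper(trimws(element)),
             stringsAsFactors = FALSE)
}

# All pairwise distances between two coordinate blocks (n x 3, m x 3).
cross_distances <- function(xyz_a, xyz_b) {
  sq_a <- rowSums(xyz_a^2); sq_b <- rowSums(xyz_b^2)
  d2 <- outer(sq_a, sq_b, "+") - 2 * xyz_a %*% t(xyz_b)
  sqrt(pmax(d2, 0))
}

#' Interface residues between two chain groups
#'
#' A residue of one group is interfacial iff any of its heavy atoms
#' (element != H) lies within `cutoff` of any heavy atom of the other
#' group; distances exactly at the cutoff are included. The analysis is
#' symmetric in the two groups.
#'
#' @param atoms Atom data.frame from [read_structure()].
#' @param groupA,groupB Non-empty, disjoint character vectors of chain
#'   ids.
#' @param cutoff Contact distance cutoff in Angstrom (default 4.5).
#' @return An `InterfaceReport` list with `residues` (data.frame:
#'   `group`, `chain`, `resno`, `resid`, `min_distance`, at the
#'   interface) and `all_residues` (same columns for every residue of
#'   both groups, with `interface` flag), plus `cutoff`.
#' @export
interface_residues <- function(atoms, groupA, groupB, cutoff = 4.5) {
  if (length(groupA) == 0L || length(groupB) == 0L) {
    stop("both chain groups must be non-empty", call. = FALSE)
  }
  if (length(intersect(groupA, groupB)) > 0L) {
    stop("chain groups overlap: ",
         paste(intersect(groupA, groupB), collapse = ", "),
         call. = FALSE)
  }
  heavy <- atoms[atoms$element != "H", , drop = FALSE]
  a <- heavy[heavy$chain %in% groupA, , drop = FALSE]
  b <- heavy[heavy$chain %in% groupB, , drop = FALSE]
  if (nrow(a) == 0L || nrow(b) == 0L) {
    stop("no heavy atoms found in one of the chain groups",
         call. = FALSE)
  }
  d <- cross_distances(as.matrix(a[, c("x", "y", "z")]),
                       as.matrix(b[, c("x", "y", "z")]))
  per_res <- function(block, min_d, group) {
    key <- paste(block$chain, block$resno)
    agg <- tapply(min_d, key, min)
    first <- !duplicated(key)
    out <- data.frame(group = group, chain = block$chain[first],
                      resno = block$resno[first],
                      resid = block$resid[first],
                      min_distance = as.numeric(agg[key[first]]),
                      stringsAsFactors = FALSE)
    out[order(out$chain, out$resno), ]
  }
  res_a <- per_res(a, apply(d, 1L, min), "A")
  res_b <- per_res(b, apply(d, 2L, min), "B")
  all_res <- rbind(res_a, res_b)
  all_res$interface <- all_res$min_distance <= cutoff
  structure(
    list(residues = all_res[all_res$interface, , drop = FALSE],
         all_residues = all_res, cutoff = cutoff),
    class = "InterfaceReport"
  )
}

#' @export
print.InterfaceReport <- function(x, ...) {
  cat(sprintf("<InterfaceReport> %d interfacial residues at cutoff %.1f A\n",
              nrow(x$residues), x$cutoff))
  invisible(x)
}

#' Classify hotspot positions by proximity to an interface
#'
#' Each hotspot residue (author numbering, on the chains of one group)
#' is classified `interface` if it appears in the interface report,
#' `proximal` if its minimal heavy-atom distance to the partner group is
#' at most `near`, and `distal` otherwise. Hotspot residues absent from
#' the structure are reported `unresolved`.
#'
#' @param report An [interface_residues()] report.
#' @param hotspots Integer vector of residue numbers.
#' @param group Which side of the interface the hotspots live on
#'   (`"A"` or `"B"`).
#' @param near Proximity distance in Angstrom (default 8).
#' @return data.frame with columns `resno`, `min_distance`, `class`.
#' @export
hotspot_proximity <- function(report, hotspots, group = "A", near = 8.0) {
  side <- report$all_residues[report$all_residues$group == group, ,
                              drop = FALSE]
  rows <- lapply(as.integer(hotspots), function(pos) {
    hit <- side[side$resno == pos, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(data.frame(resno = pos, min_distance = NA_real_,
                        class = "unresolved",
                        stringsAsFactors = FALSE))
    }
    d <- min(hit$min_distance)
    cls <- if (d <= report$cutoff) "interface"
    else if (d <= near) "proximal" else "distal"
    data.frame(resno = pos, min_distance = d, class = cls,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write an interface report as TSV
#' @param report An [interface_residues()] report.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interface_report <- function(report, path) {
  tab <- report$all_residues
  tab$class <- ifelse(tab$interface, "interface", "outside")
  write.table(tab[, c("group", "chain", "resno", "resid",
                      "min_distance", "class")],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
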