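# Partition of the 20 standard residues into physicochemical classes used
# to judge whether a nonbinder residue "clearly deviates" from the binder
# consensus. Gaps form their own class (never conserved, always deviating).
RESIDUE_CLASSES <- list(
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C", "G", "P"),
  polar       = c("S", "T", "N", "Q", "Y", "H"),
  positive    = c("K", "R"),
  negative    = c("D", "E")
)

residue_class <- function(residues) {
  cls <- rep(NA_character_, length(residues))
  for (name in names(RESIDUE_CLASSES)) {
    cls[residues %in% RESIDUE_CLASSES[[name]]] <- name
  }
  cls[residues == "-"] <- "gap"
  cls
}

#' Configuration for the hotspot search
#'
#' @param theta_cons Minimum binder conservation: fraction of binder rows
#'   sharing the consensus residue for a column to count as conserved
#'   (default 0.8).
#' @param theta_dev Minimum nonbinder deviation: fraction of nonbinder
#'   rows whose residue falls in a different physicochemical class than
#'   the binder consensus (default 0.6).
#' @param group_window Maximum reference-position gap between consecutive
#'   members of one hotspot site (default 7).
#' @param excluded Named list of excluded reference intervals; defaults to
#'   the switch I/II regions ([switch_regions()]).
#' @param classes Partition of the 20 residue codes into physicochemical
#'   classes; must cover all codes disjointly.
#' @return A `HotspotConfig` list.
#' @export
hotspot_config <- function(theta_cons = 0.8, theta_dev = 0.6,
                           group_window = 7L,
                           excluded = switch_regions(),
                           classes = RESIDUE_CLASSES) {
  stopifnot(theta_cons > 0, theta_cons <= 1,
            theta_dev > 0, theta_dev <= 1, group_window >= 0)
  all_codes <- sort(unlist(classes, use.names = FALSE))
  if (!identical(all_codes, sort(AA_CODES))) {
    stop("classes must cover the 20 standard residue codes disjointly",
         call. = FALSE)
  }
  list(theta_cons = theta_cons, theta_dev = theta_dev,
       group_window = as.integer(group_window), excluded = excluded,
       classes = classes)
}

#' Per-column conservation and deviation statistics
#'
#' For each alignment column carrying a reference residue, computes the
#' binder consensus residue, the binder conservation `f_b` (maximum
#' residue frequency among binder rows; consensus ties broken
#' alphabetically), and the nonbinder deviation `d` (fraction of
#' nonbinder rows whose residue belongs to a different physicochemical
#' class than the binder consensus). A column is a candidate hotspot
#' position when `f_b >= theta_cons`, `d >= theta_dev` and its reference
#' position lies outside the excluded regions. Columns where the
#' reference row is gapped are skipped (positions are named in reference
#' numbering). Gaps in other rows count as a distinct symbol: never part
#' of a consensus majority, always class-deviating.
#'
#' @param alignment An [alignment_set()] with at least one binder and one
#'   nonbinder row.
#' @param config A [hotspot_config()].
#' @return A data.frame with columns `column`, `ref_pos`, `consensus`,
#'   `f_b`, `d`, `excluded`, `candidate`.
#' @export
column_statistics <- function(alignment, config = hotspot_config()) {
  labels <- row_labels(alignment)
  if (!any(labels == "binder") || !any(labels == "nonbinder")) {
    stop("alignment needs at least one binder and one nonbinder row",
         call. = FALSE)
  }
  mat <- alignment_matrix(alignment)
  cols <- which(!is.na(alignment$column_to_ref))
  b <- mat[labels == "binder", cols, drop = FALSE]
  nb <- mat[labels == "nonbinder", cols, drop = FALSE]
  stats <- lapply(seq_along(cols), function(j) {
    bres <- b[, j]
    tab <- table(bres[bres != "-"])
    if (length(tab) == 0L) {          # binders all gapped
      consensus <- "-"; f_b <- 0
    } else {
      top <- max(tab)
      consensus <- sort(names(tab)[tab == top])[1L]
      f_b <- top / length(bres)
    }
    cons_class <- residue_class(consensus)
    d <- mean(residue_class(nb[, j]) != cons_class)
    data.frame(column = cols[j],
               ref_pos = alignment$column_to_ref[cols[j]],
               consensus = consensus, f_b = f_b, d = d,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, stats)
  out$excluded <- in_regions(out$ref_pos, config$excluded)
  out$candidate <- out$f_b >= config$theta_cons &
    out$d >= config$theta_dev & !out$excluded
  out
}

#' Specificity-determining positions of a labelled alignment
#'
#' Ascending reference positions whose columns are conserved within the
#' binders, class-deviating in the nonbinders, and outside the excluded
#' (switch) regions; see [column_statistics()] for the criteria.
#'
#' @inheritParams column_statistics
#' @return Integer vector of reference positions.
#' @export
find_discriminating_positions <- function(alignment,
                                          config = hotspot_config()) {
  stats <- column_statistics(alignment, config)
  sort(stats$ref_pos[stats$candidate])
}

#' Group discriminating positions into hotspot sites
#'
#' Greedy left-to-right grouping: a site is extended while the next
#' position is within `group_window` of the previous one. The output is a
#' partition of the input.
#'
#' @param positions Ascending integer vector of reference positions.
#' @param config A [hotspot_config()] providing `group_window`.
#' @return A list of `HotspotSite` lists with elements `members` and
#'   `span`.
#' @export
group_sites <- function(positions, config = hotspot_config()) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly ascending", call. = FALSE)
  }
  if (length(positions) == 0L) return(list())
  breaks <- c(0L, which(diff(positions) > config$group_window),
              length(positions))
  lapply(seq_len(length(breaks) - 1L), function(i) {
    members <- positions[(breaks[i] + 1L):breaks[i + 1L]]
    list(members = members, span = c(min(members), max(members)))
  })
}

#' Run the full hotspot analysis
#'
#' Convenience wrapper: computes column statistics, selects
#' discriminating positions and groups them into sites.
#'
#' @inheritParams column_statistics
#' @return A list with `stats` (data.frame), `positions` (integer) and
#'   `sites` (list), plus the `config` used.
#' @export
find_hotspots <- function(alignment, config = hotspot_config()) {
  stats <- column_statistics(alignment, config)
  positions <- sort(stats$ref_pos[stats$candidate])
  list(stats = stats, positions = positions,
       sites = group_sites(positions, config), config = config)
}
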