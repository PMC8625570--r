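#' Construct a labelled multiple alignment
#'
#' An `alignment_set` couples gapped rows with their [sequence_record()]s
#' and a numbering reference: positions are reported in the residue
#' numbering of the reference row (conventionally CDC42 or RAC1), so that
#' results can be named like T25 or Q74 regardless of gaps.
#'
#' @param records List of [sequence_record()] objects, one per row.
#' @param gapped Character vector of equal-length gapped strings using
#'   `-` for gaps; ungapping a row must reproduce its record's residues.
#' @param reference_id Id of the numbering reference row.
#' @return An object of class `alignment_set` with a `column_to_ref`
#'   element mapping column index to reference residue number (`NA` where
#'   the reference is gapped).
#' @export
alignment_set <- function(records, gapped, reference_id) {
  stopifnot(length(records) == length(gapped), length(records) > 0L)
  widths <- nchar(gapped)
  if (length(unique(widths)) != 1L) {
    stop("gapped rows differ in length", call. = FALSE)
  }
  ids <- vapply(records, function(r) r$id, character(1))
  for (i in seq_along(records)) {
    ungapped <- gsub("-", "", gapped[i], fixed = TRUE)
    if (ungapped != records[[i]]$residues) {
      stop("ungapping row '", ids[i],
           "' does not reproduce its record's residues", call. = FALSE)
    }
  }
  if (!reference_id %in% ids) {
    stop("reference row '", reference_id, "' not present", call. = FALSE)
  }
  ref_chars <- strsplit(gapped[match(reference_id, ids)], "")[[1]]
  ref_rec <- records[[match(reference_id, ids)]]
  column_to_ref <- rep(NA_integer_, length(ref_chars))
  column_to_ref[ref_chars != "-"] <-
    seq(ref_rec$range_start, length.out = sum(ref_chars != "-"))
  structure(
    list(records = records, gapped = gapped, ids = ids,
         reference_id = reference_id, column_to_ref = column_to_ref),
    class = "alignment_set"
  )
}

#' @export
print.alignment_set <- function(x, ...) {
  labs <- table(factor(vapply(x$records, function(r) r$label, character(1)),
                       levels = SEQ_LABELS))
  cat(sprintf(paste0("<alignment_set> %d rows x %d columns, reference %s",
                     " (%d binders / %d nonbinders)\n"),
              length(x$records), nchar(x$gapped[1L]), x$reference_id,
              labs[["binder"]], labs[["nonbinder"]]))
  invisible(x)
}

alignment_nrow <- function(alignment) length(alignment$records)

alignment_ncol <- function(alignment) nchar(alignment$gapped[1L])

# Character matrix (rows x columns) of the gapped alignment.
alignment_matrix <- function(alignment) {
  do.call(rbind, strsplit(alignment$gapped, ""))
}

row_labels <- function(alignment) {
  vapply(alignment$records, function(r) r$label, character(1))
}

#' Map reference residue numbers to alignment columns
#'
#' @param alignment An [alignment_set()].
#' @param positions Integer vector of residue numbers in the reference
#'   row's full-length numbering.
#' @return Named integer vector mapping each position to the column where
#'   the reference residue sits.
#' @export
map_reference_positions <- function(alignment, positions) {
  positions <- as.integer(positions)
  bad <- positions[!positions %in% alignment$column_to_ref]
  if (length(bad) > 0L) {
    stop("reference position(s) ", paste(bad, collapse = ", "),
         " not covered by reference row '", alignment$reference_id, "'",
         call. = FALSE)
  }
  setNames(match(positions, alignment$column_to_ref), positions)
}

# Full-length residue interval of `id` aligning to reference interval
# `ref_range` (used for the G-domain trim of net-charge reports).
gdomain_range <- function(alignment, id, ref_range = c(1L, 178L)) {
  stopifnot(id %in% alignment$ids)
  row <- match(id, alignment$ids)
  rec <- alignment$records[[row]]
  chars <- strsplit(alignment$gapped[row], "")[[1]]
  res_no <- rep(NA_integer_, length(chars))
  res_no[chars != "-"] <- seq(rec$range_start,
                              length.out = sum(chars != "-"))
  cols <- which(!is.na(alignment$column_to_ref) &
                  alignment$column_to_ref >= ref_range[1L] &
                  alignment$column_to_ref <= ref_range[2L])
  covered <- res_no[cols]
  covered <- covered[!is.na(covered)]
  if (length(covered) == 0L) {
    stop("row '", id, "' has no residues aligning to reference ",
         ref_range[1L], "-", ref_range[2L], call. = FALSE)
  }
  c(min(covered), max(covered))
}

#' Read a labelled alignment from aligned FASTA
#'
#' Rows use the same header dialect as [read_fasta()]; `-` marks gaps.
#'
#' @param path Path to an aligned FASTA file.
#' @param reference_id Numbering reference row id; defaults to the first
#'   row.
#' @return An [alignment_set()].
#' @export
read_alignment <- function(path, reference_id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  gapped <- toupper(as.character(set))
  heads <- lapply(names(set), parse_fasta_header)
  records <- lapply(seq_along(set), function(i) {
    h <- heads[[i]]
    sequence_record(h$id, gsub("-", "", gapped[i], fixed = TRUE),
                    range_start = h$range_start, range_end = h$range_end,
                    accession = h$accession, description = h$description,
                    label = h$label)
  })
  if (is.null(reference_id)) reference_id <- records[[1L]]$id
  alignment_set(records, unname(gapped), reference_id)
}

#' Write a labelled alignment as aligned FASTA
#' @param alignment An [alignment_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(alignment, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(alignment$records)) {
    rec <- alignment$records[[i]]
    header <- sprintf(">%s", rec$id)
    if (nzchar(rec$accession)) {
      header <- paste0(header, " accession=", rec$accession)
    }
    header <- paste0(header, sprintf(" range=%d-%d label=%s",
                                     rec$range_start, rec$range_end,
                                     rec$label))
    writeLines(c(header, alignment$gapped[i]), con)
  }
  invisible(path)
}

#' Switch-region intervals of RHO GTPases
#'
#' The conformationally mobile switch I and II regions (reference
#' numbering 29-42 and 62-68) form the shared core interface for
#' effectors and regulators and are excluded from the hotspot search.
#'
#' @return A named list of `c(start, end)` intervals (a `RegionSet`).
#' @export
switch_regions <- function() {
  list(switch_I = c(29L, 42L), switch_II = c(62L, 68L))
}

in_regions <- function(positions, regions) {
  if (length(regions) == 0L) return(rep(FALSE, length(positions)))
  Reduce(`|`, lapply(regions, function(r) {
    positions >= r[1L] & positions <= r[2L]
  }))
}
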