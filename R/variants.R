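#' Parse substitution strings
#'
#' Converts strings like `"K27T"` into `Substitution` records
#' (wild-type residue, 1-based full-length position, replacement).
#'
#' @param x Character vector of substitutions in `WposR` notation.
#' @return A list of `Substitution` lists with elements `wild_type`,
#'   `position`, `replacement`.
#' @examples
#' parse_substitutions(c("K27T", "D28N"))
#' @export
parse_substitutions <- function(x) {
  lapply(x, function(s) {
    m <- regmatches(s, regexec("^([A-Z])([0-9]+)([A-Z])$", s))[[1]]
    if (length(m) != 4L) {
      stop("cannot parse substitution '", s, "' (expected e.g. K27T)",
           call. = FALSE)
    }
    wt <- m[2L]; pos <- as.integer(m[3L]); rep <- m[4L]
    if (!wt %in% AA_CODES || !rep %in% AA_CODES) {
      stop("substitution '", s, "' uses a non-standard residue code",
           call. = FALSE)
    }
    if (wt == rep) {
      stop("substitution '", s, "' replaces a residue with itself",
           call. = FALSE)
    }
    list(wild_type = wt, position = pos, replacement = rep)
  })
}

#' Apply point substitutions to a construct
#'
#' Builds a variant record differing from the input at exactly the
#' substituted positions. Each substitution's stated wild-type residue is
#' checked against the record (in full-length numbering), which guards
#' against numbering-offset mistakes when porting residue names between
#' paralogs (e.g. RAC1 T25 vs the corresponding RHOA K27).
#'
#' @param record A [sequence_record()].
#' @param subs Either a character vector like `c("K27T", "D28N")` or the
#'   output of [parse_substitutions()].
#' @return A new [sequence_record()] with the id suffixed by the
#'   substitution string.
#' @export
apply_substitutions <- function(record, subs) {
  stopifnot(inherits(record, "SequenceRecord"))
  if (is.character(subs)) subs <- parse_substitutions(subs)
  chars <- strsplit(record$residues, "")[[1]]
  tags <- character(length(subs))
  for (i in seq_along(subs)) {
    s <- subs[[i]]
    if (s$position < record$range_start || s$position > record$range_end) {
      stop("substitution position ", s$position, " outside range ",
           record$range_start, "-", record$range_end, " of '",
           record$id, "'", call. = FALSE)
    }
    idx <- s$position - record$range_start + 1L
    if (chars[idx] != s$wild_type) {
      stop("wild-type mismatch at position ", s$position, " of '",
           record$id, "': expected ", s$wild_type, ", found ",
           chars[idx], call. = FALSE)
    }
    chars[idx] <- s$replacement
    tags[i] <- paste0(s$wild_type, s$position, s$replacement)
  }
  sequence_record(
    id = paste0(record$id, "_", paste(tags, collapse = "_")),
    residues = paste(chars, collapse = ""),
    range_start = record$range_start, range_end = record$range_end,
    accession = record$accession,
    description = record$description, label = record$label
  )
}
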