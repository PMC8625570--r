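#' @importFrom stats coef lm optimise qnorm rnorm runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

SEQ_LABELS <- c("binder", "nonbinder", "unknown")

#' Create a protein construct record
#'
#' A `SequenceRecord` describes one protein construct: its residues, the
#' 1-based residue range it occupies in the full-length protein (so that
#' positions can be named in full-length numbering, e.g. T25 or K27), an
#' optional UniProt-style accession, and a binder/nonbinder label used by
#' the hotspot analysis.
#'
#' @param id Short identifier (e.g. `"RAC1"`).
#' @param residues Character string over the 20 standard one-letter
#'   amino-acid codes (uppercase).
#' @param range_start,range_end 1-based inclusive residue numbers of the
#'   construct in the full-length protein. `range_end` defaults to
#'   `range_start + nchar(residues) - 1`.
#' @param accession UniProt-style accession, or `""`.
#' @param description Free-text description.
#' @param label One of `"binder"`, `"nonbinder"`, `"unknown"`.
#' @return An object of class `SequenceRecord`.
#' @examples
#' rec <- sequence_record("RAC1", "MQAIKCVVVG")
#' net_charge(rec)$net_charge
#' @export
sequence_record <- function(id, residues, range_start = 1L,
                            range_end = NULL, accession = "",
                            description = "", label = "unknown") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  residues <- toupper(as.character(residues))
  if (!nzchar(residues)) {
    stop("record '", id, "': empty residue string", call. = FALSE)
  }
  bad <- setdiff(strsplit(residues, "")[[1]], AA_CODES)
  if (length(bad) > 0L) {
    pos <- which(!strsplit(residues, "")[[1]] %in% AA_CODES)[1L]
    stop("record '", id, "': non-standard residue code '",
         substring(residues, pos, pos), "' at position ", pos,
         call. = FALSE)
  }
  range_start <- as.integer(range_start)
  if (is.na(range_start) || range_start < 1L) {
    stop("record '", id, "': range_start must be >= 1", call. = FALSE)
  }
  if (is.null(range_end)) {
    range_end <- range_start + nchar(residues) - 1L
  }
  range_end <- as.integer(range_end)
  if (range_end - range_start + 1L != nchar(residues)) {
    stop("record '", id, "': range ", range_start, "-", range_end,
         " does not match sequence length ", nchar(residues),
         call. = FALSE)
  }
  label <- match.arg(label, SEQ_LABELS)
  structure(
    list(id = id, accession = accession, description = description,
         residues = residues, range_start = range_start,
         range_end = range_end, label = label),
    class = "SequenceRecord"
  )
}

#' @export
print.SequenceRecord <- function(x, ...) {
  cat(sprintf("<SequenceRecord> %s%s aa %d-%d (%d aa) [%s]\n",
              x$id,
              if (nzchar(x$accession)) paste0(" (", x$accession, ")") else "",
              x$range_start, x$range_end, nchar(x$residues), x$label))
  invisible(x)
}

#' @export
length.SequenceRecord <- function(x) nchar(x$residues)

# Residue at a full-length position (1-based, full-protein numbering).
residue_at <- function(record, position) {
  position <- as.integer(position)
  if (any(position < record$range_start) || any(position > record$range_end)) {
    stop("position ", paste(position[position < record$range_start |
                                       position > record$range_end],
                            collapse = ","),
         " outside range ", record$range_start, "-", record$range_end,
         " of record '", record$id, "'", call. = FALSE)
  }
  idx <- position - record$range_start + 1L
  substring(record$residues, idx, idx)
}

# --- FASTA I/O -------------------------------------------------------------
#
# Header dialect (whitespace separated, all fields after the id optional):
#   >id accession=P63000 range=1-179 label=binder free text description
# A bare "s-e" token is also accepted as a range for brevity.

parse_fasta_header <- function(header) {
  tokens <- strsplit(trimws(header), "\\s+")[[1]]
  id <- tokens[1L]
  accession <- ""
  range_start <- 1L
  range_end <- NULL
  label <- "unknown"
  desc <- character()
  for (tok in tokens[-1L]) {
    if (grepl("^accession=", tok)) {
      accession <- sub("^accession=", "", tok)
    } else if (grepl("^range=[0-9]+-[0-9]+$", tok)) {
      rng <- as.integer(strsplit(sub("^range=", "", tok), "-")[[1]])
      range_start <- rng[1L]; range_end <- rng[2L]
    } else if (grepl("^[0-9]+-[0-9]+$", tok)) {
      rng <- as.integer(strsplit(tok, "-")[[1]])
      range_start <- rng[1L]; range_end <- rng[2L]
    } else if (grepl("^label=", tok)) {
      label <- sub("^label=", "", tok)
    } else {
      desc <- c(desc, tok)
    }
  }
  list(id = id, accession = accession, range_start = range_start,
       range_end = range_end, label = label,
       description = paste(desc, collapse = " "))
}

#' Read protein records from a FASTA file
#'
#' Parses FASTA via [Biostrings::readBStringSet()] and interprets the header
#' dialect `>id accession=A range=s-e label=binder` (all fields after the id
#' optional; a bare `s-e` token is also accepted as a range). Unspecified
#' fields default to `accession = ""`, `range` starting at 1 and
#' `label = "unknown"`.
#'
#' @param path Path to a FASTA file.
#' @return A list of [sequence_record()] objects (empty list for an empty
#'   file).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(list())
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA in '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  lapply(seq_along(set), function(i) {
    h <- parse_fasta_header(names(set)[i])
    seq <- gsub("[\\s-]", "", as.character(set[[i]]), perl = TRUE)
    sequence_record(h$id, seq, range_start = h$range_start,
                    range_end = h$range_end, accession = h$accession,
                    description = h$description, label = h$label)
  })
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()]: emits the same header dialect, so
#' `read_fasta(write_fasta(records, path))` reproduces the records.
#'
#' @param records List of [sequence_record()] objects.
#' @param path Output path.
#' @param width Line width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "SequenceRecord")) records <- list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    header <- sprintf(">%s", rec$id)
    if (nzchar(rec$accession)) {
      header <- paste0(header, " accession=", rec$accession)
    }
    header <- paste0(header, sprintf(" range=%d-%d label=%s",
                                     rec$range_start, rec$range_end,
                                     rec$label))
    if (nzchar(rec$description)) {
      header <- paste(header, rec$description)
    }
    writeLines(header, con)
    body <- rec$residues
    starts <- seq(1L, nchar(body), by = width)
    writeLines(substring(body, starts, pmin(starts + width - 1L,
                                            nchar(body))), con)
  }
  invisible(path)
}
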