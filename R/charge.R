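#' Net charge of a protein construct
#'
#' Computes the integer net charge of a sequence with +1 attributed to each
#' arginine or lysine and -1 to each aspartate or glutamate; all other
#' residues (including histidine) count as neutral. This is the statistic
#' used to compare the electrostatic character of RHO GTPase G-domains.
#'
#' @param record A [sequence_record()].
#' @param domain Optional 1-based inclusive interval `c(start, end)` in
#'   full-length numbering restricting the computation (default: the whole
#'   record).
#' @return A `ChargeReport` list with elements `id`, `n_K`, `n_R`, `n_D`,
#'   `n_E`, `net_charge` and `domain_range`.
#' @examples
#' net_charge(sequence_record("x", "KKRDE"))$net_charge  # +1
#' @export
net_charge <- function(record, domain = NULL) {
  stopifnot(inherits(record, "SequenceRecord"))
  if (is.null(domain)) {
    domain <- c(record$range_start, record$range_end)
  }
  domain <- as.integer(domain)
  stopifnot(length(domain) == 2L, domain[1L] <= domain[2L])
  if (domain[1L] < record$range_start || domain[2L] > record$range_end) {
    stop("domain ", domain[1L], "-", domain[2L],
         " outside record range ", record$range_start, "-",
         record$range_end, " of '", record$id, "'", call. = FALSE)
  }
  sub <- substring(record$residues,
                   domain[1L] - record$range_start + 1L,
                   domain[2L] - record$range_start + 1L)
  chars <- strsplit(sub, "")[[1]]
  n_K <- sum(chars == "K"); n_R <- sum(chars == "R")
  n_D <- sum(chars == "D"); n_E <- sum(chars == "E")
  structure(
    list(id = record$id, n_K = n_K, n_R = n_R, n_D = n_D, n_E = n_E,
         net_charge = (n_K + n_R) - (n_D + n_E),
         domain_range = domain),
    class = "ChargeReport"
  )
}

#' @export
print.ChargeReport <- function(x, ...) {
  cat(sprintf("<ChargeReport> %s aa %d-%d: K=%d R=%d D=%d E=%d  q=%+d\n",
              x$id, x$domain_range[1L], x$domain_range[2L],
              x$n_K, x$n_R, x$n_D, x$n_E, x$net_charge))
  invisible(x)
}

#' Net-charge table for a set of records
#'
#' Applies [net_charge()] to each record, optionally over the G-domain
#' (residues aligning to CDC42 1-178 via a supplied alignment) instead of
#' the raw construct range.
#'
#' @param records List of [sequence_record()] objects.
#' @param alignment Optional [alignment_set()] whose reference row defines
#'   the G-domain trim; when supplied, each record is restricted to the
#'   residues aligning to reference positions `gdomain_ref`.
#' @param gdomain_ref Reference interval defining the G-domain (default
#'   CDC42 numbering 1-178).
#' @return A data.frame with columns `id`, `n_K`, `n_R`, `n_D`, `n_E`,
#'   `net_charge`.
#' @export
charge_table <- function(records, alignment = NULL,
                         gdomain_ref = c(1L, 178L)) {
  if (inherits(records, "SequenceRecord")) records <- list(records)
  rows <- lapply(records, function(rec) {
    domain <- NULL
    if (!is.null(alignment)) {
      domain <- gdomain_range(alignment, rec$id, gdomain_ref)
    }
    rep <- net_charge(rec, domain)
    data.frame(id = rep$id, n_K = rep$n_K, n_R = rep$n_R, n_D = rep$n_D,
               n_E = rep$n_E, net_charge = rep$net_charge,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a charge table as TSV
#' @param tab A data.frame from [charge_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_charge_table <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Columns of an alignment containing charged residues
#'
#' Returns the (1-based) alignment columns in which at least one row
#' carries a residue of the requested polarity: positive = K/R,
#' negative = D/E. This is the charged-locus reduction used to visualise
#' how the placement of charges varies across an aligned protein family.
#'
#' @param alignment An [alignment_set()].
#' @param polarity `"positive"`, `"negative"` or `"either"`.
#' @return Ascending integer vector of column indices (empty for an empty
#'   alignment).
#' @export
charged_locus_columns <- function(alignment,
                                  polarity = c("either", "positive",
                                               "negative")) {
  polarity <- match.arg(polarity)
  if (alignment_nrow(alignment) == 0L) return(integer())
  wanted <- switch(polarity,
                   positive = c("K", "R"),
                   negative = c("D", "E"),
                   either = c("K", "R", "D", "E"))
  mat <- alignment_matrix(alignment)
  which(apply(mat, 2L, function(col) any(col %in% wanted)))
}
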