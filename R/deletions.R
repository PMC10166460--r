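#' Build a deletion table from breakpoint coordinates
#'
#' A deletion is stored as its 5' and 3' breakpoints (1-based bp, rCRS
#' convention, taken as reported -- no normalisation of the rotation
#' ambiguity inside repeated sequence). The derived `center` is the midpoint
#' `(del5 + del3) / 2` (kept as a real number, possibly half-integral) and
#' `length` is `del3 - del5`.
#'
#' @param del5,del3 Integer vectors of 5' and 3' breakpoints.
#' @param sample_id Optional sample identifiers.
#' @param provenance Free-text label recorded as an attribute.
#' @return A tibble with columns `sample_id`, `del5`, `del3`, `center`,
#'   `length`.
#' @export
deletion_table <- function(del5, del3, sample_id = NULL, provenance = "user") {
  stopifnot(length(del5) == length(del3))
  if (is.null(sample_id)) sample_id <- paste0("d", seq_along(del5))
  bad <- !is.finite(del5) | !is.finite(del3) | del3 <= del5
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing or inverted coordinates skipped")
    del5 <- del5[!bad]; del3 <- del3[!bad]; sample_id <- sample_id[!bad]
  }
  out <- tibble::tibble(
    sample_id = as.character(sample_id),
    del5 = as.integer(del5),
    del3 = as.integer(del3),
    center = (del5 + del3) / 2,
    length = as.integer(del3 - del5)
  )
  attr(out, "provenance") <- provenance
  out
}

#' Read a MitoBreak-style breakpoint TSV
#'
#' Expects a tab-separated file with a header naming (at least) the two
#' coordinate columns. Malformed rows (non-integer coordinates, or
#' `del3 <= del5`) are skipped with a warning giving the count.
#'
#' @param path Path to the TSV.
#' @param col_del5,col_del3,col_sample Column names in the file.
#' @param dedup Drop duplicate (sample_id, del5, del3) triples (default TRUE).
#' @return A deletion tibble as from [deletion_table()].
#' @export
read_breakpoints <- function(path, col_del5 = "del5", col_del3 = "del3",
                             col_sample = "sample_id", dedup = TRUE) {
  raw <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (cl in c(col_del5, col_del3)) {
    if (!cl %in% names(raw)) {
      stop("column '", cl, "' not found in ", path, call. = FALSE)
    }
  }
  d5 <- suppressWarnings(as.integer(raw[[col_del5]]))
  d3 <- suppressWarnings(as.integer(raw[[col_del3]]))
  sid <- if (col_sample %in% names(raw)) as.character(raw[[col_sample]])
         else paste0("d", seq_along(d5))
  keep <- is.finite(d5) & is.finite(d3) & d3 > d5
  n_bad <- sum(!keep)
  if (all(!keep)) stop("no parseable breakpoint rows in ", path, call. = FALSE)
  if (n_bad > 0) {
    warning(n_bad, " malformed row(s) skipped while reading ", path)
  }
  out <- deletion_table(d5[keep], d3[keep], sid[keep],
                        provenance = basename(path))
  if (dedup) {
    out <- dplyr::distinct(out, .data$sample_id, .data$del5, .data$del3,
                           .keep_all = TRUE)
  }
  out
}

#' Write a deletion table as TSV
#'
#' @param dels A deletion tibble.
#' @param path Output path.
#' @export
write_breakpoints <- function(dels, path) {
  write.table(dels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Keep deletions whose breakpoints both fall inside an arc
#'
#' Bounds are inclusive, so a deletion spanning the whole major arc
#' (5781, 16569) is retained. Idempotent.
#'
#' @param dels A deletion tibble.
#' @param arc An [arc_region()].
#' @return The filtered tibble (possibly empty).
#' @export
filter_major_arc <- function(dels, arc = major_arc()) {
  dplyr::filter(dels, .data$del5 >= arc$start, .data$del3 <= arc$end)
}
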