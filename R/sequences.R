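#' Circular nucleotide sequences
#'
#' Human mtDNA is circular: position 16,569 of the rCRS neighbours position 1.
#' `circular_seq()` wraps a character string of A/C/G/T/N residues together
#' with an identifier; [subsequence()] provides 1-based inclusive extraction
#' with wrap-around through the origin.
#'
#' @param residues Character scalar over the alphabet A, C, G, T, N
#'   (lowercase accepted and normalised).
#' @param id Sequence identifier.
#'
#' @return An object of class `circular_seq`: a list with elements `id`,
#'   `length` and `residues`.
#' @export
#' @examples
#' s <- circular_seq("ACGT")
#' subsequence(s, 4, 1)  # wraps: "TA"
circular_seq <- function(residues, id = "seq") {
  stopifnot(is.character(residues), length(residues) == 1L)
  residues <- toupper(residues)
  bad <- gregexpr("[^ACGTN]", residues)[[1]]
  if (bad[1] != -1L) {
    stop("invalid residue '", substr(residues, bad[1], bad[1]),
         "' at position ", bad[1], call. = FALSE)
  }
  structure(
    list(id = id, length = nchar(residues), residues = residues),
    class = "circular_seq"
  )
}

#' @export
print.circular_seq <- function(x, ...) {
  cat("<circular_seq> ", x$id, ": ", x$length, " bp\n", sep = "")
  invisible(x)
}

#' @export
length.circular_seq <- function(x) x$length

#' Read a single-record FASTA file as a circular genome
#'
#' @param path Path to a FASTA file containing exactly one record.
#' @return A [circular_seq()].
#' @export
read_genome <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  if (length(set) != 1L) {
    stop("expected a single-record FASTA, found ", length(set), " records",
         call. = FALSE)
  }
  circular_seq(as.character(set[[1]]), id = names(set)[1])
}

#' Write a circular genome to FASTA
#'
#' @param seq A [circular_seq()].
#' @param path Output path.
#' @param width Line width.
#' @export
write_genome <- function(seq, path, width = 70L) {
  stopifnot(inherits(seq, "circular_seq"))
  starts <- seq.int(1L, seq$length, by = width)
  lines <- substring(seq$residues, starts, pmin(starts + width - 1L, seq$length))
  writeLines(c(paste0(">", seq$id), lines), path)
  invisible(path)
}

#' Extract a 1-based inclusive subsequence, wrapping through the origin
#'
#' When `end < start` the extraction runs off the end of the molecule and
#' continues from position 1, so its length is
#' `(length - start + 1) + end`.
#'
#' @param seq A [circular_seq()].
#' @param start,end 1-based inclusive coordinates.
#' @return Character scalar.
#' @export
subsequence <- function(seq, start, end) {
  stopifnot(inherits(seq, "circular_seq"))
  L <- seq$length
  if (start < 1 || start > L || end < 1 || end > L) {
    stop("coordinates must lie in [1, ", L, "]", call. = FALSE)
  }
  if (end >= start) {
    substr(seq$residues, start, end)
  } else {
    paste0(substr(seq$residues, start, L), substr(seq$residues, 1L, end))
  }
}

#' Reverse complement of a nucleotide string
#'
#' Standard Watson-Crick complementation; N maps to N. Involution:
#' `reverse_complement(reverse_complement(s)) == s`.
#'
#' @param s Character scalar over A, C, G, T, N.
#' @return Character scalar.
#' @export
reverse_complement <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- toupper(s)
  if (grepl("[^ACGTN]", s)) {
    stop("invalid character in sequence", call. = FALSE)
  }
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' The major arc of human mtDNA and general arc regions
#'
#' The major arc is the segment of the circular molecule between the two
#' replication origins that spends the longest time single-stranded during
#' strand-displacement replication; on the rCRS it runs from 5781 to 16,569
#' (1-based inclusive).
#'
#' @param start,end 1-based inclusive bounds, `start <= end` after
#'   linearisation at the heavy-strand origin.
#' @return An `arc_region` list with `start` and `end`.
#' @export
arc_region <- function(start, end) {
  stopifnot(start >= 1, end >= start)
  structure(list(start = as.integer(start), end = as.integer(end)),
            class = "arc_region")
}

#' @rdname arc_region
#' @export
major_arc <- function() arc_region(5781L, 16569L)

#' @export
print.arc_region <- function(x, ...) {
  cat("<arc_region> [", x$start, ", ", x$end, "] (", x$end - x$start + 1L,
      " bp)\n", sep = "")
  invisible(x)
}

#' Partition an arc into a contiguous grid of fixed-length windows
#'
#' The downstream matrices (microhomology, repeat density, duplex energy,
#' regression cells) all live on this grid. The default slices the major arc
#' into 100 windows of 100 bp anchored at 6001, so windows span
#' \[6001, 16000\] and window centers fall on the x\*100 + 50.5 pattern
#' (e.g. window 16 is \[7501, 7600\], center 7550.5).
#'
#' @param arc An [arc_region()].
#' @param window_length Window length in bp.
#' @param n_windows Number of windows.
#' @param grid_start First coordinate of window 1. If `NULL`, 6001 is used
#'   for the default major arc and `arc$start` otherwise.
#' @return A tibble of class `window_grid` with columns `window` (1-based),
#'   `start`, `end`, `center`, and attributes `grid_start`, `window_length`,
#'   `n_windows`, `arc`.
#' @export
#' @examples
#' g <- build_grid()
#' g[g$window == 16, ]  # center 7550.5
build_grid <- function(arc = major_arc(), window_length = 100L,
                       n_windows = 100L, grid_start = NULL) {
  stopifnot(inherits(arc, "arc_region"), window_length >= 1, n_windows >= 1)
  if (is.null(grid_start)) {
    default_arc <- identical(unclass(arc), unclass(major_arc()))
    grid_start <- if (default_arc && window_length == 100L && n_windows == 100L)
      6001L else arc$start
  }
  grid_start <- as.integer(grid_start)
  span_end <- grid_start + n_windows * window_length - 1L
  if (grid_start < arc$start || span_end > arc$end) {
    stop("grid [", grid_start, ", ", span_end, "] exceeds arc [",
         arc$start, ", ", arc$end, "]", call. = FALSE)
  }
  k <- seq_len(n_windows) - 1L
  out <- tibble::tibble(
    window = k + 1L,
    start = grid_start + k * as.integer(window_length),
    end = grid_start + (k + 1L) * as.integer(window_length) - 1L,
    center = grid_start + k * window_length + (window_length - 1) / 2
  )
  structure(out,
            grid_start = grid_start, window_length = as.integer(window_length),
            n_windows = as.integer(n_windows), arc = arc,
            class = c("window_grid", class(out)))
}

#' Map genome positions to grid windows
#'
#' @param grid A [build_grid()] result.
#' @param pos Integer vector of 1-based positions.
#' @return Integer vector of window indices (1-based); NA for positions
#'   outside the grid.
#' @export
window_of <- function(grid, pos) {
  gs <- attr(grid, "grid_start")
  wl <- attr(grid, "window_length")
  nw <- attr(grid, "n_windows")
  w <- (as.integer(pos) - gs) %/% wl + 1L
  w[pos < gs | w > nw] <- NA_integer_
  w
}

#' Extract the window sequences of a grid
#'
#' @inheritParams window_of
#' @param seq A [circular_seq()].
#' @return Character vector of window sequences, one per window.
#' @export
grid_sequences <- function(seq, grid) {
  stopifnot(inherits(seq, "circular_seq"))
  substring(seq$residues, grid$start, grid$end)
}

#' Export a window grid as TSV (0-based window_index convention)
#'
#' @inheritParams window_of
#' @param path Output path.
#' @export
export_grid <- function(grid, path) {
  out <- data.frame(window_index = grid$window - 1L, start = grid$start,
                    end = grid$end, center = grid$center)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
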