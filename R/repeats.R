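#' Detect direct or inverted repeat pairs on a circular genome
#'
#' Performs an exhaustive ungapped scan of every (anti)diagonal of the
#' region's self-comparison, reporting each repeat pair that
#' \itemize{
#'   \item has arm length `>= min_length` and identity
#'     (matches / aligned columns) `>= min_identity`,
#'   \item has non-overlapping arms, arm1 leftmost,
#'   \item is maximal: extending the pair by one position at either end
#'     would violate the identity threshold, the region bounds, the arm
#'     overlap constraint, or `max_arm`.
#' }
#' For `kind = "inverted"` arm2 is matched against the reverse complement
#' of arm1. N residues never match. Identity is ungapped; gapped similarity
#' between windows is the microhomology module's job.
#'
#' @param seq A [circular_seq()].
#' @param region Optional [arc_region()]; both arms must lie inside it.
#'   Defaults to the whole (linearised) molecule. Repeats spanning the
#'   origin are not searched.
#' @param kind `"direct"` or `"inverted"`.
#' @param min_length Minimum arm length (bp); must be >= 4.
#' @param min_identity Minimum identity fraction, in (0.5, 1].
#' @param max_arm Longest arm considered (bp); extension past this length
#'   is treated as structurally blocked.
#' @return A tibble of class `repeat_set` with columns `kind`, `arm1_start`,
#'   `arm1_end`, `arm2_start`, `arm2_end`, `length`, `identity`, `motif`
#'   (the arm1 sequence), 1-based inclusive coordinates.
#' @export
find_repeats <- function(seq, region = NULL, kind = c("direct", "inverted"),
                         min_length = 10L, min_identity = 0.8,
                         max_arm = 100L) {
  kind <- match.arg(kind)
  stopifnot(inherits(seq, "circular_seq"))
  if (min_length < 4) stop("min_length < 4: seed infeasible", call. = FALSE)
  if (min_identity <= 0.5 || min_identity > 1) {
    stop("min_identity must lie in (0.5, 1]", call. = FALSE)
  }
  if (is.null(region)) region <- arc_region(1L, seq$length)
  s <- subsequence(seq, region$start, region$end)
  hits <- .repeat_scan_cpp(s, kind == "direct", as.integer(min_length),
                           min_identity, as.integer(max_arm))
  off <- region$start - 1L
  out <- tibble::tibble(
    kind = rep(kind, nrow(hits)),
    arm1_start = hits$arm1_start + off,
    arm1_end = hits$arm1_start + hits$length - 1L + off,
    arm2_start = hits$arm2_start + off,
    arm2_end = hits$arm2_start + hits$length - 1L + off,
    length = hits$length,
    identity = hits$matches / hits$length
  )
  out <- dplyr::arrange(out, .data$arm1_start, .data$arm2_start)
  out$motif <- if (nrow(out) == 0) character(0) else
    substring(seq$residues, out$arm1_start, out$arm1_end)
  attr(out, "params") <- list(kind = kind, min_length = min_length,
                              min_identity = min_identity, max_arm = max_arm,
                              region = region)
  class(out) <- c("repeat_set", class(out))
  out
}

#' Perfect direct repeats (identity 1)
#'
#' @inheritParams find_repeats
#' @return A `repeat_set` tibble; every pair has `identity == 1`.
#' @export
#' @examples
#' s <- circular_seq(paste0(strrep("A", 20), "ACCTCCCTCACCA",
#'                          strrep("C", 20), "ACCTCCCTCACCA",
#'                          strrep("G", 20)))
#' find_perfect_direct(s)
find_perfect_direct <- function(seq, region = NULL, min_length = 10L,
                                max_arm = 100L) {
  find_repeats(seq, region, "direct", min_length, min_identity = 1,
               max_arm = max_arm)
}

#' Degraded (imperfect) repeats
#'
#' @inheritParams find_repeats
#' @export
find_degraded <- function(seq, region = NULL, kind = c("direct", "inverted"),
                          min_length = 10L, min_identity = 0.8,
                          max_arm = 100L) {
  find_repeats(seq, region, kind, min_length, min_identity, max_arm)
}

#' Per-window-pair repeat density matrix
#'
#' Cell (i, j) counts the nucleotides (each genome position at most once
#' per cell) lying inside window i in an arm whose partner arm intersects
#' window j, plus the mirror contribution from window j; a pair with both
#' arms fully inside windows i and j of arm length 12 therefore contributes
#' 24. Arms straddling a window boundary contribute their nucleotides to
#' the adjacent cells pro rata.
#'
#' @param repeats A `repeat_set` tibble.
#' @param grid A [build_grid()] result.
#' @return A symmetric `n_windows x n_windows` integer matrix.
#' @export
repeat_density_matrix <- function(repeats, grid) {
  nw <- attr(grid, "n_windows")
  acc <- new.env(parent = emptyenv())
  add <- function(i, j, positions) {
    key <- paste0(i, "_", j)
    acc[[key]] <- c(acc[[key]], positions)
  }
  if (nrow(repeats) > 0) {
    for (r in seq_len(nrow(repeats))) {
      a1 <- repeats$arm1_start[r]:repeats$arm1_end[r]
      a2 <- repeats$arm2_start[r]:repeats$arm2_end[r]
      w1 <- window_of(grid, a1)
      w2 <- window_of(grid, a2)
      for (i in unique(w1[!is.na(w1)])) {
        for (j in unique(w2[!is.na(w2)])) {
          add(i, j, a1[which(w1 == i)])
          add(i, j, a2[which(w2 == j)])
        }
      }
    }
  }
  m <- matrix(0L, nw, nw)
  for (key in ls(acc)) {
    ij <- as.integer(strsplit(key, "_")[[1]])
    cnt <- length(unique(acc[[key]]))
    m[ij[1], ij[2]] <- m[ij[1], ij[2]] + cnt
  }
  # symmetrise: (i, j) and (j, i) describe the same unordered cell
  out <- m + t(m)
  diag(out) <- diag(m)
  out
}

#' Write a repeat set as TSV
#'
#' @param repeats A `repeat_set` tibble.
#' @param path Output path.
#' @export
write_repeats <- function(repeats, path) {
  write.table(as.data.frame(repeats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
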