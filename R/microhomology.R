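#' Alignment parameters for the microhomology score
#'
#' Defaults follow the EMBOSS Needle DNA defaults: match +5, mismatch -4
#' (the EDNAFULL diagonal/off-diagonal), gap open 10, gap extend 0.5 (both
#' penalties), and free end gaps (Needle's `endweight = false`). Setting
#' `end_gaps_free = FALSE` penalises terminal gaps like an ordinary global
#' alignment.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open,gap_extend Gap penalties (non-negative;
#'   `gap_open >= gap_extend`). A gap of length L costs
#'   `gap_open + gap_extend * L`.
#' @param end_gaps_free Logical.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(match = 5, mismatch = -4, gap_open = 10,
                             gap_extend = 0.5, end_gaps_free = TRUE) {
  stopifnot(gap_open >= gap_extend, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, end_gaps_free = end_gaps_free),
            class = "alignment_params")
}

#' Global (Needleman-Wunsch) alignment score under affine gaps
#'
#' Score only, no traceback; deterministic; invariant to argument order.
#' Identical sequences of length L score `match * L` exactly.
#'
#' @param a,b Non-empty nucleotide strings.
#' @param params An [alignment_params()].
#' @return Numeric scalar score.
#' @export
#' @examples
#' global_align_score("AAAA", "AAAT")  # 3*5 - 4 = 11
global_align_score <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  .nw_score_cpp(toupper(a), toupper(b), params$match, params$mismatch,
                params$gap_open, params$gap_extend, params$end_gaps_free)
}

#' Microhomology similarity matrix over a window grid
#'
#' Aligns every unordered pair of grid windows globally and records the
#' score; with the default 100-window grid that is C(100, 2) = 4950
#' pairwise alignments. The matrix is symmetric; the diagonal holds each
#' window's self-score (`match * window_length`) and is excluded from all
#' downstream modelling.
#'
#' @param seq A [circular_seq()].
#' @param grid A [build_grid()] result.
#' @param params An [alignment_params()].
#' @return A symmetric numeric matrix with attribute `grid`.
#' @export
microhomology_matrix <- function(seq, grid, params = alignment_params()) {
  w <- grid_sequences(seq, grid)
  m <- .nw_matrix_cpp(w, params$match, params$mismatch, params$gap_open,
                      params$gap_extend, params$end_gaps_free)
  attr(m, "grid") <- grid
  attr(m, "params") <- params
  m
}

#' z-standardize a numeric vector
#'
#' Standardized predictors make the logistic-regression coefficients
#' directly comparable in magnitude. The transform parameters are stored so
#' it can be inverted with [unstandardize()].
#'
#' @param x Numeric vector with positive variance.
#' @return `x` centred and scaled to mean 0, sd 1, with attributes `mean`
#'   and `sd`.
#' @export
standardize <- function(x) {
  m <- mean(x)
  s <- sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance: cannot standardize",
                                    call. = FALSE)
  structure((x - m) / s, mean = m, sd = s)
}

#' @rdname standardize
#' @param z A vector produced by [standardize()].
#' @export
unstandardize <- function(z) {
  as.numeric(z) * attr(z, "sd") + attr(z, "mean")
}

#' Write a dense window-pair matrix as TSV
#'
#' @param m A square matrix on a window grid.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  d <- as.data.frame(m)
  names(d) <- paste0("w", seq_len(ncol(m)))
  write.table(cbind(window = seq_len(nrow(m)), d), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense window-pair matrix written by [write_matrix_tsv()]
#'
#' @param path Path to the TSV.
#' @return A numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  d <- read.delim(path, sep = "\t", check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  dimnames(m) <- NULL
  m
}
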