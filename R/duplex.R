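#' Nearest-neighbor DNA duplex parameters (37 degrees C)
#'
#' Loads the unified nearest-neighbor free-energy increments for the 16
#' Watson-Crick stacks, the duplex initiation penalty and the terminal A:T
#' penalty from a two-column TSV (`parameter`, `value`). The packaged table
#' is the unified 37 C set; stacks must be negative and symmetric under
#' reverse complementation of the dimer, which is validated on load.
#'
#' @param path Path to a parameter TSV; default is the packaged table.
#' @param loop_open,loop_extend Affine penalty (kcal/mol) for interior
#'   loops/bulges: a loop skipping g bases costs
#'   `loop_open + loop_extend * g`.
#' @return A list of class `nn_params` with elements `stack` (4x4 matrix,
#'   rows/cols in A, C, G, T order, entry \[x, y\] = dG of the 5'-xy-3'
#'   stack), `initiation`, `terminal_at`, `loop_open`, `loop_extend`.
#' @export
nn_params <- function(path = NULL, loop_open = 4, loop_extend = 0.5) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_unified_dG37.tsv", package = "mitoarc")
  }
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$value, tab$parameter)
  bases <- c("A", "C", "G", "T")
  stack <- matrix(NA_real_, 4, 4, dimnames = list(bases, bases))
  for (x in bases) for (y in bases) stack[x, y] <- vals[[paste0(x, y)]]
  if (any(stack >= 0)) stop("all stack dG must be negative", call. = FALSE)
  for (x in bases) for (y in bases) {
    rc <- chartr("ACGT", "TGCA", paste0(y, x))
    rcd <- strsplit(rc, "")[[1]]
    if (abs(stack[x, y] - stack[rcd[1], rcd[2]]) > 1e-9) {
      stop("stack table not reverse-complement symmetric at ", x, y,
           call. = FALSE)
    }
  }
  structure(list(stack = stack,
                 initiation = unname(vals[["initiation"]]),
                 terminal_at = unname(vals[["terminal_AT"]]),
                 loop_open = loop_open, loop_extend = loop_extend),
            class = "nn_params")
}

#' Minimum free energy of an intermolecular DNA duplex
#'
#' Hybridizes strand `a` with strand `b` (antiparallel), allowing interior
#' loops and bulges under an affine penalty but no intramolecular
#' structure. The optimum over all duplex alignments is reported; 0 means
#' no pairing achieves a stabilising (negative) free energy. Symmetric in
#' its arguments; for perfect complements dG decreases monotonically with
#' length.
#'
#' @param a,b Nucleotide strings over A, C, G, T (N never pairs).
#' @param params An [nn_params()].
#' @return dG in kcal/mol (<= 0).
#' @export
#' @examples
#' duplex_energy(strrep("A", 10), strrep("T", 10))
duplex_energy <- function(a, b, params = nn_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence", call. = FALSE)
  .duplex_energy_cpp(toupper(a), toupper(b), params$stack,
                     params$initiation, params$terminal_at,
                     params$loop_open, params$loop_extend)
}

#' Window-pair hybridization energy matrix
#'
#' Approximates the fine-scale contact structure of the single-stranded
#' major arc: every unordered pair of grid windows is hybridized in silico
#' and its duplex free energy recorded. More negative energy means a
#' stronger predicted contact; window pairs linked by inverted repeats
#' stand out as the most negative cells.
#'
#' @param seq A [circular_seq()].
#' @param grid A [build_grid()] result.
#' @param params An [nn_params()].
#' @return A symmetric numeric matrix (kcal/mol) with attribute `grid`.
#' @export
energy_matrix <- function(seq, grid, params = nn_params()) {
  w <- grid_sequences(seq, grid)
  m <- .duplex_matrix_cpp(w, params$stack, params$initiation,
                          params$terminal_at, params$loop_open,
                          params$loop_extend)
  attr(m, "grid") <- grid
  m
}

#' Rank correlation between a contact matrix and a repeat-density matrix
#'
#' Stronger contact means more negative dG, so when `contacts` holds
#' energies the correlation is computed on `-contacts`. Cells with
#' `|i - j| <= band_width` (including the diagonal) are removed before the
#' Spearman correlation, mirroring the regression cell table.
#'
#' @param contacts Square matrix: duplex energies ([energy_matrix()]) or an
#'   imported contact matrix ([import_external_fold()]).
#' @param density Square matrix from [repeat_density_matrix()].
#' @param band_width Half-width (in windows) of the excluded diagonal band.
#' @param contacts_are_energies If TRUE (default) flip the sign of
#'   `contacts` before correlating.
#' @return A tibble with `rho`, `p_value`, `n`.
#' @export
correlate_contacts <- function(contacts, density, band_width = 10L,
                               contacts_are_energies = TRUE) {
  stopifnot(all(dim(contacts) == dim(density)))
  n <- nrow(contacts)
  idx <- which(upper.tri(contacts) & abs(row(contacts) - col(contacts)) > band_width)
  if (length(idx) < 3) {
    stop("no cells left after band exclusion", call. = FALSE)
  }
  x <- contacts[idx]
  if (contacts_are_energies) x <- -x
  y <- density[idx]
  if (sd(x) == 0 || sd(y) == 0) {
    stop("degenerate (constant) matrix: correlation undefined", call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value,
                 n = length(idx))
}

#' Import an externally computed whole-molecule folding contact matrix
#'
#' Bridge to external secondary-structure tools: accepts either a dense
#' numeric TSV (n_windows x n_windows, as written by [write_matrix_tsv()])
#' or a base-pair list with columns (i, j, bond), where `bond` is a
#' hydrogen-bond count or a base-pair string ("GC"/"CG" = 3 bonds,
#' "AT"/"TA" = 2). Base pairs are aggregated into grid cells by the windows
#' containing each partner nucleotide.
#'
#' @param path Path to the TSV.
#' @param grid A [build_grid()] result.
#' @return A symmetric numeric matrix of hydrogen-bond counts.
#' @export
import_external_fold <- function(path, grid) {
  nw <- attr(grid, "n_windows")
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !nzchar(first)) {
    warning("empty contact file: returning zero matrix")
    return(matrix(0, nw, nw))
  }
  d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                  check.names = FALSE, header = FALSE)
  # tolerate a header line
  if (suppressWarnings(is.na(as.numeric(d[1, 1]))) ||
      suppressWarnings(is.na(as.numeric(d[1, 2])))) {
    d <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, header = TRUE)
    if (names(d)[1] %in% c("window", "window_index")) d <- d[, -1]
  }
  if (ncol(d) == 3L) {
    i <- as.integer(d[[1]]); j <- as.integer(d[[2]])
    bond <- d[[3]]
    if (is.character(bond)) {
      bp <- toupper(bond)
      bondn <- ifelse(bp %in% c("GC", "CG"), 3,
                      ifelse(bp %in% c("AT", "TA"), 2, NA_real_))
      if (anyNA(bondn)) {
        stop("unrecognised base pair(s): ",
             paste(unique(bp[is.na(bondn)]), collapse = ", "), call. = FALSE)
      }
    } else {
      bondn <- as.numeric(bond)
    }
    wi <- window_of(grid, i)
    wj <- window_of(grid, j)
    out_of <- unique(c(i[is.na(wi)], j[is.na(wj)]))
    if (length(out_of) > 0) {
      stop("coordinates outside the grid: ",
           paste(head(sort(out_of), 10), collapse = ", "), call. = FALSE)
    }
    m <- matrix(0, nw, nw)
    for (k in seq_along(wi)) {
      a <- wi[k]; b <- wj[k]
      m[a, b] <- m[a, b] + bondn[k]
      if (a != b) m[b, a] <- m[b, a] + bondn[k]
    }
    return(m)
  }
  m <- unname(as.matrix(d))
  storage.mode(m) <- "double"
  if (!all(dim(m) == c(nw, nw))) {
    stop("dense matrix is ", nrow(m), "x", ncol(m), ", expected ", nw, "x",
         nw, call. = FALSE)
  }
  m
}
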