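#' Specify a repeat pair to plant in a synthetic genome
#'
#' @param kind `"direct"` or `"inverted"`.
#' @param motif_length Arm length in bp.
#' @param positions Length-2 integer vector: 1-based start of each arm.
#' @param mismatches Substitutions introduced into the second arm copy.
#' @return A list of class `plant_spec`.
#' @export
plant_spec <- function(kind = c("direct", "inverted"), motif_length,
                       positions, mismatches = 0L) {
  kind <- match.arg(kind)
  stopifnot(length(positions) == 2L, positions[1] < positions[2],
            motif_length >= 1, mismatches >= 0, mismatches < motif_length)
  if (positions[1] + motif_length - 1L >= positions[2]) {
    stop("planted arms overlap", call. = FALSE)
  }
  structure(list(kind = kind, motif_length = as.integer(motif_length),
                 positions = as.integer(positions),
                 mismatches = as.integer(mismatches)),
            class = "plant_spec")
}

#' Generate a circular genome with planted repeats
#'
#' Background residues are i.i.d. with the given GC content (no
#' dinucleotide structure -- sufficient for the rank-based downstream
#' checks). Each plant writes a random motif at its first position and the
#' same motif (or its reverse complement for inverted plants) at the
#' second, then applies the requested number of mismatches to the second
#' copy. Bit-reproducible under `seed`.
#'
#' @param length Genome length in bp.
#' @param gc GC fraction of the background.
#' @param plants List of [plant_spec()] objects (arms must not overlap
#'   between plants).
#' @param seed Optional integer seed.
#' @param id Sequence identifier.
#' @return A list with `seq` (a [circular_seq()]) and `truth` (a tibble of
#'   planted repeats: kind, arm coordinates, motif, mismatches).
#' @export
generate_genome <- function(length = 16569L, gc = 0.44, plants = list(),
                            seed = NULL, id = "synthetic") {
  run <- function() {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    res <- sample(names(p), length, replace = TRUE, prob = p)
    spans <- list()
    truth <- list()
    for (pl in plants) {
      stopifnot(inherits(pl, "plant_spec"))
      a1 <- pl$positions[1]:(pl$positions[1] + pl$motif_length - 1L)
      a2 <- pl$positions[2]:(pl$positions[2] + pl$motif_length - 1L)
      if (max(a2) > length) stop("plant outside genome", call. = FALSE)
      for (sp in spans) {
        if (length(intersect(sp, c(a1, a2))) > 0) {
          stop("overlapping plants", call. = FALSE)
        }
      }
      spans <- c(spans, list(c(a1, a2)))
      motif <- res[a1]
      arm2 <- if (pl$kind == "direct") motif
              else strsplit(reverse_complement(paste(motif, collapse = "")),
                            "")[[1]]
      if (pl$mismatches > 0) {
        pos <- sample(pl$motif_length, pl$mismatches)
        for (q in pos) {
          arm2[q] <- sample(setdiff(c("A", "C", "G", "T"), arm2[q]), 1)
        }
      }
      res[a2] <- arm2
      truth[[length(truth) + 1]] <- tibble::tibble(
        kind = pl$kind,
        arm1_start = pl$positions[1], arm1_end = max(a1),
        arm2_start = pl$positions[2], arm2_end = max(a2),
        length = pl$motif_length, mismatches = pl$mismatches,
        motif = paste(motif, collapse = "")
      )
    }
    list(seq = circular_seq(paste(res, collapse = ""), id = id),
         truth = dplyr::bind_rows(truth))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Generative logistic model for synthetic deletions
#'
#' The generator inverts the fitted deletion model: each included cell of
#' the window grid realizes a deletion with probability
#' `plogis(beta0 + beta_ms * ms_z + beta_cz * cz)`.
#'
#' @param beta0,beta_ms,beta_cz Coefficients on the logit scale (`cz` is
#'   the raw 0/1 indicator).
#' @param zone5,zone3 Contact-zone intervals (bp).
#' @param band_width Excluded diagonal band (windows).
#' @param contact_point Optional length-2 integer vector of window indices
#'   (i0, j0). When given, the zone indicator is replaced by a planted
#'   contact point: cells realize deletions with probability
#'   `plogis(beta0 + beta_ms * ms_z + beta_dist * dist_z)`, where `dist`
#'   is the Euclidean distance (bp) from each cell's window centers to the
#'   planted point's. This is the ground truth the minimum-AIC scan should
#'   recover.
#' @param beta_dist Coefficient of the standardized distance (negative:
#'   deletions concentrate near the contact point).
#' @param seed Optional integer seed.
#' @return A list of class `generative_model`.
#' @export
generative_model <- function(beta0 = -2.38, beta_ms = 0.33, beta_cz = 0.91,
                             zone5 = c(6000, 9000), zone3 = c(13000, 16000),
                             band_width = 10L, contact_point = NULL,
                             beta_dist = -1, seed = NULL) {
  structure(list(beta0 = beta0, beta_ms = beta_ms, beta_cz = beta_cz,
                 zone5 = zone5, zone3 = zone3,
                 band_width = as.integer(band_width),
                 contact_point = contact_point, beta_dist = beta_dist,
                 seed = seed),
            class = "generative_model")
}

#' Draw a synthetic deletion table from the logistic realization model
#'
#' For each included cell a Bernoulli draw decides whether the cell
#' realizes a deletion; realized cells emit one deletion with the 5'
#' breakpoint uniform within window i and the 3' breakpoint uniform within
#' window j. The returned truth records every cell's probability, so any
#' expectation used in a test can be recomputed.
#'
#' @param grid A [build_grid()] result.
#' @param mm A [microhomology_matrix()] on the same grid.
#' @param model A [generative_model()].
#' @return A list with `deletions` (a deletion tibble) and `truth` (the
#'   per-cell tibble with `ms_z`, `cz`, `p`, `y`).
#' @export
generate_deletions <- function(grid, mm, model) {
  stopifnot(inherits(model, "generative_model"))
  run <- function() {
    cells <- build_cell_table(grid, mm,
                              deletion_table(integer(0), integer(0)),
                              band_width = model$band_width)
    cells <- code_contact_zone(cells, model$zone5, model$zone3)
    p <- if (is.null(model$contact_point)) {
      plogis(model$beta0 + model$beta_ms * cells$ms_z +
             model$beta_cz * cells$cz)
    } else {
      grd <- attr(cells, "grid")
      c0 <- grd$center[model$contact_point]
      d <- sqrt((cells$center_i - c0[1])^2 + (cells$center_j - c0[2])^2)
      plogis(model$beta0 + model$beta_ms * cells$ms_z +
             model$beta_dist * as.numeric(standardize(d)))
    }
    y <- rbinom(nrow(cells), 1L, p)
    hit <- which(y == 1L)
    wl <- attr(grid, "window_length")
    d5 <- grid$start[cells$i[hit]] + sample.int(wl, length(hit),
                                                replace = TRUE) - 1L
    d3 <- grid$start[cells$j[hit]] + sample.int(wl, length(hit),
                                                replace = TRUE) - 1L
    truth <- tibble::tibble(i = cells$i, j = cells$j, ms_z = cells$ms_z,
                            cz = cells$cz, p = p, y = y)
    list(deletions = deletion_table(d5, d3, provenance = "synthetic"),
         truth = truth)
  }
  if (is.null(model$seed)) run() else withr::with_seed(model$seed, run())
}

#' Uniformly placed synthetic deletions (randomization-test null)
#'
#' Places `n` deletions uniformly at random within the arc, preserving the
#' drawn lengths: the length of each deletion comes from
#' `length_distribution` (a fixed value, a vector resampled with
#' replacement, or a function of `n`), then the 5' breakpoint is uniform
#' on the feasible integer range.
#'
#' @param n Number of deletions.
#' @param arc An [arc_region()].
#' @param length_distribution Fixed length, vector of lengths to resample,
#'   or `function(n)` returning lengths.
#' @param seed Optional integer seed.
#' @return A deletion tibble.
#' @export
generate_uniform_deletions <- function(n, arc = major_arc(),
                                       length_distribution = 4000L,
                                       seed = NULL) {
  run <- function() {
    span <- arc$end - arc$start + 1L
    L <- if (is.function(length_distribution)) {
      as.integer(length_distribution(n))
    } else if (length(length_distribution) == 1L) {
      rep(as.integer(length_distribution), n)
    } else if (length(length_distribution) == n) {
      as.integer(length_distribution)
    } else {
      as.integer(sample(length_distribution, n, replace = TRUE))
    }
    if (any(L >= span)) stop("deletion length exceeds arc span",
                             call. = FALSE)
    hi <- arc$end - L
    d5 <- arc$start + floor(runif(n) * (hi - arc$start + 1))
    deletion_table(d5, d5 + L, provenance = "uniform_null")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
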