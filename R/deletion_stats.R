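#' Median and dispersion of deletion centers
#'
#' @param dels A deletion tibble (see [deletion_table()]).
#' @return A tibble with `n`, `median_center`, `sd_center`.
#' @export
centers_summary <- function(dels) {
  if (nrow(dels) == 0) stop("empty deletion set", call. = FALSE)
  tibble::tibble(n = nrow(dels),
                 median_center = median(dels$center),
                 sd_center = if (nrow(dels) > 1) sd(dels$center) else 0)
}

#' Randomization test for deletion-center dispersion
#'
#' Tests whether the observed deletion centers are more tightly clustered
#' than expected if each deletion, keeping its length, had been placed
#' uniformly at random within the arc. Each replicate repositions every
#' deletion independently (5' breakpoint uniform on the feasible integer
#' range) and records the standard deviation of the replicate midpoints;
#' the one-sided empirical p-value with add-one smoothing is
#' `(1 + #\{replicate sd <= observed sd\}) / (1 + n_replicates)`, so p = 0 is
#' never reported.
#'
#' @param dels A deletion tibble.
#' @param arc An [arc_region()]; every deletion must be shorter than the
#'   arc span.
#' @param n_replicates Number of randomization replicates.
#' @param seed Optional integer seed for reproducibility.
#' @param statistic `"sd_midpoints"` (default) uses the SD of the per-
#'   deletion midpoints in each replicate; `"sd_of_means"` collects each
#'   replicate's mean midpoint and compares the observed SD against the SD
#'   across replicate means (an alternative reading of the same procedure,
#'   kept behind this flag).
#' @return An object of class `center_dispersion` with fields
#'   `observed_sd`, `observed_median`, `replicate_sds`, `n_replicates`,
#'   `p_value`, `seed`.
#' @export
randomize_centers_test <- function(dels, arc = major_arc(),
                                   n_replicates = 10000L, seed = NULL,
                                   statistic = c("sd_midpoints",
                                                 "sd_of_means")) {
  statistic <- match.arg(statistic)
  if (nrow(dels) == 0) stop("empty deletion set", call. = FALSE)
  span <- arc$end - arc$start + 1L
  if (any(dels$length >= span)) {
    stop("deletion longer than the arc span", call. = FALSE)
  }
  run <- function() {
    L <- sort(dels$length)       # order-invariant replicate stream
    n <- length(L)
    obs_sd <- if (n > 1) sd(dels$center) else 0
    # replicate matrix of midpoints: n deletions x n_replicates
    hi <- arc$end - L                      # last feasible del5 per deletion
    u <- matrix(runif(n * n_replicates), nrow = n)
    d5 <- arc$start + floor(u * (hi - arc$start + 1L))
    mid <- d5 + L / 2
    if (statistic == "sd_midpoints") {
      rep_sds <- apply(mid, 2, sd)
    } else {
      rep_means <- colMeans(mid)
      rep_sds <- rep(sd(rep_means), n_replicates)
      obs_sd <- sd(dels$center)
    }
    p <- (1 + sum(rep_sds <= obs_sd)) / (1 + n_replicates)
    structure(list(observed_sd = obs_sd,
                   observed_median = median(dels$center),
                   replicate_sds = rep_sds,
                   n_replicates = as.integer(n_replicates),
                   p_value = p, seed = seed,
                   statistic = statistic),
              class = "center_dispersion")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.center_dispersion <- function(x, ...) {
  cat("Deletion-center dispersion randomization test\n",
      "  observed sd: ", format(x$observed_sd), " bp",
      " (median center ", format(x$observed_median), " bp)\n",
      "  replicates:  ", x$n_replicates, "\n",
      "  one-sided p: ", format(x$p_value), "\n", sep = "")
  invisible(x)
}

#' Density-based clustering of deletion breakpoints
#'
#' Clusters deletions in the (del5, del3) plane with a hierarchical
#' density-based algorithm (HDBSCAN: mutual-reachability minimum spanning
#' tree, condensed cluster tree, excess-of-mass cluster selection) and
#' labels low-density points as noise. Output is invariant to the ordering
#' of the input rows.
#'
#' @param dels A deletion tibble.
#' @param min_cluster_size Smallest cluster retained in the condensed tree.
#' @param min_samples Neighbourhood size used for core distances.
#' @return The input tibble with an integer `cluster` column (0 = noise,
#'   clusters numbered contiguously from 1) and a `params` attribute.
#' @export
cluster_breakpoints <- function(dels, min_cluster_size = 20L,
                                min_samples = 10L) {
  stopifnot(min_cluster_size >= 2L, min_samples >= 1L)
  X <- cbind(dels$del5, dels$del3)
  if (nrow(X) < min_cluster_size) {
    warning("fewer deletions than min_cluster_size: all points are noise")
    lab <- rep(0L, nrow(X))
  } else {
    # canonical point order makes the labelling input-order invariant
    ord <- order(X[, 1], X[, 2])
    lab_sorted <- hdbscan_labels(X[ord, , drop = FALSE], min_cluster_size,
                                 min_samples)
    lab <- integer(nrow(X))
    lab[ord] <- lab_sorted
    nz <- lab != 0L
    lab[nz] <- as.integer(factor(lab[nz], levels = unique(lab[nz])))
  }
  out <- dels
  out$cluster <- lab
  attr(out, "params") <- list(min_cluster_size = min_cluster_size,
                              min_samples = min_samples)
  out
}

#' Sweep clustering parameters to assess stability
#'
#' @param dels A deletion tibble.
#' @param min_cluster_sizes,min_samples Integer vectors defining the sweep
#'   grid.
#' @return A tibble with one row per parameter combination: the number of
#'   clusters found and the noise fraction.
#' @export
cluster_stability_sweep <- function(dels,
                                    min_cluster_sizes = c(10L, 20L, 30L),
                                    min_samples = c(5L, 10L, 15L)) {
  grid <- tidyr::expand_grid(min_cluster_size = min_cluster_sizes,
                             min_samples = min_samples)
  res <- purrr::pmap(grid, function(min_cluster_size, min_samples) {
    cl <- suppressWarnings(
      cluster_breakpoints(dels, min_cluster_size, min_samples))
    tibble::tibble(n_clusters = length(setdiff(unique(cl$cluster), 0L)),
                   noise_fraction = mean(cl$cluster == 0L))
  })
  dplyr::bind_cols(grid, dplyr::bind_rows(res))
}

#' Per-cluster breakpoint dispersion along each axis
#'
#' Deletion clusters tend to be wider along the 5' axis than the 3' axis;
#' this summarises, for every non-noise cluster, the SD of the 5' and 3'
#' breakpoints and flags clusters with `sd_5prime > sd_3prime`.
#'
#' @param clustered Output of [cluster_breakpoints()].
#' @return A tibble with one row per cluster: `cluster`, `n`, `sd_5prime`,
#'   `sd_3prime`, `wider_5prime`.
#' @export
breakpoint_axis_dispersion <- function(clustered) {
  clustered |>
    dplyr::filter(.data$cluster != 0L) |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(
      n = dplyr::n(),
      sd_5prime = if (dplyr::n() > 1) sd(.data$del5) else 0,
      sd_3prime = if (dplyr::n() > 1) sd(.data$del3) else 0,
      .groups = "drop"
    ) |>
    dplyr::mutate(wider_5prime = .data$sd_5prime > .data$sd_3prime)
}
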