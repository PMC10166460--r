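#' Build the per-cell regression table
#'
#' One record per unordered window pair (i < j) with `|i - j| > band_width`;
#' with the default 100-window grid and band width 10 that is
#' 4950 - 945 = 4005 cells. Each record carries the raw microhomology
#' score `ms_raw`, its z-score `ms_z` (standardized over the included
#' cells only), and the response `y`: 1 if at least one deletion has its
#' 5' breakpoint in window i and its 3' breakpoint in window j. Deletions
#' whose breakpoints fall outside the grid are dropped with a warning;
#' deletions landing in the excluded diagonal band are dropped from the
#' regression (but counted in the `y_total_*` attributes, which also
#' report the full-grid split of deletion-bearing vs empty cells).
#'
#' @param grid A [build_grid()] result.
#' @param mm A [microhomology_matrix()] on the same grid.
#' @param dels A deletion tibble.
#' @param band_width Diagonal half-width (in windows) to exclude.
#' @return A tibble of class `cell_table` with columns `i`, `j`,
#'   `center_i`, `center_j`, `ms_raw`, `ms_z`, `y`.
#' @export
build_cell_table <- function(grid, mm, dels, band_width = 10L) {
  nw <- attr(grid, "n_windows")
  stopifnot(nrow(mm) == nw, ncol(mm) == nw)
  pairs <- tidyr::expand_grid(i = seq_len(nw), j = seq_len(nw)) |>
    dplyr::filter(.data$i < .data$j)
  wi <- window_of(grid, dels$del5)
  wj <- window_of(grid, dels$del3)
  outside <- is.na(wi) | is.na(wj)
  if (any(outside)) {
    warning(sum(outside), " deletion(s) outside the window grid dropped")
  }
  hit <- unique(paste0(wi[!outside], "_", wj[!outside]))
  pairs$y <- as.integer(paste0(pairs$i, "_", pairs$j) %in% hit)
  y_total_1 <- sum(pairs$y)
  pairs$ms_raw <- mm[cbind(pairs$i, pairs$j)]
  pairs$center_i <- grid$center[pairs$i]
  pairs$center_j <- grid$center[pairs$j]
  cells <- dplyr::filter(pairs, .data$j - .data$i > band_width)
  cells$ms_z <- as.numeric(standardize(cells$ms_raw))
  cells <- dplyr::select(cells, "i", "j", "center_i", "center_j",
                         "ms_raw", "ms_z", "y")
  structure(cells,
            band_width = as.integer(band_width), grid = grid,
            ms_mean = mean(cells$ms_raw), ms_sd = sd(cells$ms_raw),
            y_total_cells = nrow(pairs), y_total_with_deletion = y_total_1,
            y_total_empty = nrow(pairs) - y_total_1,
            class = c("cell_table", class(cells)))
}

#' Code the contact-zone indicator for each cell
#'
#' A cell is inside the contact zone iff window i's center lies in `zone5`
#' and window j's center lies in `zone3` (inclusive bounds; membership is
#' by window center, not overlap fraction).
#'
#' @param cells A [build_cell_table()] result.
#' @param zone5,zone3 Length-2 numeric intervals (bp) for the 5' and 3'
#'   zone; defaults are the 6-9 kb and 13-16 kb regions.
#' @return `cells` with integer column `cz` and its z-scored version `cz_z`.
#' @export
code_contact_zone <- function(cells, zone5 = c(6000, 9000),
                              zone3 = c(13000, 16000)) {
  cz <- as.integer(cells$center_i >= zone5[1] & cells$center_i <= zone5[2] &
                   cells$center_j >= zone3[1] & cells$center_j <= zone3[2])
  cells$cz <- cz
  cells$cz_z <- if (sd(cz) > 0) as.numeric(standardize(cz)) else cz
  cells
}

#' Maximum-likelihood logistic regression
#'
#' Fits `response ~ predictors` by iteratively reweighted least squares
#' (binomial family, logit link), returning coefficients, standard errors,
#' the log-likelihood and `AIC = 2k - 2 logLik`. Errors on constant
#' predictors and on (quasi-)perfect separation.
#'
#' @param data A data frame.
#' @param response Name of the 0/1 response column.
#' @param predictors Character vector of predictor column names.
#' @param tol Convergence tolerance.
#' @param max_iter Maximum IRLS iterations.
#' @return An object of class `logistic_fit`.
#' @export
fit_logistic <- function(data, response = "y", predictors,
                         tol = 1e-8, max_iter = 100L) {
  y <- data[[response]]
  if (length(unique(y)) < 2) stop("constant response", call. = FALSE)
  for (p in predictors) {
    if (sd(data[[p]]) == 0) {
      stop("constant predictor: ", p, call. = FALSE)
    }
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[predictors]))
  fit <- glm.fit(X, y, family = binomial(),
                 control = list(epsilon = tol, maxit = max_iter))
  eta <- drop(X %*% fit$coefficients)
  if (max(abs(eta[is.finite(eta)])) > 30) {
    worst <- predictors[which.max(abs(fit$coefficients[-1]))]
    stop("(quasi-)perfect separation detected; predictor: ", worst,
         call. = FALSE)
  }
  p_hat <- plogis(eta)
  ll <- sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
  k <- ncol(X)
  # Wald standard errors from the observed information
  W <- p_hat * (1 - p_hat)
  XtWX <- crossprod(X, X * W)
  se <- sqrt(diag(solve(XtWX)))
  structure(list(
    coefficients = tibble::tibble(
      term = colnames(X),
      estimate = unname(fit$coefficients),
      std.error = unname(se),
      statistic = unname(fit$coefficients / se),
      p.value = 2 * stats::pnorm(-abs(unname(fit$coefficients / se)))
    ),
    loglik = ll, aic = 2 * k - 2 * ll, n = length(y), k = k,
    converged = fit$converged,
    response = response, predictors = predictors
  ), class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic fit: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  print(as.data.frame(x$coefficients), digits = 5)
  cat("logLik ", format(x$loglik), "  AIC ", format(x$aic),
      "  n ", x$n, if (!x$converged) "  [NOT CONVERGED]" else "", "\n",
      sep = "")
  invisible(x)
}

#' Microhomology-only and microhomology + contact-zone models
#'
#' `fit_ms_model()` regresses deletion presence on the standardized
#' microhomology score alone; `fit_ms_cz_model()` adds the contact-zone
#' indicator (raw 0/1 by default; set `standardize_cz = TRUE` to use its
#' z-score so coefficient magnitudes are comparable).
#'
#' @param cells A [build_cell_table()] result, for the CZ model after
#'   [code_contact_zone()].
#' @param standardize_cz Use the z-scored contact-zone indicator.
#' @return A `logistic_fit`.
#' @export
fit_ms_model <- function(cells) {
  fit_logistic(cells, "y", "ms_z")
}

#' @rdname fit_ms_model
#' @export
fit_ms_cz_model <- function(cells, standardize_cz = FALSE) {
  if (!"cz" %in% names(cells)) cells <- code_contact_zone(cells)
  fit_logistic(cells, "y", c("ms_z", if (standardize_cz) "cz_z" else "cz"))
}

#' Minimum-AIC contact-point scan
#'
#' For every included cell (i0, j0) as a candidate contact point, fits
#' `y ~ ms_z + dist_z` where `dist` is the Euclidean distance (bp) from
#' each cell's window-center pair to the candidate's, z-standardized, and
#' records the model AIC. The candidate with the minimum AIC is the
#' data-driven contact point. Fit failures are recorded as NA in the
#' surface and excluded from the argmin.
#'
#' @param cells A [build_cell_table()] result.
#' @param grid The grid the cells were built on (defaults to the attribute
#'   stored in `cells`).
#' @return An object of class `contact_scan`: list with `aic_surface`
#'   (n_windows x n_windows matrix, NA outside the included cells),
#'   `best` (one-row tibble: `i`, `j`, `center_5p`, `center_3p`, `aic`),
#'   and `fit`, the `logistic_fit` at the argmin.
#' @export
contact_point_scan <- function(cells, grid = attr(cells, "grid")) {
  if (length(unique(cells$y)) < 2) {
    stop("constant response: scan impossible", call. = FALSE)
  }
  nw <- attr(grid, "n_windows")
  ci <- cells$center_i
  cj <- cells$center_j
  n <- nrow(cells)
  X <- cbind(1, cells$ms_z, 0)
  y <- cells$y
  aics <- rep(NA_real_, n)
  fam <- binomial()
  ctrl <- list(epsilon = 1e-8, maxit = 50, trace = FALSE)
  for (k in seq_len(n)) {
    d <- sqrt((ci - ci[k])^2 + (cj - cj[k])^2)
    sdd <- sd(d)
    if (sdd == 0) next
    X[, 3] <- (d - mean(d)) / sdd
    fit <- tryCatch(
      suppressWarnings(glm.fit(X, y, family = fam, control = ctrl)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    p_hat <- plogis(drop(X %*% fit$coefficients))
    ll <- sum(y * log(p_hat) + (1 - y) * log(1 - p_hat))
    aics[k] <- 2 * 3 - 2 * ll
  }
  if (all(is.na(aics))) stop("every candidate fit failed", call. = FALSE)
  surface <- matrix(NA_real_, nw, nw)
  surface[cbind(cells$i, cells$j)] <- aics
  best_k <- which.min(aics)
  d <- sqrt((ci - ci[best_k])^2 + (cj - cj[best_k])^2)
  dat <- tibble::tibble(y = y, ms_z = cells$ms_z,
                        dist_z = as.numeric(standardize(d)))
  best_fit <- fit_logistic(dat, "y", c("ms_z", "dist_z"))
  structure(list(
    aic_surface = surface,
    best = tibble::tibble(i = cells$i[best_k], j = cells$j[best_k],
                          center_5p = ci[best_k], center_3p = cj[best_k],
                          aic = aics[best_k]),
    fit = best_fit,
    grid = grid
  ), class = "contact_scan")
}

#' @export
print.contact_scan <- function(x, ...) {
  cat("Contact-point AIC scan (", sum(!is.na(x$aic_surface)),
      " candidate fits)\n", sep = "")
  cat("  best contact point: windows (", x$best$i, ", ", x$best$j,
      "), centers (", x$best$center_5p, ", ", x$best$center_3p,
      ") bp, AIC ", format(x$best$aic), "\n", sep = "")
  invisible(x)
}

#' Write a cell table as TSV
#'
#' @param cells A [build_cell_table()] result.
#' @param path Output path.
#' @export
write_cells <- function(cells, path) {
  write.table(as.data.frame(cells), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
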