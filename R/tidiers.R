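#' Tidy a logistic fit
#'
#' @param x A `logistic_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @export
tidy.logistic_fit <- function(x, ...) x$coefficients

#' @rdname tidy.logistic_fit
#' @export
glance.logistic_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, nobs = x$n,
                 df = x$k, converged = x$converged)
}

#' Tidy a contact-point scan
#'
#' @param x A `contact_scan`.
#' @param ... Unused.
#' @return One row per candidate cell with its AIC.
#' @export
tidy.contact_scan <- function(x, ...) {
  idx <- which(!is.na(x$aic_surface), arr.ind = TRUE)
  g <- x$grid
  tibble::tibble(i = idx[, 1], j = idx[, 2],
                 center_5p = g$center[idx[, 1]],
                 center_3p = g$center[idx[, 2]],
                 aic = x$aic_surface[idx])
}

#' @rdname tidy.contact_scan
#' @export
glance.contact_scan <- function(x, ...) {
  dplyr::bind_cols(x$best,
                   tibble::tibble(n_candidates = sum(!is.na(x$aic_surface))))
}

#' Tidy a center-dispersion randomization test
#'
#' @param x A `center_dispersion`.
#' @param ... Unused.
#' @return One row per replicate with the replicate SD.
#' @export
tidy.center_dispersion <- function(x, ...) {
  tibble::tibble(replicate = seq_along(x$replicate_sds),
                 replicate_sd = x$replicate_sds)
}

#' @rdname tidy.center_dispersion
#' @export
glance.center_dispersion <- function(x, ...) {
  tibble::tibble(observed_sd = x$observed_sd,
                 observed_median = x$observed_median,
                 n_replicates = x$n_replicates,
                 p_value = x$p_value)
}
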