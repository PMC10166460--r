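#' Classify repeats as realized or non-realized against a deletion table
#'
#' A direct repeat is realized when some deletion is flanked by its arms:
#' the deletion's 5' breakpoint falls within `arm1 +/- tolerance` and its
#' 3' breakpoint within `arm2 +/- tolerance` (intervals expanded by
#' `tolerance` bp on each side, reflecting breakpoint-reporting ambiguity
#' inside repeated sequence). Calls are monotone in the tolerance: a larger
#' tolerance never un-realizes a repeat.
#'
#' @param repeats A `repeat_set` tibble ([find_repeats()]).
#' @param dels A deletion tibble.
#' @param tolerance Slack in bp between a breakpoint and its arm.
#' @return `repeats` with columns `realized` (logical), `n_matched`
#'   (deletions flanked by the pair) and `matched` (list of deletion row
#'   indices).
#' @export
call_realization <- function(repeats, dels, tolerance = 5L) {
  matched <- purrr::map(seq_len(nrow(repeats)), function(r) {
    which(dels$del5 >= repeats$arm1_start[r] - tolerance &
          dels$del5 <= repeats$arm1_end[r] + tolerance &
          dels$del3 >= repeats$arm2_start[r] - tolerance &
          dels$del3 <= repeats$arm2_end[r] + tolerance)
  })
  out <- repeats
  out$n_matched <- lengths(matched)
  out$realized <- out$n_matched > 0L
  out$matched <- matched
  attr(out, "tolerance") <- tolerance
  out
}

#' Group repeats with the same motif into clusters
#'
#' Repeats are grouped by motif identity (optionally widened to motif
#' families within a Hamming radius for equal-length motifs). A cluster is
#' retained only if it has at least `min_arms` distinct arms and at least
#' one realized pair (a deletion associated with two of its arms).
#'
#' @param calls Output of [call_realization()].
#' @param min_arms Minimum distinct arm count per cluster.
#' @param motif_radius Hamming radius for motif-family merging (0 = exact
#'   motif identity).
#' @return A tibble with one row per retained cluster: `cluster_id`,
#'   `motif_family`, `n_arms`, `n_pairs`, `n_realized`, and a nested
#'   `pairs` tibble of the member repeat pairs.
#' @export
build_motif_clusters <- function(calls, min_arms = 3L, motif_radius = 0L) {
  if (nrow(calls) == 0) return(empty_cluster_tbl())
  fam <- motif_families(calls$motif, motif_radius)
  calls$motif_family <- fam
  grp <- dplyr::group_by(calls, .data$motif_family)
  keys <- dplyr::group_keys(grp)$motif_family
  members <- dplyr::group_split(grp)
  rows <- purrr::map2(members, keys, function(m, key) {
    arms <- unique(c(paste0(m$arm1_start, ":", m$arm1_end),
                     paste0(m$arm2_start, ":", m$arm2_end)))
    n_realized <- sum(m$realized)
    if (length(arms) < min_arms || n_realized == 0) return(NULL)
    tibble::tibble(motif_family = key, n_arms = length(arms),
                   n_pairs = nrow(m), n_realized = n_realized,
                   pairs = list(m))
  })
  rows <- purrr::compact(rows)
  if (length(rows) == 0) return(empty_cluster_tbl())
  out <- dplyr::bind_rows(rows)
  out$cluster_id <- seq_len(nrow(out))
  dplyr::select(out, "cluster_id", "motif_family", "n_arms", "n_pairs",
                "n_realized", "pairs")
}

empty_cluster_tbl <- function() {
  tibble::tibble(cluster_id = integer(), motif_family = character(),
                 n_arms = integer(), n_pairs = integer(),
                 n_realized = integer(), pairs = list())
}

# exact grouping, or greedy Hamming-radius families for equal-length motifs
motif_families <- function(motifs, radius = 0L) {
  if (radius == 0L) return(motifs)
  uniq <- unique(motifs)
  uniq <- uniq[order(-tabulate(match(motifs, uniq)), uniq)]
  rep_of <- character(0)
  fam <- stats::setNames(character(length(uniq)), uniq)
  hamming <- function(a, b) {
    if (nchar(a) != nchar(b)) return(Inf)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }
  for (m in uniq) {
    hit <- NULL
    for (r in rep_of) {
      if (hamming(m, r) <= radius) { hit <- r; break }
    }
    if (is.null(hit)) { rep_of <- c(rep_of, m); hit <- m }
    fam[m] <- hit
  }
  unname(fam[motifs])
}

#' Admissible realized/non-realized pairs within motif clusters
#'
#' Within each cluster, a non-realized repeat is paired with a realized one
#' only if they share an arm: the same arm1 interval (same 5' start) or the
#' same arm2 interval (same 3' end). Differences are non-realized minus
#' realized.
#'
#' @param clusters Output of [build_motif_clusters()].
#' @return A tibble with one row per admissible pair: `cluster_id`,
#'   `d_start` (5' start difference, bp), `d_end` (3' end difference, bp),
#'   `d_arm_distance` (inter-arm gap difference, bp).
#' @export
admissible_pairs <- function(clusters) {
  res <- purrr::map2(clusters$pairs, clusters$cluster_id, function(m, id) {
    re <- m[m$realized, , drop = FALSE]
    nr <- m[!m$realized, , drop = FALSE]
    if (nrow(re) == 0 || nrow(nr) == 0) return(NULL)
    out <- list()
    for (a in seq_len(nrow(re))) for (b in seq_len(nrow(nr))) {
      share1 <- re$arm1_start[a] == nr$arm1_start[b] &&
                re$arm1_end[a] == nr$arm1_end[b]
      share2 <- re$arm2_start[a] == nr$arm2_start[b] &&
                re$arm2_end[a] == nr$arm2_end[b]
      if (!share1 && !share2) next
      gap_re <- re$arm2_start[a] - re$arm1_end[a]
      gap_nr <- nr$arm2_start[b] - nr$arm1_end[b]
      out[[length(out) + 1]] <- tibble::tibble(
        cluster_id = id,
        d_start = nr$arm1_start[b] - re$arm1_start[a],
        d_end = nr$arm2_end[b] - re$arm2_end[a],
        d_arm_distance = gap_nr - gap_re
      )
    }
    if (length(out) == 0) NULL else dplyr::bind_rows(out)
  })
  res <- purrr::compact(res)
  if (length(res) == 0) {
    return(tibble::tibble(cluster_id = integer(), d_start = numeric(),
                          d_end = numeric(), d_arm_distance = numeric()))
  }
  dplyr::bind_rows(res)
}

#' Positional contrasts between realized and non-realized repeats
#'
#' Summarises the admissible pairs: median differences (non-realized minus
#' realized) in 5' start, 3' end and inter-arm distance, with paired
#' Wilcoxon (Mann-Whitney) tests of the null of no shift. A single
#' admissible pair still yields the medians, with `p_reliable = FALSE`.
#'
#' @param clusters Output of [build_motif_clusters()].
#' @return A one-row tibble: medians, p-values, `n_pairs`, `n_clusters`,
#'   `p_reliable`.
#' @export
paired_position_contrasts <- function(clusters) {
  pr <- admissible_pairs(clusters)
  if (nrow(pr) == 0) stop("no admissible realized/non-realized pairs",
                          call. = FALSE)
  ptest <- function(x) {
    if (all(x == 0)) return(1)
    tryCatch(suppressWarnings(wilcox.test(x, mu = 0)$p.value),
             error = function(e) NA_real_)
  }
  tibble::tibble(
    median_d_start = median(pr$d_start),
    median_d_end = median(pr$d_end),
    median_d_arm_distance = median(pr$d_arm_distance),
    p_start = ptest(pr$d_start),
    p_end = ptest(pr$d_end),
    p_arm_distance = ptest(pr$d_arm_distance),
    n_pairs = nrow(pr),
    n_clusters = dplyr::n_distinct(pr$cluster_id),
    p_reliable = nrow(pr) >= 10
  )
}

#' Contact-zone enrichment of realized repeats
#'
#' Cross-classifies repeat pairs by realization and by contact-zone
#' membership (inside iff the arm1 center lies in `zone5` and the arm2
#' center in `zone3`) and tests the association with Fisher's exact test.
#' The conditional maximum-likelihood odds ratio (Fisher) is reported
#' alongside the sample (cross-product) odds ratio; when a margin is zero
#' the sample OR uses the Haldane-Anscombe 0.5 correction and is flagged.
#'
#' @param calls Output of [call_realization()].
#' @param zone5,zone3 Contact-zone intervals in bp.
#' @return A one-row tibble: the 2x2 counts
#'   (`realized_in`, `realized_out`, `nonrealized_in`, `nonrealized_out`),
#'   `odds_ratio` (conditional MLE), `odds_ratio_sample`, `p_value`,
#'   `haldane_corrected`.
#' @export
contact_zone_enrichment <- function(calls, zone5 = c(6000, 9000),
                                    zone3 = c(13000, 16000)) {
  c1 <- (calls$arm1_start + calls$arm1_end) / 2
  c2 <- (calls$arm2_start + calls$arm2_end) / 2
  inside <- c1 >= zone5[1] & c1 <= zone5[2] & c2 >= zone3[1] & c2 <= zone3[2]
  a <- sum(calls$realized & inside)
  b <- sum(calls$realized & !inside)
  cc <- sum(!calls$realized & inside)
  d <- sum(!calls$realized & !inside)
  tab <- matrix(c(a, cc, b, d), 2, 2,
                dimnames = list(c("realized", "non_realized"),
                                c("inside", "outside")))
  ft <- fisher.test(tab)
  zero_margin <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or_sample <- if (zero_margin || any(tab == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  tibble::tibble(
    realized_in = a, realized_out = b,
    nonrealized_in = cc, nonrealized_out = d,
    odds_ratio = unname(ft$estimate),
    odds_ratio_sample = or_sample,
    p_value = ft$p.value,
    haldane_corrected = zero_margin || any(tab == 0)
  )
}
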