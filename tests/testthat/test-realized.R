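make_repeat <- function(a1s, a1e, a2s, a2e, motif = "M") {
  tibble::tibble(kind = "direct", arm1_start = a1s, arm1_end = a1e,
                 arm2_start = a2s, arm2_end = a2e,
                 length = a1e - a1s + 1L, identity = 1, motif = motif)
}

test_that("realization calls flank deletions within tolerance", {
  common <- make_repeat(8470L, 8482L, 13447L, 13459L)
  d1 <- deletion_table(8470L, 13447L)
  expect_true(call_realization(common, d1)$realized)
  d2 <- deletion_table(9000L, 14000L)
  expect_false(call_realization(common, d2)$realized)

  # off-by-3 breakpoints realize only under a large enough tolerance
  d3 <- deletion_table(8467L, 13462L)
  expect_false(call_realization(common, d3, tolerance = 0)$realized)
  expect_true(call_realization(common, d3, tolerance = 50)$realized)
})

test_that("realization is monotone in tolerance", {
  set.seed(71)
  reps <- dplyr::bind_rows(lapply(1:30, function(k) {
    a1 <- sample(6000:9000, 1)
    a2 <- sample(13000:15000, 1)
    make_repeat(a1, a1 + 11L, a2, a2 + 11L)
  }))
  dels <- generate_uniform_deletions(40, seed = 72,
                                     length_distribution = 5000:8000)
  prev <- rep(FALSE, nrow(reps))
  for (tol in c(0, 5, 20, 50)) {
    cur <- call_realization(reps, dels, tolerance = tol)$realized
    expect_true(all(cur[prev]))   # larger tolerance never un-realizes
    prev <- cur
  }
})

test_that("motif clusters require three arms and one realized pair", {
  # motif M at loci a=1000, b=3000, c=9000; deletion joins a-c
  pairs <- dplyr::bind_rows(
    make_repeat(1000L, 1011L, 3000L, 3011L),   # a-b
    make_repeat(1000L, 1011L, 9000L, 9011L),   # a-c (realized)
    make_repeat(3000L, 3011L, 9000L, 9011L))   # b-c
  dels <- deletion_table(1000L, 9011L)
  calls <- call_realization(pairs, dels)
  expect_equal(sum(calls$realized), 1L)
  cl <- build_motif_clusters(calls)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$n_arms, 3L)

  # only two loci -> fewer than three arms -> excluded
  two <- call_realization(make_repeat(1000L, 1011L, 3000L, 3011L),
                          deletion_table(1000L, 3011L))
  expect_equal(nrow(build_motif_clusters(two)), 0L)

  # three loci but no deletion -> excluded
  none <- call_realization(pairs, deletion_table(100L, 200L))
  expect_equal(nrow(build_motif_clusters(none)), 0L)
})

test_that("admissible pairs share an arm with a realized pair", {
  pairs <- dplyr::bind_rows(
    make_repeat(1000L, 1011L, 9000L, 9011L),   # realized (a-c)
    make_repeat(1000L, 1011L, 3000L, 3011L),   # shares arm1 -> admissible
    make_repeat(4000L, 4011L, 7000L, 7011L))   # shares nothing
  calls <- call_realization(pairs, deletion_table(1000L, 9011L))
  cl <- build_motif_clusters(calls)
  ap <- admissible_pairs(cl)
  expect_equal(nrow(ap), 1L)
  expect_equal(ap$d_start, 0)                   # same 5' start
  expect_equal(ap$d_end, 3011 - 9011)
  expect_equal(ap$d_arm_distance, (3000 - 1011) - (9000 - 1011))
})

test_that("planted positional shifts are recovered by the contrasts", {
  set.seed(73)
  rows <- list()
  dels5 <- integer(0); dels3 <- integer(0)
  for (k in 1:120) {
    a1 <- sample(6200:8800, 1)
    a2 <- sample(13200:15500, 1)
    # realized pair at (a1, a2); the non-realized partner shares arm1 and
    # its second arm sits ~1300 bp earlier (so the inter-arm distance is
    # shorter by the same amount)
    shift <- round(rnorm(1, -1300, 100))
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      make_repeat(a1, a1 + 11L, a2, a2 + 11L, motif = paste0("m", k)),
      make_repeat(a1, a1 + 11L, a2 + shift, a2 + shift + 11L,
                  motif = paste0("m", k)))
    dels5 <- c(dels5, a1); dels3 <- c(dels3, a2)
  }
  reps <- dplyr::bind_rows(rows)
  calls <- call_realization(reps, deletion_table(dels5, dels3 + 11L))
  cl <- build_motif_clusters(calls)
  ct <- paired_position_contrasts(cl)
  expect_lt(abs(ct$median_d_end - (-1300)), 150)
  expect_lt(abs(ct$median_d_arm_distance - (-1300)), 150)
  expect_equal(ct$median_d_start, 0)
  expect_lt(ct$p_end, 0.001)
  expect_equal(ct$n_clusters, 120L)
})

test_that("identical realized and non-realized positions give zero shifts", {
  pairs <- dplyr::bind_rows(
    make_repeat(1000L, 1011L, 9000L, 9011L),
    make_repeat(1000L, 1011L, 9000L, 9011L))
  calls <- call_realization(pairs, deletion_table(1000L, 9011L))
  # both rows realized -> no admissible pairs
  expect_error(paired_position_contrasts(build_motif_clusters(calls)),
               "no admissible")

  pairs2 <- dplyr::bind_rows(
    make_repeat(1000L, 1011L, 3000L, 3011L),
    make_repeat(1000L, 1011L, 9000L, 9011L))
  calls2 <- call_realization(pairs2, deletion_table(1000L, 3011L))
  cl2 <- build_motif_clusters(calls2)
  ct2 <- paired_position_contrasts(cl2)
  # the shared 5' arm gives a zero start shift with p = 1
  expect_equal(ct2$median_d_start, 0)
  expect_equal(ct2$p_start, 1)
  expect_equal(ct2$median_d_end, 6000)
  expect_false(ct2$p_reliable)   # a single pair is flagged unreliable
})

test_that("contact-zone enrichment reproduces hand-computed tables", {
  # construct calls giving the 2x2 table [[30,10],[10,30]]
  mk <- function(n, realized, inside) {
    a1 <- if (inside) 7000L else 11000L
    a2 <- if (inside) 14000L else 16400L
    out <- make_repeat(rep(a1, n), rep(a1 + 11L, n),
                       rep(a2, n), rep(a2 + 11L, n))
    out$realized <- realized
    out$n_matched <- as.integer(realized)
    out
  }
  calls <- dplyr::bind_rows(mk(30, TRUE, TRUE), mk(10, TRUE, FALSE),
                            mk(10, FALSE, TRUE), mk(30, FALSE, FALSE))
  enr <- contact_zone_enrichment(calls)
  expect_equal(c(enr$realized_in, enr$realized_out,
                 enr$nonrealized_in, enr$nonrealized_out),
               c(30L, 10L, 10L, 30L))
  expect_equal(enr$odds_ratio_sample, 9)
  # swapping both row and column labels leaves the OR unchanged
  flipped <- calls
  flipped$realized <- !calls$realized
  enr_flip <- contact_zone_enrichment(
    flipped, zone5 = c(10000, 12000), zone3 = c(16000, 16569))
  expect_equal(enr_flip$odds_ratio_sample, enr$odds_ratio_sample)

  balanced <- dplyr::bind_rows(mk(5, TRUE, TRUE), mk(5, TRUE, FALSE),
                               mk(5, FALSE, TRUE), mk(5, FALSE, FALSE))
  enr2 <- contact_zone_enrichment(balanced)
  expect_equal(enr2$odds_ratio_sample, 1)
  expect_equal(enr2$p_value, 1)
})

test_that("Fisher p equals full hypergeometric enumeration (n <= 40)", {
  set.seed(74)
  for (rep in 1:30) {
    n <- sample(8:40, 1)
    a <- sample(0:min(n, 12), 1)
    b <- sample(0:(n - a), 1)
    cc <- sample(0:(n - a - b), 1)
    d <- n - a - b - cc
    got <- stats::fisher.test(matrix(c(a, cc, b, d), 2, 2))$p.value
    expect_equal(got, oracle_fisher_p(a, b, cc, d), tolerance = 1e-9,
                 info = paste(a, b, cc, d))
  }
})

test_that("zero-margin tables use the Haldane correction and flag it", {
  calls <- dplyr::bind_rows(
    { x <- make_repeat(rep(7000L, 5), rep(7011L, 5),
                       rep(14000L, 5), rep(14011L, 5))
      x$realized <- TRUE; x$n_matched <- 1L; x },
    { x <- make_repeat(rep(11000L, 5), rep(11011L, 5),
                       rep(16400L, 5), rep(16411L, 5))
      x$realized <- FALSE; x$n_matched <- 0L; x })
  enr <- contact_zone_enrichment(calls)
  expect_true(enr$haldane_corrected)
  expect_true(is.finite(enr$odds_ratio_sample))
})
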