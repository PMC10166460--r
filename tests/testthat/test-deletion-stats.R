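test_that("center summaries follow the midpoint definition", {
  d <- deletion_table(c(6000L, 7000L), c(14000L, 15000L))
  cs <- centers_summary(d)
  expect_equal(cs$median_center, 10500)
  expect_equal(centers_summary(deletion_table(6000L, 14000L))$sd_center, 0)
  expect_error(centers_summary(deletion_table(integer(0), integer(0))),
               "empty")
})

test_that("the randomization test is deterministic, order-invariant and
           bounded below by add-one smoothing", {
  d <- deletion_table(rep(8000L, 20), rep(14000L, 20))
  r <- randomize_centers_test(d, n_replicates = 200, seed = 7)
  expect_equal(r$observed_sd, 0)
  expect_equal(r$p_value, 1 / 201)       # minimum attainable p
  r2 <- randomize_centers_test(d, n_replicates = 200, seed = 7)
  expect_identical(r$replicate_sds, r2$replicate_sds)

  set.seed(8)
  d3 <- generate_uniform_deletions(50, length_distribution = c(3000:6000))
  ra <- randomize_centers_test(d3, n_replicates = 300, seed = 11)
  rb <- randomize_centers_test(d3[sample(nrow(d3)), ], n_replicates = 300,
                               seed = 11)
  expect_equal(ra$p_value, rb$p_value)
})

test_that("deletions longer than the arc are rejected", {
  d <- deletion_table(1L, 12000L)
  expect_error(randomize_centers_test(d, arc_region(5781, 16569)), "longer")
})

test_that("uniform placement centers a deletion at the arc midpoint", {
  # a deletion of any length L placed uniformly (d5 on [start, end - L])
  # has mean midpoint (start + end) / 2, up to the integer placement grid
  arc <- major_arc()
  d <- generate_uniform_deletions(10000, arc, length_distribution = 4000L,
                                  seed = 13)
  exp_mid <- (arc$start + arc$end) / 2
  se <- sd(d$center) / sqrt(nrow(d))
  expect_lt(abs(mean(d$center) - exp_mid), 3 * se + 1)
})

test_that("uniformly placed deletions give calibrated p-values", {
  set.seed(9)
  pvals <- vapply(1:60, function(k) {
    d <- generate_uniform_deletions(40, length_distribution = 4000L)
    randomize_centers_test(d, n_replicates = 99)$p_value
  }, numeric(1))
  # roughly uniform: no mass collapse at either end
  expect_gt(suppressWarnings(ks.test(pvals, "punif")$p.value), 0.01)
})

test_that("clustering separates blobs, labels noise, and is order-invariant", {
  set.seed(51)
  blob1 <- cbind(round(rnorm(50, 7000, 50)), round(rnorm(50, 13500, 50)))
  blob2 <- cbind(round(rnorm(50, 10000, 50)), round(rnorm(50, 15500, 50)))
  noise <- cbind(round(runif(5, 6000, 12000)), round(runif(5, 13000, 16000)))
  pts <- rbind(blob1, blob2, noise)
  d <- deletion_table(pts[, 1], pts[, 2])
  cl <- cluster_breakpoints(d, min_cluster_size = 20, min_samples = 10)
  labs <- cl$cluster
  expect_equal(length(setdiff(unique(labs), 0L)), 2L)
  # >= 90% of each blob co-clustered
  main1 <- names(which.max(table(labs[1:50])))
  main2 <- names(which.max(table(labs[51:100])))
  expect_true(main1 != "0" && main2 != "0" && main1 != main2)
  expect_gte(mean(labs[1:50] == as.integer(main1)), 0.9)
  expect_gte(mean(labs[51:100] == as.integer(main2)), 0.9)

  perm <- sample(nrow(d))
  cl2 <- cluster_breakpoints(d[perm, ], min_cluster_size = 20,
                             min_samples = 10)
  # same partition up to label names
  expect_equal(length(unique(paste(labs[perm], cl2$cluster))),
               length(unique(paste(labs[perm]))))
})

test_that("degenerate clustering inputs behave per contract", {
  d_same <- deletion_table(rep(8000L, 30), rep(14000L, 30))
  cl <- cluster_breakpoints(d_same, min_cluster_size = 10, min_samples = 5)
  expect_equal(unique(cl$cluster), 1L)

  d_small <- deletion_table(c(7000L, 8000L, 9000L),
                            c(14000L, 14500L, 15000L))
  expect_warning(cl3 <- cluster_breakpoints(d_small, min_cluster_size = 10,
                                            min_samples = 2),
                 "noise")
  expect_true(all(cl3$cluster == 0L))
})

test_that("per-cluster axis dispersion flags 5'-elongated clusters", {
  set.seed(52)
  c1 <- deletion_table(round(rnorm(200, 7000, 300)),
                       round(rnorm(200, 14000, 100)))
  c1$cluster <- 1L
  disp <- breakpoint_axis_dispersion(c1)
  expect_true(disp$wider_5prime)
  expect_gt(disp$sd_5prime, disp$sd_3prime)

  c2 <- deletion_table(round(rnorm(200, 7000, 150)),
                       round(rnorm(200, 14000, 150)))
  c2$cluster <- 1L
  disp2 <- breakpoint_axis_dispersion(c2)
  expect_lt(abs(disp2$sd_5prime / disp2$sd_3prime - 1), 0.3)

  c3 <- deletion_table(7000L, 14000L)
  c3$cluster <- 1L
  disp3 <- breakpoint_axis_dispersion(c3)
  expect_equal(c(disp3$sd_5prime, disp3$sd_3prime), c(0, 0))
})
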