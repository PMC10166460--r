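# shared synthetic genome/grid/matrix for the model tests
local_fixture <- local({
  g <- generate_genome(16569, 0.44, seed = 101)$seq
  grid <- build_grid()
  mm <- microhomology_matrix(g, grid)
  list(seq = g, grid = grid, mm = mm)
})

test_that("cell-table combinatorics match the grid and band width", {
  fx <- local_fixture
  empty <- deletion_table(integer(0), integer(0))
  cells <- build_cell_table(fx$grid, fx$mm, empty, band_width = 10)
  expect_equal(nrow(cells), 4005L)                 # 4950 - 945
  cells0 <- build_cell_table(fx$grid, fx$mm, empty, band_width = 0)
  expect_equal(nrow(cells0), 4950L)                # all unordered pairs
  expect_equal(mean(cells$ms_z), 0, tolerance = 1e-12)
  expect_equal(sd(cells$ms_z), 1, tolerance = 1e-12)
})

test_that("a deletion marks exactly its own cell", {
  fx <- local_fixture
  d <- deletion_table(7550L, 15150L)
  cells <- build_cell_table(fx$grid, fx$mm, d)
  expect_equal(sum(cells$y), 1L)
  hit <- cells[cells$y == 1, ]
  expect_equal(c(hit$i, hit$j), c(16L, 92L))
  # deletions outside the grid are dropped with a warning
  expect_warning(
    build_cell_table(fx$grid, fx$mm, deletion_table(5800L, 15000L)),
    "outside")
})

test_that("contact-zone coding uses window centers and inclusive bounds", {
  fx <- local_fixture
  cells <- code_contact_zone(
    build_cell_table(fx$grid, fx$mm, deletion_table(integer(0), integer(0))))
  expect_equal(cells$cz[cells$center_i == 7550.5 &
                        cells$center_j == 15150.5], 1L)
  expect_equal(cells$cz[cells$center_i == 10050.5 &
                        cells$center_j == 15150.5], 0L)
  all_in <- code_contact_zone(cells, zone5 = c(0, 20000),
                              zone3 = c(0, 20000))
  expect_true(all(all_in$cz == 1L))
})

test_that("logistic fits match the closed-form 2x2 logit", {
  x <- c(rep(1, 100), rep(0, 100))
  y <- c(rep(1, 30), rep(0, 70), rep(1, 10), rep(0, 90))
  f <- fit_logistic(data.frame(y = y, x = x), "y", "x")
  co <- tidy(f)
  expect_equal(co$estimate[co$term == "x"], log((30 / 70) / (10 / 90)),
               tolerance = 1e-6)
  expect_equal(co$estimate[co$term == "(Intercept)"], log(10 / 90),
               tolerance = 1e-6)
  # intercept-only model recovers logit of the mean
  f0 <- fit_logistic(data.frame(y = y), "y", character(0))
  expect_equal(tidy(f0)$estimate, qlogis(mean(y)), tolerance = 1e-8)
})

test_that("AIC equals 2k - 2 logLik and matches stats::glm", {
  set.seed(61)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  d$y <- rbinom(300, 1, plogis(-1 + 0.8 * d$x1 - 0.5 * d$x2))
  f <- fit_logistic(d, "y", c("x1", "x2"))
  ref <- stats::glm(y ~ x1 + x2, binomial(), d)
  expect_equal(tidy(f)$estimate, unname(coef(ref)), tolerance = 1e-6)
  expect_equal(tidy(f)$std.error,
               unname(summary(ref)$coefficients[, 2]), tolerance = 1e-4)
  g <- glance(f)
  expect_equal(g$AIC, 2 * 3 - 2 * g$logLik)
  expect_equal(g$AIC, AIC(ref), tolerance = 1e-6)
})

test_that("degenerate fits error informatively", {
  d <- data.frame(y = c(0, 1, 0, 1), x = c(1, 1, 1, 1))
  expect_error(fit_logistic(d, "y", "x"), "constant predictor")
  d2 <- data.frame(y = rep(1, 10), x = rnorm(10))
  expect_error(fit_logistic(d2, "y", "x"), "constant response")
  d3 <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                   x = c(rnorm(20, -5), rnorm(20, 5)))
  expect_error(suppressWarnings(fit_logistic(d3, "y", "x")), "separation")
})

test_that("coefficients of the generative model are recovered", {
  fx <- local_fixture
  gm <- generative_model(beta0 = -2.38, beta_ms = 0.33, beta_cz = 0.91,
                         seed = 202)
  sim <- generate_deletions(fx$grid, fx$mm, gm)
  cells <- code_contact_zone(build_cell_table(fx$grid, fx$mm,
                                              sim$deletions))
  f <- fit_ms_cz_model(cells)
  co <- tidy(f)
  est <- co$estimate
  se <- co$std.error
  truth <- c(-2.38, 0.33, 0.91)
  expect_true(all(abs(est - truth) < 3 * se))
})

test_that("the AIC scan finds a planted contact point", {
  fx <- local_fixture
  gm <- generative_model(beta0 = -2.3, beta_ms = 0.33,
                         contact_point = c(16L, 92L), beta_dist = -1,
                         seed = 303)
  sim <- generate_deletions(fx$grid, fx$mm, gm)
  cells <- build_cell_table(fx$grid, fx$mm, sim$deletions)
  sc <- contact_point_scan(cells)
  expect_lte(abs(sc$best$i - 16L), 2L)
  expect_lte(abs(sc$best$j - 92L), 2L)
  expect_equal(sum(!is.na(sc$aic_surface)), 4005L)
  # the surface argmin is consistent with the reported best cell
  expect_equal(min(sc$aic_surface, na.rm = TRUE), sc$best$aic)
  # scan AIC at the argmin equals an independent glm fit of the same model
  ci0 <- fx$grid$center[sc$best$i]; cj0 <- fx$grid$center[sc$best$j]
  d <- sqrt((cells$center_i - ci0)^2 + (cells$center_j - cj0)^2)
  ref <- stats::glm(cells$y ~ cells$ms_z + scale(d), binomial())
  expect_equal(sc$best$aic, AIC(ref), tolerance = 1e-4)
})

test_that("a constant response aborts the scan", {
  fx <- local_fixture
  cells <- build_cell_table(fx$grid, fx$mm,
                            deletion_table(integer(0), integer(0)))
  expect_error(contact_point_scan(cells), "constant")
})
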