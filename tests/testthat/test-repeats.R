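# the 13-bp motif of the longest perfect direct repeat in human mtDNA
COMMON_MOTIF <- "ACCTCCCTCACCA"

test_that("a planted perfect 13-bp repeat is recovered exactly", {
  set.seed(11)
  bg <- random_dna(400)
  s <- plant_into(plant_into(bg, COMMON_MOTIF, 51), COMMON_MOTIF, 301)
  # guard characters block extension beyond the planted arms
  s <- set_char(s, c(50, 64, 300, 314), c("G", "G", "T", "T"))
  s <- circular_seq(s)
  r <- find_perfect_direct(s)
  hit <- r[r$motif == COMMON_MOTIF, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$arm1_start, hit$arm1_end), c(51L, 63L))
  expect_equal(c(hit$arm2_start, hit$arm2_end), c(301L, 313L))
  expect_equal(hit$length, 13L)
  expect_equal(hit$identity, 1)
})

test_that("degraded detection respects the identity threshold", {
  set.seed(12)
  bg <- random_dna(300)
  # non-matching margins so windows cannot creep past the planted arms
  bg <- set_char(bg, c(35:40, 53:58), rep("A", 12))
  bg <- set_char(bg, c(195:200, 213:218), rep("C", 12))
  motif <- "ACGTTGCAGGTC"                      # 12-mer
  mm2 <- "ACGATGCAGGTG"                        # 2 mismatches: 10/12 = 0.83
  mm3 <- "ACGATGAAGGTG"                        # 3 mismatches: 9/12 = 0.75
  s2 <- circular_seq(plant_into(plant_into(bg, motif, 41), mm2, 201))
  s3 <- circular_seq(plant_into(plant_into(bg, motif, 41), mm3, 201))
  hit2 <- find_degraded(s2, kind = "direct", min_length = 12)
  expect_true(any(hit2$arm1_start == 41 & hit2$arm2_start == 201 &
                  hit2$length == 12))
  hit3 <- find_degraded(s3, kind = "direct", min_length = 12)
  expect_false(any(hit3$arm1_start == 41 & hit3$arm2_start == 201 &
                   hit3$length == 12))
})

test_that("inverted repeats are found via the reverse complement", {
  set.seed(13)
  bg <- random_dna(300)
  motif <- "ACGTTGCAGGTCAT"
  s <- plant_into(plant_into(bg, motif, 31), reverse_complement(motif), 201)
  # block symmetric extension: s[30] vs comp(s[215]), s[45] vs comp(s[200])
  s <- set_char(s, c(30, 215, 45, 200), c("A", "A", "A", "A"))
  s <- circular_seq(s)
  r <- find_degraded(s, kind = "inverted", min_length = 14)
  # a maximal degraded pair may extend past the perfect core; require a
  # reported pair whose arms contain the planted arms
  expect_true(any(r$arm1_start <= 31 & r$arm1_end >= 44 &
                  r$arm2_start <= 201 & r$arm2_end >= 214))
  expect_true(all(r$kind == "inverted"))
})

test_that("parameter validation errors fire", {
  s <- circular_seq(random_dna(50))
  expect_error(find_perfect_direct(s, min_length = 3), "seed infeasible")
  expect_error(find_degraded(s, min_identity = 0.4), "0.5")
  expect_error(find_degraded(s, min_identity = 1.2), "0.5")
})

test_that("scanner equals the brute-force oracle on random fixtures", {
  set.seed(14)
  for (rep in 1:6) {
    n <- sample(80:160, 1)
    s <- random_dna(n)
    # plant something so non-trivial hits exist
    motif <- random_dna(12)
    s <- plant_into(s, motif, 5)
    s <- plant_into(s, motif, n - 20)
    for (kind in c("direct", "inverted")) {
      got <- find_repeats(circular_seq(s), kind = kind, min_length = 8,
                          min_identity = 0.8, max_arm = 30)
      want <- oracle_repeats(s, kind, min_len = 8, min_id = 0.8,
                             max_arm = 30)
      got_df <- data.frame(arm1_start = got$arm1_start,
                           arm2_start = got$arm2_start,
                           length = got$length)
      got_df <- got_df[order(got_df$arm1_start, got_df$arm2_start,
                             got_df$length), ]
      rownames(got_df) <- rownames(want) <- NULL
      expect_equal(got_df, want, info = paste(kind, "rep", rep))
    }
  }
})

test_that("degraded detection at identity 1 reproduces the perfect scan", {
  set.seed(15)
  s <- circular_seq(plant_into(plant_into(random_dna(250), "GATTACAGATT", 11),
                               "GATTACAGATT", 171))
  a <- find_perfect_direct(s, min_length = 10)
  b <- find_degraded(s, kind = "direct", min_length = 10, min_identity = 1)
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("inverted detection is strand-symmetric", {
  set.seed(16)
  motif <- random_dna(15)
  s <- plant_into(plant_into(random_dna(220), motif, 21),
                  reverse_complement(motif), 151)
  r1 <- find_degraded(circular_seq(s), kind = "inverted", min_length = 15)
  r2 <- find_degraded(circular_seq(reverse_complement(s)),
                      kind = "inverted", min_length = 15)
  L <- nchar(s)
  # mirror: arm1 of the reverse-complement scan maps to L - arm2_end + 1
  m1 <- sort(L - r1$arm2_end + 1)
  m2 <- sort(r2$arm1_start)
  expect_equal(m1, m2)
})

test_that("repeat density matrices count arm nucleotides per cell", {
  g <- build_grid()
  # arms fully inside windows 3 ([6201,6300]) and 70 ([12901,13000])
  reps <- tibble::tibble(kind = "direct",
                         arm1_start = 6220L, arm1_end = 6231L,
                         arm2_start = 12920L, arm2_end = 12931L,
                         length = 12L, identity = 1, motif = "x")
  m <- repeat_density_matrix(reps, g)
  expect_equal(m[3, 70], 24L)
  expect_equal(m[70, 3], 24L)
  expect_equal(sum(m), 48L)

  # empty set
  expect_true(all(repeat_density_matrix(reps[0, ], g) == 0))

  # arm straddling the window 3 / window 4 boundary at 6300|6301
  reps2 <- tibble::tibble(kind = "direct",
                          arm1_start = 6295L, arm1_end = 6306L,
                          arm2_start = 12920L, arm2_end = 12931L,
                          length = 12L, identity = 1, motif = "x")
  m2 <- repeat_density_matrix(reps2, g)
  expect_equal(m2[3, 70], 6L + 12L)    # 6 arm1 nt in window 3 + arm2
  expect_equal(m2[4, 70], 6L + 12L)    # other 6 arm1 nt in window 4 + arm2
})
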