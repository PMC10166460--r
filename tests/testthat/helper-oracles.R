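# Independent oracles used to verify the package's primitives.
# Each oracle is a deliberately naive second implementation: full-matrix
# dynamic programs, exhaustive enumerations, closed forms.

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

comp_vec <- function(x) chartr("ACGT", "TGCA", x)

# --- exhaustive affine-gap global alignment (end gaps penalized) ---------
# Three-state Gotoh with full matrices, written against the same scoring
# contract: gap of length L costs open + ext * L.
oracle_nw_global <- function(a, b, match = 5, mismatch = -4,
                             open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, Y[i - 1, j] - open - ext,
                     X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Free end gaps on both sequences at both ends: optimum equals the best
# single aligned segment, found here by trying every anchored start.
oracle_nw_free <- function(a, b, match = 5, mismatch = -4,
                           open = 10, ext = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -Inf
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1], 0) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, Y[i - 1, j] - open - ext,
                     X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, X[i, j - 1] - open - ext,
                     Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- brute-force maximal ungapped repeat scan ----------------------------
# Enumerates, for every (anti)diagonal, every (start, length) window via
# cumulative match counts and applies the validity + single-step
# inextensibility contract directly. Same contract as the package scanner,
# organised and computed independently (R vectors, floating-point identity
# test with a tolerance instead of scaled integers).
oracle_repeats <- function(s, kind = "direct", min_len = 10L,
                           min_id = 0.8, max_arm = 100L) {
  sv <- strsplit(s, "")[[1]]
  L <- length(sv)
  ok_pos <- sv != "N"
  res <- list()
  emit <- function(a1, a2, len) {
    res[[length(res) + 1]] <<- data.frame(arm1_start = a1, arm2_start = a2,
                                          length = len)
  }
  scan_diag <- function(m, cap, report) {
    # m: logical match vector along the diagonal; cap: max admissible
    # window length; report(a, len) called for each maximal valid window
    T <- length(m)
    if (T < min_len) return(invisible())
    Mc <- c(0, cumsum(m))
    ok <- function(a, len) {
      # vectorized over a
      a >= 1 & a + len - 1 <= T & len <= cap &
        Mc[pmax(pmin(a + len, T + 1), 1)] - Mc[pmax(a, 1)] >=
          min_id * len - 1e-9
    }
    len_hi <- min(cap, max_arm, T)
    if (len_hi < min_len) return(invisible())
    for (len in min_len:len_hi) {
      a <- seq_len(T - len + 1L)
      v <- ok(a, len)
      if (!any(v)) next
      lext <- ok(a - 1L, len + 1L) & (len + 1) <= min(cap, max_arm)
      rext <- ok(a, len + 1L) & (len + 1) <= min(cap, max_arm)
      keep <- v & !lext & !rext
      for (aa in a[keep]) report(aa, len)
    }
  }
  if (kind == "direct") {
    for (d in seq_len(L - 1L)) {
      T <- L - d
      if (T < min_len) next
      i <- seq_len(T)
      m <- sv[i] == sv[i + d] & ok_pos[i] & ok_pos[i + d]
      scan_diag(m, cap = d, report = function(a, len) emit(a, a + d, len))
    }
  } else {
    for (cc in 2:(2L * L)) {
      i0 <- max(1L, cc - L)
      i1 <- (cc - 1L) %/% 2L
      if (i1 - i0 + 1L < min_len) next
      i <- i0:i1
      m <- sv[i] == comp_vec(sv[cc - i]) & ok_pos[i] & ok_pos[cc - i]
      scan_diag(m, cap = length(i),
                report = function(a, len) {
                  a1 <- i0 + a - 1L
                  b1 <- a1 + len - 1L
                  emit(a1, cc - b1, len)
                })
    }
  }
  if (length(res) == 0) {
    return(data.frame(arm1_start = integer(), arm2_start = integer(),
                      length = integer()))
  }
  out <- unique(do.call(rbind, res))
  out[order(out$arm1_start, out$arm2_start, out$length), , drop = FALSE]
}

# --- exhaustive duplex enumeration ---------------------------------------
# Recursively explores every monotone pairing chain of a against the
# reverse complement of b, scoring stacks, affine loops, initiation and
# terminal A:T penalties.
oracle_duplex <- function(a, b, params) {
  av <- strsplit(a, "")[[1]]
  bR <- rev(strsplit(comp_vec(b), "")[[1]])
  n <- length(av); m <- length(bR)
  stack <- params$stack
  term <- function(x) if (x %in% c("A", "T")) params$terminal_at else 0
  suffix_best <- function(i, j) {
    # min energy from pair (i, j) onward, including the final terminal
    best <- term(av[i])                    # end the duplex here
    if (i < n && j < m) {
      for (i2 in (i + 1):n) for (j2 in (j + 1):m) {
        if (av[i2] != bR[j2] || av[i2] == "N") next
        trans <- if (i2 == i + 1 && j2 == j + 1) {
          stack[av[i], av[i2]]
        } else {
          params$loop_open +
            params$loop_extend * ((i2 - i - 1) + (j2 - j - 1))
        }
        best <- min(best, trans + suffix_best(i2, j2))
      }
    }
    best
  }
  best <- Inf
  for (i in 1:n) for (j in 1:m) {
    if (av[i] != bR[j] || av[i] == "N") next
    best <- min(best, params$initiation + term(av[i]) + suffix_best(i, j))
  }
  if (!is.finite(best) || best >= 0) 0 else best
}

# --- Fisher exact p by full hypergeometric enumeration -------------------
oracle_fisher_p <- function(a, b, cc, d) {
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  pk <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  p_obs <- pk[ks == a]
  sum(pk[pk <= p_obs * (1 + 1e-7)])
}

# --- misc ---------------------------------------------------------------
set_char <- function(s, pos, ch) {
  for (k in seq_along(pos)) substr(s, pos[k], pos[k]) <- ch[k]
  s
}

plant_into <- function(background, motif, at) {
  # overwrite background string with motif starting at position `at`
  paste0(substr(background, 1, at - 1), motif,
         substr(background, at + nchar(motif), nchar(background)))
}

write_tsv_tmp <- function(df) {
  f <- tempfile(fileext = ".tsv")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}
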