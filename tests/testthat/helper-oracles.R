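# Independent oracles used across the suite. Each is a brute-force or
# closed-form computation kept deliberately separate from the package's
# own code paths.

# Gotoh local alignment score with affine gaps, Biostrings penalty
# convention: a gap of length L costs gap_open + L * gap_extend.
oracle_local_score <- function(a, b, match = 1, mismatch = -2,
                               gap_open = 5, gap_extend = 2,
                               submat = NULL) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  sub <- function(x, y) {
    if (is.null(submat)) if (x == y) match else mismatch
    else submat[x, y]
  }
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  Ix <- matrix(NEG, n + 1L, m + 1L)
  Iy <- matrix(NEG, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      Ix[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open - gap_extend,
                                Ix[i, j + 1L] - gap_extend)
      Iy[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open - gap_extend,
                                Iy[i + 1L, j] - gap_extend)
      M[i + 1L, j + 1L] <- max(0, M[i, j], Ix[i, j], Iy[i, j]) +
        sub(av[i], bv[j])
      best <- max(best, M[i + 1L, j + 1L])
    }
  }
  best
}

# Exact binomial tail by enumeration of all 2^u equally likely outcomes.
oracle_binom_tail <- function(u, n) {
  x <- 0:(2^u - 1)
  pc <- integer(length(x))
  for (b in 0:(u - 1)) pc <- pc + bitwAnd(bitwShiftR(x, b), 1L)
  mean(pc >= n)
}

# KS D by direct ECDF comparison over the pooled support.
oracle_ks_D <- function(x, y) {
  t <- sort(unique(c(x, y)))
  max(abs(vapply(t, function(v) mean(x <= v) - mean(y <= v), 0)))
}

# Hodges-Lehmann by explicit double loop.
oracle_hl <- function(x, y) {
  d <- numeric(0)
  for (xi in x) for (yj in y) d <- c(d, xi - yj)
  median(d)
}

# Ansari-Bradley statistic from first principles: mid-ranks on the
# pooled sample, scores min(rank, N + 1 - rank), summed over x.
oracle_ab_stat <- function(x, y) {
  r <- rank(c(x, y))
  N <- length(r)
  sc <- pmin(r, N + 1 - r)
  sum(sc[seq_along(x)])
}

# Fligner-Policello permutation p-value: re-split the pooled sample.
oracle_fp_perm_p <- function(x, y, z_obs, B = 5000L, seed = 42L) {
  pool <- c(x, y)
  nx <- length(x)
  zs <- numeric(B)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  for (b in seq_len(B)) {
    idx <- sample.int(length(pool), nx)
    zs[b] <- fligner_policello(pool[idx], pool[-idx])$z
  }
  mean(abs(zs) >= abs(z_obs))
}

# Sample skewness, for transform-selection checks.
oracle_skew <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}
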