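test_that("signed distances follow the genome-forward sign convention", {
  expect_equal(signed_distance(2e6, 1.5e6, TRUE), 5e5)   # anchor downstream
  expect_equal(signed_distance(1e6, 1.8e6, TRUE), -8e5)  # anchor upstream
  expect_true(is.na(signed_distance(1e6, 2e6, FALSE)))   # trans excluded
})

test_that("build_signed_distances filters methods case-insensitively", {
  rows <- data.frame(
    chrom_a = "chr1", start_a = c(100L, 200L, 300L),
    end_a = c(150L, 250L, 350L),
    chrom_b = c("chr1", "chr1", "chr2"),
    start_b = c(50L, 500L, 10L), end_b = c(60L, 510L, 20L),
    gene_a = "G1", gene_b = "X", method = c("HI-C", "ChIA-PET", "Hi-C"),
    stringsAsFactors = FALSE
  )
  genes <- data.frame(gene = "G1", chrom = "chr1", start = 1000L,
                      group = "up_unchanged", stringsAsFactors = FALSE)
  d <- build_signed_distances(rows, genes)
  # ChIA-PET dropped by the method filter; trans row dropped by distance
  expect_equal(nrow(d), 1L)
  expect_equal(d$distance, 950)
  expect_equal(d$side, "downstream")
})

test_that("distance transformations are sign-preserving and monotone", {
  expect_equal(transform_distances(-8, "signed_cbrt"), -2)
  expect_equal(transform_distances(0, "signed_log10"), 0)
  expect_error(transform_distances(1, "sqrt"), "arg")
  set.seed(41)
  for (m in c("identity", "signed_log10", "signed_cbrt")) {
    x <- rnorm(50, sd = 1e5)
    y <- transform_distances(x, m)
    expect_equal(order(y), order(x))
    expect_equal(sign(y), sign(x))
  }
})

test_that("select_transform symmetrises skewed data", {
  set.seed(42)
  x <- rnorm(500)
  expect_equal(select_transform(x), "identity")
  expect_equal(select_transform(x^3), "signed_cbrt")
  expect_equal(select_transform(rep(1, 30)), "identity")
  expect_error(select_transform(1:5), ">= 20")
})

test_that("kernel density estimates integrate to one and match closed forms", {
  set.seed(43)
  x <- rnorm(10000)
  k <- kde(x)
  area <- sum(diff(k$grid) * (head(k$density, -1) + k$density[-1]) / 2)
  expect_lt(abs(area - 1), 1e-3)
  # true N(0,1) density at 0 is 1/sqrt(2*pi) = 0.399
  at0 <- k$density[which.min(abs(k$grid))]
  expect_gte(at0, 0.35); expect_lte(at0, 0.45)

  # planted bimodal mixture shows two local maxima
  xb <- c(rnorm(4000, -4, 0.5), rnorm(4000, 4, 0.5))
  kb <- kde(xb)
  d <- kb$density
  n_max <- sum(d[2:511] > d[1:510] & d[2:511] > d[3:512] &
                 d[2:511] > max(d) / 10)
  expect_equal(n_max, 2L)

  expect_error(kde(rep(1, 5)), "distinct")
})

test_that("two-sample KS statistic matches the exhaustive ECDF oracle", {
  expect_equal(ks_2sample(1:5, 1:5), list(D = 0, p = 1))
  set.seed(44)
  for (i in 1:20) {
    x <- sample(1:10, sample(2:8, 1), TRUE)
    y <- sample(1:10, sample(2:8, 1), TRUE)
    expect_equal(ks_2sample(x, y)$D, oracle_ks_D(x, y))
  }
  expect_error(ks_2sample(numeric(0), 1:3), ">= 2")
})

test_that("Hodges-Lehmann shift equals the all-pairs oracle", {
  expect_equal(hodges_lehmann(1:6 + 7, 1:6), 7)
  expect_equal(hodges_lehmann(c(1, 2), c(1, 2)), 0)
  set.seed(45)
  for (i in 1:10) {
    x <- rnorm(sample(3:12, 1)); y <- rnorm(sample(3:12, 1))
    expect_equal(hodges_lehmann(x, y), oracle_hl(x, y))
  }
})

test_that("Fligner-Policello test is antisymmetric and calibrated", {
  x <- c(1, 3, 5, 7, 9)
  expect_equal(fligner_policello(x, x), list(z = 0, p = 1))
  set.seed(46)
  for (i in 1:5) {
    a <- rnorm(10); b <- rnorm(12, sd = 2)
    f1 <- fligner_policello(a, b)
    f2 <- fligner_policello(b, a)
    expect_equal(f1$z, -f2$z)
    expect_equal(f1$p, f2$p)
  }
  expect_error(fligner_policello(1:2, 1:5), ">= 3")
})

test_that("Fligner-Policello p is close to a permutation oracle", {
  set.seed(47)
  x <- rnorm(15)
  y <- rnorm(15, mean = 1)
  f <- fligner_policello(x, y)
  p_perm <- oracle_fp_perm_p(x, y, f$z, B = 5000L)
  expect_lt(abs(f$p - p_perm), 0.02)
})

test_that("Ansari-Bradley detects scale differences and matches the score oracle", {
  set.seed(48)
  nonrej <- vapply(1:10, function(s) {
    set.seed(s)
    a <- rnorm(60); b <- rnorm(60)
    ansari_bradley(a, b)$p > 0.05
  }, TRUE)
  expect_gte(sum(nonrej), 9L)

  set.seed(49)
  a <- rnorm(100)
  b <- 5 * rnorm(100)
  expect_lt(ansari_bradley(a, b)$p, 0.01)

  for (i in 1:10) {
    x <- sample(1:8, sample(3:6, 1), TRUE)
    y <- sample(1:8, sample(3:6, 1), TRUE)
    expect_equal(unname(ansari_bradley(x, y)$stat), oracle_ab_stat(x, y))
  }
})

test_that("DSCF pairwise p-values are adjusted and detect a shifted group", {
  g <- list(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5),
            c = c(1, 2, 3, 4, 5))
  p <- dscf_pairwise(g)
  expect_true(isSymmetric(p))
  expect_true(all(p[upper.tri(p)] >= 0.9))

  set.seed(50)
  g2 <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30, mean = 3))
  p2 <- dscf_pairwise(g2)
  expect_lt(p2["a", "c"], 0.01)
  expect_lt(p2["b", "c"], 0.01)
  expect_gt(p2["a", "b"], 0.05)

  # adjusted p never falls below the unadjusted normal-approximation
  # Wilcoxon p for the same standardised statistic
  for (i in 1:5) {
    gs <- list(rnorm(10), rnorm(12), rnorm(8, 1))
    padj <- dscf_pairwise(gs)
    for (a in 1:2) for (b in (a + 1):3) {
      x <- gs[[a]]; y <- gs[[b]]
      r <- rank(c(x, y)); N <- length(r)
      W <- sum(r[seq_along(x)])
      ties <- table(c(x, y))
      v <- length(x) * length(y) / 12 *
        ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      z <- (W - length(x) * (N + 1) / 2) / sqrt(v)
      expect_gte(padj[a, b], 2 * pnorm(-abs(z)) - 1e-12)
    }
  }
  expect_error(dscf_pairwise(g[1:2]), ">= 3")
})

test_that("the battery respects the side/sign symmetry", {
  gg <- data.frame(gene = sprintf("G%02d", 1:12),
                   group = rep(c("up_unchanged", "down_unchanged"), 6))
  cfg <- sim_config(seed = 51, n_interactions_per_gene = 60L)
  sim <- generate_interactions(cfg, gg, upstream_bias = 0.5)
  d <- build_signed_distances(sim$interactions, sim$genes)
  bat <- suppressWarnings(run_battery(d))

  flipped <- d
  flipped$distance <- -d$distance
  flipped$side <- ifelse(flipped$distance > 0, "downstream", "upstream")
  bat_f <- suppressWarnings(run_battery(flipped))
  expect_equal(bat$downstream$strata$overall$ks_D,
               bat_f$upstream$strata$overall$ks_D)
  expect_equal(bat$upstream$strata$overall$ks_D,
               bat_f$downstream$strata$overall$ks_D)

  # one-sided input yields a one-sided battery without crashing
  dn <- d[d$side == "downstream", ]
  bat_dn <- suppressWarnings(run_battery(dn))
  expect_null(bat_dn$upstream)
  expect_false(is.null(bat_dn$downstream))
})

test_that("planted upstream-bias ordering is recovered from median signs", {
  gg <- data.frame(gene = sprintf("G%02d", 1:20),
                   group = rep(c("up_unchanged", "down_unchanged"), 10))
  cfg <- sim_config(seed = 52, n_interactions_per_gene = 50L)
  bias <- c(up_unchanged = 0.7, down_unchanged = 0.3)
  sim <- generate_interactions(cfg, gg, upstream_bias = bias)
  d <- build_signed_distances(sim$interactions, sim$genes)
  med <- tapply(d$distance, d$group, median)
  # 70% upstream -> negative median; 30% upstream -> positive median
  expect_lt(med[["up_unchanged"]], 0)
  expect_gt(med[["down_unchanged"]], 0)
  # and the distributions differ sharply
  expect_lt(ks_2sample(d$distance[d$group == "up_unchanged"],
                       d$distance[d$group == "down_unchanged"])$p, 0.01)
})
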