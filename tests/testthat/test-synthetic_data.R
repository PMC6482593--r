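test_that("sim_config validates its fields", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(frac_up = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(rc_len = 3000, intron_len = 2000), "rc_len")
  expect_error(sim_config(circ_seq_len = 100), "circ_seq_len")
  expect_error(sim_config(frac_up = 0.7, frac_down = 0.7), "frac_up")
})

test_that("generators are pure functions of the config", {
  cfg <- sim_config(seed = 9, n_shared = 40L, n_condition_specific = 10L,
                    n_sequences = 6L)
  expect_identical(generate_circ_tables(cfg), generate_circ_tables(cfg))
  g <- c("G1", "G2")
  expect_identical(generate_mrna_table(cfg, g), generate_mrna_table(cfg, g))
  expect_identical(generate_intron_pairs(cfg, 4), generate_intron_pairs(cfg, 4))
  gg <- data.frame(gene = g, group = c("up_unchanged", "down_unchanged"))
  expect_identical(generate_interactions(cfg, gg),
                   generate_interactions(cfg, gg))
  expect_identical(generate_circ_sequences(cfg), generate_circ_sequences(cfg))
  # serialized tables are byte-identical too
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_circexplorer2(generate_circ_tables(cfg)$control, f1, "control")
  write_circexplorer2(generate_circ_tables(cfg)$control, f2, "control")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("planted expression effects obey the configured fractions", {
  cfg0 <- sim_config(seed = 2, n_shared = 200L, n_condition_specific = 0L,
                     frac_up = 0, frac_down = 0)
  tr0 <- generate_circ_tables(cfg0)$truth
  expect_true(all(tr0$class == "null"))
  expect_true(all(tr0$true_log2_effect == 0))

  cfg <- sim_config(seed = 2, n_shared = 200L, n_condition_specific = 0L,
                    frac_up = 0.1, frac_down = 0.05, effect_log2 = 2)
  tr <- generate_circ_tables(cfg)$truth
  expect_equal(sum(tr$class == "up"), 20L)
  expect_equal(sum(tr$class == "down"), 10L)
  expect_true(all(tr$true_log2_effect[tr$class == "up"] == 2))
})

test_that("planted-up log ratios separate from the null distribution", {
  # Monte-Carlo calibration of the generator's signal-to-noise: the
  # fraction of planted-up circRNAs whose empirical log2 ratio exceeds
  # the null 97.5th percentile, averaged over ten seeds, is >= 0.8.
  frac <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_shared = 1000L,
                      n_condition_specific = 0L,
                      frac_up = 0.05, frac_down = 0, effect_log2 = 3)
    sim <- generate_circ_tables(cfg)
    m <- merge_conditions(sim$control, sim$treated)
    lr <- compute_ratio(m$reads_treated, m$reads_control)$log2_ratio
    tr <- sim$truth[match(m$circ_key, sim$truth$circ_key), ]
    q <- quantile(lr[tr$class == "null"], 0.975)
    mean(lr[tr$class == "up"] > q)
  }, 0)
  expect_gte(mean(frac), 0.8)
})

test_that("housekeeping fold changes follow the configured noise", {
  cfg0 <- sim_config(seed = 6, hk_sd = 0)
  mr0 <- generate_mrna_table(cfg0, c("X1", "X2"))
  hk0 <- mr0$table$fold_change[mr0$truth$class == "housekeeping"]
  expect_equal(hk0, rep(1, 10))

  # planted mRNA classes are recovered by the housekeeping interval
  rec <- vapply(1:5, function(s) {
    cfg <- sim_config(seed = s, hk_sd = 0.02, mrna_effect = 0.3)
    mr <- generate_mrna_table(cfg, sprintf("G%03d", 1:300))
    hk <- mr$table[mr$table$gene %in% housekeeping_genes(), ]
    ci <- fit_ci(hk$fold_change)
    cls <- classify_mrna(mr$table$fold_change, ci)
    planted <- mr$truth$class %in% c("increased", "decreased")
    mean(cls[planted] == mr$truth$class[planted])
  }, 0)
  expect_gte(mean(rec), 0.95)
})

test_that("planted reverse-complement intron segments behave as constructed", {
  cfg <- sim_config(seed = 8, frac_rc_introns = 1, rc_identity = 1,
                    rc_len = 300L)
  ip <- generate_intron_pairs(cfg, n_pairs = 2L)
  for (i in 1:2) {
    r <- align_rc(ip$pairs$intron5[i], ip$pairs$intron3[i])
    expect_equal(r$pident, 100)
    expect_gte(r$aln_len, 300L)
    expect_true(r$significant)
  }

  # without planting, random 2 kb introns never reach E < 1e-20
  for (s in 1:2) {
    cfg0 <- sim_config(seed = s, frac_rc_introns = 0)
    ip0 <- generate_intron_pairs(cfg0, n_pairs = 50L)
    sc <- score_all(ip0$pairs)
    expect_equal(sum(sc$significant), 0L)
  }
})

test_that("interaction distances follow the upstream bias and scale", {
  gg <- data.frame(gene = sprintf("G%02d", 1:10),
                   group = rep("up_unchanged", 10))
  cfg1 <- sim_config(seed = 3, n_interactions_per_gene = 20L)
  all_up <- generate_interactions(cfg1, gg, upstream_bias = 1)
  d <- build_signed_distances(all_up$interactions, all_up$genes)
  expect_true(all(d$distance < 0))
  expect_true(all(d$side == "upstream"))

  # unbiased generation is consistent with a fair coin
  cfg2 <- sim_config(seed = 4, n_interactions_per_gene = 200L)
  unb <- generate_interactions(cfg2, gg, upstream_bias = 0.5)
  du <- build_signed_distances(unb$interactions, unb$genes)
  bt <- binom.test(sum(du$distance < 0), nrow(du), p = 0.5)
  expect_gt(bt$p.value, 0.01)

  # a tenfold scale change is detected by the KS test at n = 500
  cfg_a <- sim_config(seed = 5, n_interactions_per_gene = 50L,
                      dist_scale = 1e5)
  cfg_b <- sim_config(seed = 6, n_interactions_per_gene = 50L,
                      dist_scale = 1e6)
  da <- build_signed_distances(generate_interactions(cfg_a, gg)$interactions,
                               generate_interactions(cfg_a, gg)$genes)
  db <- build_signed_distances(generate_interactions(cfg_b, gg)$interactions,
                               generate_interactions(cfg_b, gg)$genes)
  expect_equal(nrow(da), 500L)
  ks <- ks_2sample(abs(da$distance), abs(db$distance))
  expect_lt(ks$p, 0.001)
})

test_that("planted circular ORFs and Kozak motifs are found as constructed", {
  cfg <- sim_config(seed = 7, n_sequences = 10L, orf_plant_rate = 1,
                    kozak_plant_rate = 0)
  sq <- generate_circ_sequences(cfg)
  for (s in sq$seqs) {
    orfs <- find_circular_orfs(s, min_aa = 20L)
    expect_gte(sum(orfs$crosses_junction), 1L)
  }

  # with nothing planted, the 10-nt Kozak consensus is analytically rare
  # on random sequences: ~77 * 400 * 2 * (1/4)^10 = 0.06 expected hits
  # per 77-sequence set, so hits across ten sets stay near zero
  hits <- vapply(1:10, function(s) {
    cfg0 <- sim_config(seed = s, n_sequences = 77L, kozak_plant_rate = 0,
                       orf_plant_rate = 0)
    sum(lengths(lapply(generate_circ_sequences(cfg0)$seqs, kozak_scan)))
  }, 0)
  expect_gte(sum(hits == 0), 7L)
  expect_lte(sum(hits), 3)
})
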