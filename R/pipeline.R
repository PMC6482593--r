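# End-to-end orchestration over synthetic inputs, plus the spliceosome
# overlap helper and the summary report.

#' Spliceosome components outside the housekeeping interval
#'
#' Splits a gene list by whether its mRNA fold change falls below or
#' above the housekeeping confidence interval (strict inequalities, as
#' everywhere in the workflow).
#'
#' @param mrna_fc Data frame with `gene` and `fold_change`.
#' @param spliceosome_genes Character vector of spliceosome gene symbols.
#' @param ci An [expression_ci()] (housekeeping interval).
#' @return A list with `down` and `up` character vectors.
#' @export
spliceosome_overlap <- function(mrna_fc, spliceosome_genes, ci) {
  stopifnot(inherits(ci, "expression_ci"))
  sub <- mrna_fc[mrna_fc$gene %in% spliceosome_genes, , drop = FALSE]
  list(
    down = sub$gene[sub$fold_change < ci$lower],
    up = sub$gene[sub$fold_change > ci$upper]
  )
}

#' @noRd
.pct <- function(count, total) {
  if (total == 0L) return(NA_real_)
  round(100 * count / total, 1L)
}

#' Run the full synthetic-data pipeline
#'
#' Generates every input from `cfg`, then runs the stages in order:
#' merge of the two conditions, ratio computation, CI fitting (or
#' overrides), six-group classification, direction-bias tests,
#' exon-count tests, flanking-intron homology scoring, the chromatin
#' interaction battery, and circular ORF / Kozak / IRES
#' characterisation. Fully deterministic given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param circ_ci,mrna_ci Optional [expression_ci()] overrides; fitted
#'   from the data when `NULL`.
#' @param out_dir Optional directory; when given, stage tables are
#'   written as tab-separated files and the report as JSON.
#' @return A list of class `circ_report`; see Details. Stage tables are
#'   attached under `$tables`.
#' @export
run_pipeline <- function(cfg = sim_config(), circ_ci = NULL,
                         mrna_ci = NULL, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))

  sim <- generate_circ_tables(cfg)
  merged <- merge_conditions(sim$control, sim$treated)
  rr <- compute_ratio(merged$reads_treated, merged$reads_control)
  merged$ratio <- rr$ratio
  merged$log2_ratio <- rr$log2_ratio

  mrna <- generate_mrna_table(cfg, merged$gene_symbol)
  merged$mrna_fc <- mrna$table$fold_change[
    match(merged$gene_symbol, mrna$table$gene)]

  if (is.null(circ_ci)) circ_ci <- fit_ci(merged$log2_ratio)
  if (is.null(mrna_ci)) {
    hk <- mrna$table[mrna$table$gene %in% housekeeping_genes(), ]
    mrna_ci <- fit_ci(hk$fold_change)
  }
  merged <- assign_six_groups(merged, circ_ci, mrna_ci)
  counts <- group_counts(merged)
  n_sig <- sum(counts)
  n_up <- sum(counts[c("up_increased", "up_unchanged", "up_decreased")])
  n_down <- n_sig - n_up

  bias_overall <- if (n_sig > 0L) {
    direction_bias_p(n_sig, max(n_up, n_down))
  } else NA_real_
  n_up_mrna_up <- counts[["up_increased"]]
  n_up_mrna_down <- counts[["up_decreased"]]
  u2 <- n_up_mrna_up + n_up_mrna_down
  bias_up_mrna <- if (u2 > 0L) {
    direction_bias_p(u2, max(n_up_mrna_up, n_up_mrna_down))
  } else NA_real_

  sig <- merged[!is.na(merged$group), , drop = FALSE]
  exon_tests <- if (nrow(sig) > 0L &&
                    nlevels(droplevels(sig$group)) >= 2L &&
                    length(unique(sig$exon_count)) > 1L) {
    compare_exon_counts(sig$exon_count, sig$group)
  } else list(anova_p = NA_real_, kw_p = NA_real_)

  introns <- generate_intron_pairs(cfg, n_pairs = max(nrow(sig), 2L))
  hom <- score_all(introns$pairs)
  n_hom_sig <- sum(hom$significant)
  hom$group <- if (nrow(sig) >= nrow(hom)) {
    as.character(sig$group[seq_len(nrow(hom))])
  } else {
    rep(as.character(sig$group), length.out = nrow(hom))
  }
  bit_tests <- if (length(unique(hom$group)) >= 2L &&
                   length(unique(hom$bitscore)) > 1L) {
    group_bitscore_tests(hom$bitscore, hom$group)
  } else list(anova_p = NA_real_, kw_p = NA_real_)

  genes_with_groups <- data.frame(
    gene = sig$gene_symbol, group = as.character(sig$group),
    stringsAsFactors = FALSE
  )
  battery <- NULL
  dist_tab <- NULL
  if (nrow(genes_with_groups) > 0L) {
    inter <- generate_interactions(cfg, genes_with_groups)
    dist_tab <- build_signed_distances(inter$interactions, inter$genes)
    battery <- suppressWarnings(run_battery(dist_tab))
  }

  seqs <- generate_circ_sequences(cfg)
  orfs <- lapply(seqs$seqs, find_circular_orfs)
  n_with_orf <- sum(vapply(orfs, nrow, 0L) > 0L)
  kozak <- lapply(seqs$seqs, kozak_scan)
  n_kozak <- sum(lengths(kozak) > 0L)
  ires_pass <- filter_ires(seqs$ires)

  report <- structure(list(
    seed = cfg$seed,
    n_detected = c(control = nrow(sim$control), treated = nrow(sim$treated)),
    n_merged = nrow(merged),
    circ_ci = circ_ci, mrna_ci = mrna_ci,
    n_significant = n_sig, n_up = n_up, n_down = n_down,
    pct_up = .pct(n_up, n_sig),
    group_sizes = as.integer(counts),
    group_labels = names(counts),
    direction_bias = list(
      overall = list(u = n_sig, n = max(n_up, n_down), p = bias_overall),
      up_circ_mrna = list(u = u2, n = max(n_up_mrna_up, n_up_mrna_down),
                          p = bias_up_mrna)
    ),
    exon_tests = exon_tests,
    homology = list(n = nrow(hom), n_significant = n_hom_sig,
                    pct_significant = .pct(n_hom_sig, nrow(hom)),
                    tests = bit_tests),
    orf = list(n = length(orfs), n_with_orf = n_with_orf,
               pct_with_orf = .pct(n_with_orf, length(orfs)),
               n_kozak = n_kozak,
               n_ires_pass = nrow(ires_pass),
               pct_ires_pass = .pct(nrow(ires_pass), length(orfs))),
    battery = battery,
    tables = list(merged = merged, homology = hom,
                  distances = dist_tab, ires = seqs$ires,
                  mrna = mrna$table)
  ), class = "circ_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.table(merged, file.path(out_dir, "merged_classified.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(hom, file.path(out_dir, "intron_homology.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dist_tab)) {
      write.table(dist_tab, file.path(out_dir, "signed_distances.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(
      report_summary(report),
      file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  report
}

#' Plain-list summary of a pipeline report (JSON-serialisable)
#'
#' @param report A `circ_report` from [run_pipeline()].
#' @return A nested list of counts, percentages and p-values.
#' @export
report_summary <- function(report) {
  list(
    seed = report$seed,
    n_detected = as.list(report$n_detected),
    n_merged = report$n_merged,
    circ_ci = list(center = report$circ_ci$center,
                   half_width = report$circ_ci$half_width),
    mrna_ci = list(center = report$mrna_ci$center,
                   half_width = report$mrna_ci$half_width),
    n_significant = report$n_significant,
    n_up = report$n_up, n_down = report$n_down, pct_up = report$pct_up,
    group_sizes = as.list(setNames(report$group_sizes,
                                   report$group_labels)),
    direction_bias = report$direction_bias,
    exon_tests = report$exon_tests,
    homology = report$homology[c("n", "n_significant", "pct_significant",
                                 "tests")],
    orf = report$orf
  )
}

#' @export
print.circ_report <- function(x, ...) {
  cat("circRNA pipeline report (seed ", x$seed, ")\n", sep = "")
  cat(sprintf("  detected: %d control / %d treated; merged: %d\n",
              x$n_detected[["control"]], x$n_detected[["treated"]],
              x$n_merged))
  cat(sprintf("  significant: %d (%d up / %d down, %.1f%% up)\n",
              x$n_significant, x$n_up, x$n_down, x$pct_up))
  cat("  group sizes:",
      paste(x$group_labels, x$group_sizes, sep = "=", collapse = " "),
      "\n")
  cat(sprintf("  direction bias p (overall): %.4g\n",
              x$direction_bias$overall$p))
  cat(sprintf("  homology: %d/%d significant (%.1f%%)\n",
              x$homology$n_significant, x$homology$n,
              x$homology$pct_significant))
  cat(sprintf("  ORFs: %d/%d sequences (%.1f%%); IRES pass: %d\n",
              x$orf$n_with_orf, x$orf$n, x$orf$pct_with_orf,
              x$orf$n_ires_pass))
  invisible(x)
}
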