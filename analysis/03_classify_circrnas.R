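#!/usr/bin/env Rscript
# Read the serialised synthetic calls back through the dialect parsers,
# merge the two conditions, fit the log-ratio and housekeeping
# intervals, assign the six groups and score recovery against the
# planted truth.

library(circlpc)

ctrl <- read_circexplorer2("results/sim/control.circexplorer2.txt",
                           condition = "control")
trt <- read_circexplorer2("results/sim/treated.circexplorer2.txt",
                          condition = "treated")
merged <- merge_conditions(ctrl, trt)
rr <- compute_ratio(merged$reads_treated, merged$reads_control)
merged$ratio <- rr$ratio
merged$log2_ratio <- rr$log2_ratio

mrna <- read.delim("results/sim/mrna_fold_changes.tsv")
merged$mrna_fc <- mrna$fold_change[match(merged$gene_symbol, mrna$gene)]

circ_ci <- fit_ci(merged$log2_ratio)
hk <- mrna[mrna$gene %in% housekeeping_genes(), ]
mrna_ci <- fit_ci(hk$fold_change)
merged <- assign_six_groups(merged, circ_ci, mrna_ci)

counts <- group_counts(merged)
n_sig <- sum(counts)
n_up <- sum(counts[c("up_increased", "up_unchanged", "up_decreased")])
p_bias <- direction_bias_p(n_sig, max(n_up, n_sig - n_up))

truth <- read.delim("results/sim/circ_truth.tsv")
tr <- truth[match(merged$circ_key, truth$circ_key), ]
sig <- merged$circ_class != "not_significant"
precision <- mean(merged$circ_class[sig] == tr$class[sig])

write.table(merged, "results/classified_circrnas.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("merged %d circRNAs; log-ratio CI %.3f +/- %.3f; housekeeping CI %.3f +/- %.3f\n",
            nrow(merged), circ_ci$center, circ_ci$half_width,
            mrna_ci$center, mrna_ci$half_width))
cat(sprintf("significant: %d (%d up); direction-bias p = %.4g\n",
            n_sig, n_up, p_bias))
cat("group sizes:",
    paste(names(counts), as.integer(counts), sep = "=", collapse = " "),
    "\n")
cat(sprintf("direction agreement with planted truth among significant calls: %.1f%%\n",
            100 * precision))
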