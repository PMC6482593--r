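#!/usr/bin/env Rscript
# Generate the synthetic input set under the default study conditions
# and serialise every table in its external dialect, so the later
# stages exercise the same parsers a real dataset would.

library(circlpc)

seed <- 20240901L
cfg <- sim_config(seed = seed)
dir.create("results/sim", showWarnings = FALSE, recursive = TRUE)

sim <- generate_circ_tables(cfg)
write_circexplorer2(sim$control, "results/sim/control.circexplorer2.txt",
                    condition = "control")
write_circexplorer2(sim$treated, "results/sim/treated.circexplorer2.txt",
                    condition = "treated")
write_ciri(sim$treated, "results/sim/treated.ciri.txt",
           condition = "treated")
write.table(sim$truth, "results/sim/circ_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

mrna <- generate_mrna_table(cfg, unique(sim$truth$gene_symbol))
write.table(mrna$table, "results/sim/mrna_fold_changes.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(mrna$truth, "results/sim/mrna_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

ip <- generate_intron_pairs(cfg, n_pairs = 77L)
seqs <- setNames(
  c(ip$pairs$intron5, ip$pairs$intron3),
  c(paste0(ip$pairs$key, "/5"), paste0(ip$pairs$key, "/3"))
)
write_fasta(seqs, "results/sim/flanking_introns.fasta")
write.table(ip$truth, "results/sim/intron_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

sq <- generate_circ_sequences(cfg)
write_fasta(sq$seqs, "results/sim/circ_sequences.fasta")
write.table(sq$ires, "results/sim/ires_annotations.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sq$truth, "results/sim/sequence_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("simulated", nrow(sim$control), "control and", nrow(sim$treated),
    "treated circRNA calls;", sum(sim$truth$shared), "shared\n")
cat("planted classes:",
    paste(names(table(sim$truth$class)), table(sim$truth$class),
          sep = "=", collapse = " "), "\n")
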