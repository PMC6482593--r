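#!/usr/bin/env Rscript
# Score reverse-complement homology for the serialised flanking-intron
# pairs and compare recovered significance against the planted truth.

library(circlpc)

fa <- read_fasta("results/sim/flanking_introns.fasta")
keys <- unique(sub("/[53]$", "", names(fa)))
pairs <- data.frame(
  key = keys,
  intron5 = unname(fa[paste0(keys, "/5")]),
  intron3 = unname(fa[paste0(keys, "/3")]),
  stringsAsFactors = FALSE
)
scores <- score_all(pairs)
truth <- read.delim("results/sim/intron_truth.tsv")

n_sig <- sum(scores$significant)
agree <- mean(scores$significant ==
                truth$planted[match(scores$key, truth$key)])

write.table(scores, "results/intron_homology_scores.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat(sprintf("significant reverse complements: %d / %d (%.1f%%)\n",
            n_sig, nrow(scores), 100 * n_sig / nrow(scores)))
cat(sprintf("agreement with planted truth: %.1f%%\n", 100 * agree))
cat(sprintf("median pident of significant pairs: %.1f\n",
            median(scores$pident[scores$significant])))
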