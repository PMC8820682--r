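#!/usr/bin/env Rscript
# miR-21 correlation screen over the treatment-arm design (all diets and
# treatments at 0 and 24 h), with raw p < 0.05 partner calls, and the check
# against the planted correlation classes.

suppressPackageStartupMessages(library(regenmir))

expr <- read_expression("results/logcpm.tsv", "results/samples_filtered.tsv")
smp <- expr$samples
ids <- smp$sample_id[smp$time_h %in% c(0, 24)]
screen <- correlate_to_reference(expr, "miR-21", ids)
write.table(screen, "results/mir21_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

parts <- significant_partners(screen, alpha = 0.05)
cat(sprintf("screen over %d samples: %d positive, %d negative partners (raw p < 0.05)\n",
            length(ids), length(parts$pos), length(parts$neg)))

truth <- read.delim("results/truth_corr_class.tsv")
pos_t <- truth$mirna[truth$corr_class == "pos"]
neg_t <- truth$mirna[truth$corr_class == "neg"]
cat(sprintf("planted partners recovered: %d/%d positive (%s), %d/%d negative (%s)\n",
            sum(pos_t %in% parts$pos), length(pos_t),
            paste(intersect(pos_t, parts$pos), collapse = ","),
            sum(neg_t %in% parts$neg), length(neg_t),
            paste(intersect(neg_t, parts$neg), collapse = ",")))
top <- screen[order(screen$p), ][1:8, c("mirna_id", "r", "p")]
cat("strongest correlations to miR-21:\n")
print(top, row.names = FALSE)
cat("wrote results/mir21_screen.tsv\n")
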