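#!/usr/bin/env Rscript
# TMM scaling factors and the log2-cpm transform for the simulated counts;
# precision weights are computed for reference but the downstream pattern and
# correlation stages use unweighted log-cpm.

suppressPackageStartupMessages(library(regenmir))

counts <- read_counts("results/counts.tsv", "results/samples.tsv")
counts <- filter_expressed(counts, min_cpm = 1, min_samples = 3)
cat(sprintf("expression filter kept %d miRNAs\n", nrow(counts$counts)))

nf <- tmm_factors(counts)
cat(sprintf("TMM reference sample: %s; factor range %.3f - %.3f\n",
            nf$reference_sample, min(nf$factors), max(nf$factors)))
write.table(data.frame(sample_id = names(nf$factors), factor = nf$factors),
            "results/tmm_factors.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

expr <- log_cpm(counts, nf)
write_expression(expr, "results/logcpm.tsv", "results/samples_filtered.tsv")

X <- group_design(counts$samples)
w <- precision_weights(counts, nf, X)
cat(sprintf("precision weights span %.2f - %.2f (median %.2f)\n",
            min(w$weights), max(w$weights), median(w$weights)))
cat("wrote results/tmm_factors.tsv, results/logcpm.tsv\n")
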