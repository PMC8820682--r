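#!/usr/bin/env Rscript
# ddCT relative quantification of the in-vitro qPCR arm: per-replicate
# normalization against the three endogenous reference miRNAs, fold changes
# versus the untreated group, and unpaired t-tests with star annotations.

suppressPackageStartupMessages(library(regenmir))

ct <- read_qpcr("results/qpcr_ct.tsv")
refs <- c("hsa-miR-99b-5p", "hsa-miR-23a-3p", "hsa-miR-100-5p")
dct <- delta_ct(ct, refs)
res <- ddct_fold_change(dct, control_group = "untreated")
write.table(res, "results/ddct_results.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("fold change vs untreated (mean of n = 4, ddCT method):\n")
print(res[, c("target", "group", "n", "fold_change", "se_fold_change",
              "p", "stars")], row.names = FALSE, digits = 3)
cat("wrote results/ddct_results.tsv\n")
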