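#!/usr/bin/env Rscript
# Moderated-t differential expression of every post-hepatectomy time point
# against baseline within each diet (untreated animals), with the
# |log2FC| >= 1.5 + BH <= 0.05 call rule.

suppressPackageStartupMessages(library(regenmir))

expr <- read_expression("results/logcpm.tsv", "results/samples_filtered.tsv")
smp <- expr$samples
unt <- smp$treatment == "untreated"
e <- expression_matrix(expr$values[, smp$sample_id[unt], drop = FALSE],
                       smp[unt, ])
X <- group_design(e$samples)

contrasts <- list()
for (diet in c("CHO", "EtOH")) {
  for (t in c(6, 24, 72)) {
    contrasts[[sprintf("%s_t%d_vs_t0", diet, t)]] <-
      make_contrast(X, sprintf("%s.untreated.t%d", diet, t),
                    sprintf("%s.untreated.t0", diet))
  }
}
mod <- moderate(fit_models(e, X, contrasts))
cat(sprintf("moderation prior: d0 = %.2f, s0^2 = %.4f\n",
            mod$params$d0, mod$params$s02))
write.table(mod$table, "results/de_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

calls <- call_de(mod$table, lfc_min = 1.5, alpha = 0.05)
for (cn in names(calls)) {
  cat(sprintf("%-16s up %3d  down %3d\n", cn,
              length(calls[[cn]]$up), length(calls[[cn]]$down)))
}

by_diet <- lapply(c(CHO = "CHO_t72_vs_t0", EtOH = "EtOH_t72_vs_t0"),
                  function(cn) unique(unlist(calls[[cn]])))
cat(sprintf("DE by 72 h: union %d, intersection %d\n",
            length(unique(unlist(by_diet))),
            length(Reduce(intersect, by_diet))))
cat("wrote results/de_table.tsv\n")
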