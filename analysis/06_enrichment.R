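#!/usr/bin/env Rscript
# Signature enrichment: panel overlap of the curated nonparenchymal-cell
# miRNA signatures, then permutation GSEA of each against the EtOH 24 h
# ranking. The stellate-cell activation (HSC_up) members are planted
# upregulated in EtOH, so that signature should enrich strongly.

suppressPackageStartupMessages(library(regenmir))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 1L

sigs <- load_packaged_signatures()
cat("panel overlap of curated signatures (against the assay pseudo-panel):\n")
for (s in sigs$signatures) {
  ov <- signature_overlap(s, sigs$panel)
  cat(sprintf("  %-9s %2d members, %2d overlapping, %2d nonoverlapping\n",
              s$name, length(s$members), ov$n_overlapping,
              ov$n_nonoverlapping))
}

de <- read.delim("results/de_table.tsv")
ranked <- rank_mirnas(de[de$contrast == "EtOH_t24_vs_t0", ],
                      metric = "moderated_t")
rows <- list()
for (s in sigs$signatures) {
  r <- tryCatch(gsea(ranked, s, mode = "gene_set", n_perm = 1000,
                     seed = seed + 1L),
                error = function(e) NULL)
  if (is.null(r)) next
  cat(sprintf("  GSEA %-9s ES %6.3f  NES %6.2f  p %.4g\n",
              s$name, r$es, r$nes, r$p))
  rows[[s$name]] <- data.frame(signature = s$name, es = r$es, nes = r$nes,
                               p = r$p, n_perm = r$n_perm,
                               leading_edge = paste(r$leading_edge,
                                                    collapse = ","))
}
write.table(do.call(rbind, rows), "results/gsea_results.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

# signature derivation rule (FDR < 0.1, top 20 |log2FC|) on the same contrast
derived <- derive_signature(de[de$contrast == "EtOH_t24_vs_t0", ],
                            fdr_max = 0.1, top_k = 20, name = "EtOH_24h_top")
cat(sprintf("derived signature '%s': %d members\n", derived$name,
            length(derived$members)))
cat("wrote results/gsea_results.tsv\n")
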