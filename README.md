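# regenmir

Chronic ethanol consumption impairs the liver's ability to regenerate after
injury, and miRNA regulatory networks — with miR-21 at their hub — are
implicated in that impairment through hepatic stellate cell (HSC)
activation. `regenmir` is an R package plus analysis workflow for panel-based
miRNA count data from a two-diet rat partial-hepatectomy (PHx) time course:
ethanol-fed vs pair-fed control animals sampled at 0, 6, 24 and 72 h after
70% PHx (n = 3), with anti-miR-21 (AM21) and saline treatment arms.

## What it computes

* **TMM + log-CPM normalization** — scaling factor for sample $j$ against a
  reference $r$: $f_j = 2^{\sum_{g} w_g M_g / \sum_g w_g}$ over doubly
  trimmed M-values $M_g = \log_2\frac{y_{gj}/N_j}{y_{gr}/N_r}$ with
  inverse-variance weights, rescaled to geometric mean 1; then
  $\log_2\!\big(\tfrac{y+0.5}{N f + 1}\cdot 10^6\big)$, with optional
  mean-variance precision weights.
* **Moderated differential expression** — per-miRNA least squares with an
  empirical-Bayes variance prior: posterior variance
  $\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, moderated
  $t = \hat\beta / (\tilde s \cdot \mathrm{sd_u})$ on $d_0 + d$ df, BH
  adjustment, and the study's call rule $|\log_2 FC| \ge 1.5$ at FDR ≤ 0.05.
* **COMPACT** (comparative pattern count) — each miRNA's fold-change
  trajectory against baseline is discretized per diet
  ($\ge \tau \Rightarrow$ U, $\le -\tau \Rightarrow$ D, else 0, τ = 1.5
  log2) and miRNAs are counted in the 27 × 27 joint (CHO pattern, EtOH
  pattern) matrix with full cluster membership.
* **miR-21 correlation screen** — Pearson r on log-CPM across the treatment
  arms, $t = r\sqrt{(n-2)/(1-r^2)}$, partners called at raw p < 0.05.
* **Signature GSEA** — weighted Kolmogorov–Smirnov enrichment of curated
  HSC/LSEC/Kupffer-cell miRNA signatures (shipped as a GMT fixture) with a
  gene-set permutation null, plus the signature-derivation rule
  (FDR < 0.1, top 20 |log2FC|).
* **ΔΔCT qPCR quantification** — $\Delta CT = CT_\text{target} -
  \overline{CT}_\text{refs}$ over three endogenous references, fold change
  $2^{-\Delta\Delta CT}$ vs the untreated group, unpaired t-tests.
* **Synthetic study generator** — negative-binomial NanoString-like counts
  over the full design with planted trajectories, latent-factor
  miR-21-correlated partners, an AM21 knockdown, qPCR CT tables, and
  recorded ground truth, so every stage is testable offline.

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (seed as optional argument) and write tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1
Rscript analysis/02_normalize.R
Rscript analysis/03_differential_expression.R
Rscript analysis/04_compact.R
Rscript analysis/05_correlation.R
Rscript analysis/06_enrichment.R 1
Rscript analysis/07_qpcr_ddct.R
```

Selected output from seed 1:

```
DE by 72 h: union 37, intersection 5

COMPACT result: 27 x 27 pattern cells (CHO rows, EtOH columns), 420 miRNAs
  000 | 000 : 382
  000 | 0UU : 15
  D00 | 0UU : 10
  000 | 0DD : 6
  UUU | UUU : 5
planted-pattern recovery: 36 / 36 in their true cell

screen over 36 samples: 32 positive, 18 negative partners (raw p < 0.05)
planted partners recovered: 1/1 positive (miR-340-5p),
  4/4 negative (miR-365,let-7a,miR-1224,miR-146a)

  GSEA HSC_up    ES  0.968  NES   2.16  p 0.001403
  GSEA LSEC      ES  0.440  NES   1.08  p 0.3667
```

Reading this: 36 of the planted 36 miRNAs land in their true joint
trajectory cell (e.g. `D00 | 0UU` = transiently down at 6 h in controls but
up at 24/72 h under ethanol); the screen recovers the single planted
positive and all four negative miR-21 partners; and the stellate-cell
activation signature — whose members are planted upregulated under ethanol
— enriches strongly while the LSEC signature, planted null, does not. The
qPCR stage recovers the planted 2.83-fold miR-146a increase under AM21 as
2.95 ± 0.22 (n = 4).

In R, the same end-to-end run is one call:

```r
library(regenmir)
res <- run_synthetic_study(seed = 1)
res$summary
```

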