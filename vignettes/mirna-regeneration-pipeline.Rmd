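---
title: "Methods: miRNA time-course analysis of ethanol-impaired liver regeneration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA time-course analysis of ethanol-impaired liver regeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regenmir)
```

## The analysis and its assumptions

`regenmir` implements a complete analysis pipeline for panel-based miRNA
count data from a two-diet rat partial-hepatectomy (PHx) time course:
animals chronically pair-fed an ethanol (EtOH) or carbohydrate-control (CHO)
liquid diet, 70% PHx at time 0, livers sampled at 0, 6, 24 and 72 h
(n = 3 per cell), with anti-miR-21 (AM21) and saline treatment arms at 0 and
24 h. The scientific questions the stages answer, in order:

1. **Normalization** — remove between-sample composition and depth effects
   from the raw panel counts (TMM scaling factors, then log2 counts per
   million).
2. **Differential expression** — which miRNAs change after PHx within each
   diet, using per-miRNA linear models with empirical-Bayes variance
   moderation (essential at n = 3).
3. **COMPACT** — how the *trajectories* differ between diets: discretize
   each miRNA's fold-change path against baseline into {down, unchanged, up}
   codes per time point and count miRNAs in each joint (CHO pattern, EtOH
   pattern) cell.
4. **Correlation screen** — which miRNAs co-vary with miR-21 across the
   treatment-arm samples, the candidates for a miR-21-centred regulatory
   network.
5. **Signature enrichment** — whether the bulk-tissue ranking is enriched
   for curated nonparenchymal cell-type signatures (hepatic stellate cell
   activation up/down, LSEC-enriched, Kupffer-cell post-PHx), by weighted
   Kolmogorov–Smirnov GSEA with a permutation null.
6. **ΔΔCT** — relative quantification of the in-vitro qPCR validation arm
   against three endogenous reference miRNAs.

All stages consume the shared data model (`count_matrix`,
`expression_matrix`, `qpcr_table`); no stage re-reads raw files.

## The synthetic study

Because the deposited profiling data are accession-gated (see
`reproduce_study()`), the package ships a generator whose defaults *are* the
study conditions, with recorded ground truth for every planted feature:

* **Count law.** Gamma–Poisson (negative binomial), variance
  $\mu + \phi\mu^2$. The assay is a hybridization counter with tight
  technical replication, so the default technical overdispersion is small
  ($\phi = 0.01$); $\phi = 0$ degenerates to Poisson for closed-form tests.
  Animal-to-animal biological variation is a *separate* log-normal layer
  (`biological_sd_log2`, default 0.5 log2 units), so the two noise sources
  are independently tunable — a test of correlation planting can let biology
  dominate, a test of the count law can switch biology off.
* **Abundance.** Baseline abundances are log-normal (log2 mean 7, SD 2), so
  a 420-miRNA panel spans roughly five orders of magnitude. Planted miRNAs
  are placed mid-to-high abundance, as the study's focal miRNAs are
  well-expressed.
* **Planted dynamics** (per-step effect $\delta = 3$ log2 units, i.e. twice
  the discretization threshold): 25 miRNAs up at 24 and 72 h in EtOH only —
  including the 16-member stellate-cell activation signature and miR-21
  itself — of which the first 10 are also transiently down at 6 h in CHO;
  6 miRNAs down at 24 and 72 h in EtOH only, including the four negatively
  miR-21-correlated partners; and 5 diet-independent responders. In total 36
  differentially expressed miRNAs by 72 h across the groups, matching the
  headline structure of the in-vivo study. (The in-vivo report's own
  cluster arithmetic is internally inconsistent by one — 10 + 14 vs 25 — and
  the generator resolves it as 10 + 15 = 25.)
* **Correlated partners.** One positive (miR-340-5p) and four negative
  (miR-365, let-7a, miR-1224, miR-146a) partners share a per-sample latent
  Gaussian factor with miR-21: partner loading $\pm$`corr_strength`
  (default 0.9), reference loading 1. The AM21 arm applies a fixed log2
  knockdown (default 2, i.e. four-fold) to the reference by shifting the
  latent factor, so the knockdown propagates to the partners with their
  loadings — the mechanism by which the screen's "correlated differential
  expression" arises.
* **qPCR.** CT values are `base CT − planted log2 effect + N(0, sd)`; the
  three endogenous references are constrained to zero effect.

A single integer seed governs everything; equal seeds give bit-identical
output.

### What the generator does *not* emulate

Cartridge-level artifacts (spike-in probes, fields of view), probe-specific
hybridization efficiency, cell-type deconvolution, and any form of
miRNA–target interaction. Passing recovery tests therefore demonstrates that
the *statistical machinery* is correct under the declared noise model, not
that the biological conclusions of any particular dataset are right.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| TMM trims (`m_trim`, `a_trim`) | 0.30, 0.05 | fraction/side | the published TMM defaults; the study cites the method without parameters |
| log-cpm `prior` | 0.5 | counts | keeps zeros finite; the "+1" library offset follows the published transform |
| DE call `lfc_min` | 1.5 | log2 | the study's stated fold-change rule, read literally as \|log2FC\| ≥ 1.5; boundary equality counts |
| DE call `alpha` | 0.05 | BH FDR | the conventional gate; a `fc_only` switch drops it since the figure legend names only the fold-change rule |
| COMPACT `tau` | 1.5 | log2 | same threshold as the DE rule |
| screen `alpha` | 0.05 | raw p | the screen was defined with raw p ("P < 0.05"); BH offered as an option, with the multiplicity caveat in the output |
| GSEA `weight_p` | 1 | – | canonical weighted-KS default |
| GSEA `n_perm` | 1000 | – | p resolution 1/1001 |
| `dispersion_phi` | 0.01 | – | technical overdispersion of a counting assay |
| `biological_sd_log2` | 0.5 | log2 | animal-to-animal variation at n = 3 |

## Numerical and design choices

* **Reference sample for TMM** is the column whose upper quartile of
  counts-per-million is closest to the mean upper quartile (the published
  default), overridable. Genes zero in either column are excluded; a sample
  sharing no nonzero genes with the reference gets factor 1 with a warning;
  factors are rescaled to geometric mean 1 (held to 1e-12).
* **Precision weights** follow the mean–variance trend recipe: per-miRNA
  linear fit on log-cpm, lowess of sqrt(residual SD) on average log2 count,
  weight = trend value$^{-4}$ at the observation's fitted log-count, clamped
  to the trend's range. Weights are computed but optional downstream: the
  COMPACT and correlation stages use unweighted log-cpm, matching plain
  Pearson correlation on normalized expression.
* **Moderation prior** $(d_0, s_0^2)$ uses the closed-form moment estimator
  on $\log s^2$ (digamma/trigamma inversion; Newton for the trigamma
  inverse). `prior_df = 0` recovers the ordinary t exactly; an infinite
  prior pools completely; all-zero residual variances skip moderation with a
  warning.
* **"36 DE by 72 h in both groups"** is ambiguous between union and
  intersection of diets; both are computed, and the headline number is the
  union. The EtOH-specific up/down sets require the call in the same
  direction at *both* later time points (24 and 72 h), the literal reading
  of "at later time points" and the planted pattern family.
* **COMPACT** aggregates replicates by the arithmetic mean of log-cpm
  (geometric mean in linear space); baseline is 0 h within the same diet;
  equality at ±tau counts as regulated; the input universe is the
  expression-filtered panel (an option restricts to DE calls). Raising tau
  can only move miRNAs toward the all-zero pattern.
* **GSEA permutation mode** defaults to gene-set permutation: with n = 3
  per group a phenotype null has at most $\binom{6}{3}/2 = 10$ distinct
  values, too coarse for p < 0.05. Phenotype mode is retained; with fewer
  than 10 distinct relabelings it warns and reports the exact-permutation p.
  The nominal p is sign-stratified — same-sign exceedances over (1 + number
  of same-sign permutations) — which keeps the null p approximately uniform
  and bounded below by 1/(1 + n_perm). Ranking ties break lexicographically
  by id so results are deterministic.
* **Identifier policy.** Matching is exact-string after trimming and
  case-folding the "miR"/"let" prefix; species prefixes are preserved; a
  small curated alias table resolves typographical variants (e.g.
  "miR-3405p"); unresolved ids are reported, never silently dropped.
* **ΔΔCT statistics** are computed on the cycle (ΔCT) scale — standard
  practice — with Student's pooled-variance t by default (the conventional
  unpaired test) and Welch optional; the fold-change SE is propagated by
  the delta method; double-zero-variance comparisons are flagged degenerate
  with p = 1 rather than erroring.

## Test problem sizes

The suite exercises each stage at sizes chosen to make the statistical
assertions sharp while keeping the default run fast: oracle sweeps on 20×6
to 50×6 matrices (50 replicates), null calibration of the moderated t on
10,000-miRNA panels (3 seeds), recovery benchmarks on the 420-miRNA panel
over 20 seeds, GSEA null uniformity over 200 random signatures at 1000
permutations, and 1000-replicate qPCR null calibration. The correlation
recovery benchmark sets `biological_sd_log2 = 1` so biological covariation
dominates the assay noise floor — the property under test is the screen's
detection of a planted latent correlation of 0.9, not the technical
attenuation of small biological signals.

## Known limitations

* The pseudo-panel shipped with the curated signatures encodes only the
  panel membership implied by the signatures' overlapping/nonoverlapping
  split; with real deposited data the true 420-probe panel replaces it.
* The pooled correlation screen deliberately mixes diet, time and treatment
  structure (the design of the treatment arms), so planted *group* dynamics
  also produce genuine correlations with miR-21 beyond the latent-factor
  partners; the ground-truth classes are the recovery criterion.
* No amplification-efficiency correction in the qPCR stage; no
  spline/time-course trend tests; no statistical test on COMPACT cell
  occupancy; no network inference beyond the correlation screen.
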