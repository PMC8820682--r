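#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a synthetic study at the default design conditions, then runs
#' every stage: expression filtering, TMM + log2-cpm normalization,
#' moderated-t differential expression of each time point against baseline
#' within diet, COMPACT pattern counting between diets, the miR-21
#' correlation screen over the baseline/24 h treatment arms, gene-set
#' enrichment of the packaged stellate-cell signature, and a qPCR
#' delta-delta-CT round trip. All randomness derives from `seed`.
#'
#' @param seed integer master seed.
#' @param design a [study_design()].
#' @param cfg a [synthetic_config()]; its seed is overridden by `seed`.
#' @param n_perm GSEA permutations.
#' @param lfc_min,alpha differential-expression call thresholds.
#' @param tau COMPACT discretization threshold.
#' @return list with all stage outputs and a `summary` list of headline
#'   numbers (DE counts, correlation partners, COMPACT recovery, GSEA p,
#'   qPCR recovered fold change).
#' @export
run_synthetic_study <- function(seed = 1L,
                                design = study_design(),
                                cfg = synthetic_config(),
                                n_perm = 1000,
                                lfc_min = 1.5, alpha = 0.05, tau = 1.5) {
  seed <- as.integer(seed)
  cfg$seed <- seed
  sim <- generate_counts(design, cfg)
  counts <- filter_expressed(sim$counts, min_cpm = 1, min_samples = 3)
  nf <- tmm_factors(counts)
  expr <- log_cpm(counts, nf)

  # --- differential expression: time vs baseline within diet (untreated) ---
  unt <- counts$samples$sample_id[counts$samples$treatment == design$treatments[1]]
  expr_unt <- expression_matrix(expr$values[, unt, drop = FALSE],
                                counts$samples[counts$samples$sample_id %in% unt, ])
  X <- group_design(expr_unt$samples)
  nb_times <- design$times_h[-1]
  contrasts <- list()
  for (diet in design$diets) {
    for (t in nb_times) {
      contrasts[[sprintf("%s_t%g_vs_t%g", diet, t, design$times_h[1])]] <-
        make_contrast(X,
                      plus = sprintf("%s.%s.t%g", diet, design$treatments[1], t),
                      minus = sprintf("%s.%s.t%g", diet, design$treatments[1],
                                      design$times_h[1]))
    }
  }
  fit <- fit_models(expr_unt, X, contrasts)
  mod <- moderate(fit)
  de_calls <- call_de(mod$table, lfc_min = lfc_min, alpha = alpha)

  t_last <- nb_times[length(nb_times)]
  last_names <- sprintf("%s_t%g_vs_t%g", design$diets, t_last, design$times_h[1])
  de_by_diet <- lapply(stats::setNames(last_names, design$diets), function(cn) {
    unique(c(de_calls[[cn]]$up, de_calls[[cn]]$down))
  })
  de_union <- unique(unlist(de_by_diet))
  de_intersection <- Reduce(intersect, de_by_diet)
  # "regulated at the later time points": called in the same direction at
  # both post-24 h samples of the time course
  late_times <- nb_times[nb_times >= 24]
  late_set <- function(diet, dir) {
    Reduce(intersect, lapply(late_times, function(t) {
      de_calls[[sprintf("%s_t%g_vs_t%g", diet, t, design$times_h[1])]][[dir]]
    }))
  }
  etoh_specific_up <- setdiff(late_set("EtOH", "up"), late_set("CHO", "up"))
  etoh_specific_down <- setdiff(late_set("EtOH", "down"), late_set("CHO", "down"))

  # --- COMPACT between diets ---
  cube <- fold_change_vs_baseline(expr, baseline_time = design$times_h[1],
                                  condition = "diet",
                                  treatment = design$treatments[1])
  pats <- discretize(cube, tau = tau)
  compact <- pattern_counts(pats[, "CHO"], pats[, "EtOH"],
                            condition_names = c("CHO", "EtOH"))
  truth_pat <- sim$truth$pattern_by_mirna_diet
  planted <- unique(truth_pat$mirna)
  in_cell <- vapply(planted, function(m) {
    pa <- truth_pat$pattern[truth_pat$mirna == m & truth_pat$diet == "CHO"]
    pb <- truth_pat$pattern[truth_pat$mirna == m & truth_pat$diet == "EtOH"]
    m %in% extract_cluster(compact, pa, pb)
  }, logical(1))
  compact_recovery <- mean(in_cell)

  # --- miR-21 correlation screen over the treatment-arm design ---
  smp <- counts$samples
  corr_ids <- smp$sample_id[smp$time_h %in% design$treatment_times_h]
  screen <- correlate_to_reference(expr, cfg$reference_mirna, corr_ids)
  partners <- significant_partners(screen, alpha = 0.05)
  truth_corr <- sim$truth$corr_class
  pos_planted <- names(truth_corr)[truth_corr == "pos"]
  neg_planted <- names(truth_corr)[truth_corr == "neg"]
  pos_recovered <- intersect(partners$pos, pos_planted)
  neg_recovered <- intersect(partners$neg, neg_planted)

  # --- GSEA of the stellate-cell activation signature ---
  sigs <- load_packaged_signatures()
  hsc_up <- sigs$signatures[[which(vapply(sigs$signatures, `[[`, "", "name") == "HSC_up")]]
  etoh24 <- mod$table[mod$table$contrast ==
                        sprintf("EtOH_t%g_vs_t%g", nb_times[min(2, length(nb_times))],
                                design$times_h[1]), ]
  ranked <- rank_mirnas(etoh24, metric = "moderated_t")
  gsea_hsc_up <- gsea(ranked, hsc_up, mode = "gene_set", n_perm = n_perm,
                      seed = seed + 1L)

  # --- qPCR round trip (in vitro arm) ---
  eff <- matrix(0, 2, 4,
                dimnames = list(c("hsa-miR-146a-5p", "hsa-miR-199a-3p"),
                                c("untreated", "AM21", "TGFb", "AM21+TGFb")))
  eff["hsa-miR-146a-5p", c("AM21", "AM21+TGFb")] <- c(1.5, 1.0)
  eff["hsa-miR-146a-5p", "TGFb"] <- -1.0
  eff["hsa-miR-199a-3p", "TGFb"] <- 1.2
  eff["hsa-miR-199a-3p", "AM21"] <- -0.8
  ct <- generate_qpcr(colnames(eff), eff, n_reps = 4, ct_noise_sd = 0.2,
                      seed = seed + 2L)
  dct <- delta_ct(ct, ref_targets = c("hsa-miR-99b-5p", "hsa-miR-23a-3p",
                                      "hsa-miR-100-5p"))
  ddct <- ddct_fold_change(dct, control_group = "untreated")
  qpcr_fc_146a_am21 <- ddct$fold_change[ddct$target == "hsa-miR-146a-5p" &
                                          ddct$group == "AM21"]

  list(sim = sim, counts = counts, norm_factors = nf, expr = expr,
       de = mod, de_calls = de_calls, compact = compact, patterns = pats,
       screen = screen, partners = partners, gsea_hsc_up = gsea_hsc_up,
       qpcr = list(ct = ct, dct = dct, ddct = ddct),
       summary = list(
         n_de_72h_union = length(de_union),
         n_de_72h_intersection = length(de_intersection),
         n_up_etoh_specific = length(etoh_specific_up),
         n_down_etoh_specific = length(etoh_specific_down),
         n_pos_partners = length(partners$pos),
         n_neg_partners = length(partners$neg),
         n_pos_recovered = length(pos_recovered),
         n_neg_recovered = length(neg_recovered),
         compact_recovery = compact_recovery,
         gsea_hsc_up_p = gsea_hsc_up$p,
         gsea_hsc_up_es = gsea_hsc_up$es,
         qpcr_fc_146a_am21 = qpcr_fc_146a_am21,
         qpcr_fc_146a_am21_expected = 2^1.5))
}
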