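test_that("design enumeration matches the factorial layout", {
  tab <- generate_design(study_design())
  expect_equal(sum(tab$treatment == "untreated"), 2 * 4 * 3)
  expect_equal(sum(tab$treatment == "AM21"), 2 * 2 * 3)
  expect_equal(sum(tab$treatment == "saline"), 2 * 2 * 3)
  expect_false(anyDuplicated(tab$sample_id) > 0)
  # treated arms only at the treatment times
  expect_true(all(tab$time_h[tab$treatment != "untreated"] %in% c(0, 24)))
})

test_that("degenerate designs are rejected naming the empty field", {
  expect_error(study_design(diets = character()), "diets")
  expect_error(study_design(times_h = numeric()), "times_h")
  expect_error(study_design(times_h = c(0, 6, 6)), "strictly increasing")
  expect_error(study_design(treatment_times_h = c(0, 12)), "subset")
  # n_reps = 1 is accepted here; replication is a downstream requirement
  expect_silent(generate_design(study_design(n_reps = 1)))
})

test_that("count generation is deterministic given the seed", {
  a <- generate_counts(study_design(), synthetic_config(seed = 7))
  b <- generate_counts(study_design(), synthetic_config(seed = 7))
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$corr_class, b$truth$corr_class)
  c <- generate_counts(study_design(), synthetic_config(seed = 8))
  expect_false(identical(a$counts$counts, c$counts$counts))
})

test_that("noise-free null counts match the mean formula", {
  cfg <- synthetic_config(planted_patterns = list(),
                          pos_corr_ids = character(),
                          neg_corr_ids = character(),
                          dispersion_phi = 0, biological_sd_log2 = 0,
                          library_size_range = c(1e6, 1e6), seed = 3)
  des <- study_design(panel_size = 100)
  sim <- generate_counts(des, cfg)
  m <- sim$counts$counts
  # expected proportions are recoverable from the realized matrix itself:
  # pooled total count per miRNA ~ Poisson(n_samples * lib * p_i)
  tot <- rowSums(m)
  p_hat <- tot / sum(tot)
  mu_tot <- ncol(m) * 1e6 * p_hat
  z <- (tot - mu_tot) / sqrt(mu_tot)
  expect_true(mean(abs(z) < 3) > 0.95)
})

test_that("planted log2 effects are recovered at inflated replication", {
  pat <- list(list(mirna = "miR-sim-001", delta = 2,
                   pattern = list(EtOH = c(1L, 1L, 1L))))
  cfg <- synthetic_config(planted_patterns = pat,
                          pos_corr_ids = character(),
                          neg_corr_ids = character(),
                          dispersion_phi = 0.02, biological_sd_log2 = 0.3,
                          seed = 11)
  des <- study_design(n_reps = 10, panel_size = 200)
  sim <- generate_counts(des, cfg)
  expr <- log_cpm(filter_expressed(sim$counts, 1, 3), NULL)
  cube <- fold_change_vs_baseline(expr)
  fc <- cube$fc["miR-sim-001", , "EtOH"]
  expect_true(all(abs(fc - 2) < 0.5))
})

test_that("counts obey the negative-binomial mean-variance law", {
  cfg <- synthetic_config(planted_patterns = list(),
                          pos_corr_ids = character(),
                          neg_corr_ids = character(),
                          dispersion_phi = 0.1, biological_sd_log2 = 0,
                          baseline_sd_log2 = 1,
                          library_size_range = c(5e5, 5e5), seed = 5)
  des <- study_design(diets = "CHO", times_h = 0,
                      treatments = "untreated", treatment_times_h = 0,
                      n_reps = 10000, panel_size = 70)
  sim <- generate_counts(des, cfg)
  m <- sim$counts$counts
  mu <- rowMeans(m)
  v <- apply(m, 1, var)
  hi <- mu > 200          # where the quadratic term dominates sampling error
  expect_true(any(hi))
  rel <- abs(v[hi] - (mu[hi] + 0.1 * mu[hi]^2)) / (mu[hi] + 0.1 * mu[hi]^2)
  expect_true(median(rel) < 0.10)
})

test_that("planted correlation classes carry the right sign", {
  hits <- 0L
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- synthetic_config(planted_patterns = list(),
                            corr_strength = 0.9, seed = s)
    sim <- generate_counts(study_design(panel_size = 100), cfg)
    expr <- log_cpm(sim$counts, NULL)
    v <- expr$values
    ref <- v[cfg$reference_mirna, ]
    r_pos <- cor(v[cfg$pos_corr_ids, ], ref)
    if (all(r_pos > 0)) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95)
})

test_that("panel smaller than the planted set is rejected", {
  expect_error(generate_counts(study_design(panel_size = 10),
                               synthetic_config()),
               "panel_size")
})

test_that("qPCR generator honors planted effects and rejects bad input", {
  eff <- matrix(c(0, 1), 1, 2,
                dimnames = list("miR-146a", c("ctrl", "AM21")))
  # zero noise: the planted +1 log2 change lowers CT by exactly one cycle
  tab <- generate_qpcr(c("ctrl", "AM21"), eff, ref_mirnas = "miR-99b",
                       n_reps = 3, ct_noise_sd = 0, seed = 1)
  ct_ctrl <- tab$ct[tab$target == "miR-146a" & tab$group == "ctrl"]
  ct_am21 <- tab$ct[tab$target == "miR-146a" & tab$group == "AM21"]
  expect_equal(unique(ct_ctrl) - unique(ct_am21), 1)
  # no effects, no noise: identical CTs everywhere
  eff0 <- matrix(0, 1, 2, dimnames = dimnames(eff))
  tab0 <- generate_qpcr(c("ctrl", "AM21"), eff0, ref_mirnas = "miR-99b",
                        n_reps = 2, ct_noise_sd = 0, seed = 1)
  expect_equal(length(unique(tab0$ct[tab0$target == "miR-146a"])), 1L)
  expect_error(generate_qpcr(c("a", "b"), eff, ref_mirnas = "miR-99b",
                             ct_noise_sd = -1), "ct_noise_sd")
  bad <- matrix(1, 1, 2, dimnames = list("miR-99b", c("ctrl", "AM21")))
  expect_error(generate_qpcr(c("ctrl", "AM21"), bad, ref_mirnas = "miR-99b"),
               "reference")
})

test_that("null generator keeps downstream DE calls near zero", {
  frac <- vapply(1:20, function(s) {
    sim <- generate_counts(study_design(panel_size = 100), null_config(s))
    expr <- log_cpm(sim$counts, tmm_factors(sim$counts))
    smp <- expr$samples
    unt <- smp$treatment == "untreated"
    e <- expression_matrix(expr$values[, smp$sample_id[unt]], smp[unt, ])
    X <- group_design(e$samples)
    ctr <- list(etoh72 = make_contrast(X, "EtOH.untreated.t72", "EtOH.untreated.t0"))
    mod <- moderate(fit_models(e, X, ctr))
    mean(mod$table$adj_p <= 0.05)
  }, numeric(1))
  expect_lte(mean(frac), 0.07)
})
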