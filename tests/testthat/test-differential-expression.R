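two_group_expr <- function(values_a, values_b) {
  v <- rbind(c(values_a, values_b))
  rownames(v) <- "miR-test"
  toy_expr(v, toy_samples(length(values_a) + length(values_b),
                          diets = rep(c("CHO", "EtOH"),
                                      c(length(values_a), length(values_b)))))
}

test_that("least-squares fits recover closed-form group contrasts", {
  e <- two_group_expr(c(1, 1, 1), c(3, 3, 3))
  X <- group_design(e$samples)
  ctr <- list(diff = make_contrast(X, "EtOH.untreated.t0", "CHO.untreated.t0"))
  fit <- fit_models(e, X, ctr)
  expect_equal(unname(fit$contrast_est[1, 1]), 2)
  expect_equal(unname(fit$sigma2), 0)
  # intercept-only model: coefficient is the sample mean
  e2 <- toy_expr(matrix(c(1, 2, 3, 10), 1))
  X2 <- matrix(1, 4, 1, dimnames = list(e2$samples$sample_id, "mu"))
  fit2 <- fit_models(e2, X2, list(mu = c(mu = 1)))
  expect_equal(unname(fit2$coefficients[1, 1]), 4)
})

test_that("coefficients match the normal-equations oracle", {
  set.seed(9)
  y <- matrix(rnorm(60), 10, 6)
  e <- toy_expr(y, toy_samples(6, times = rep(c(0, 24), each = 3)))
  X <- cbind(1, e$samples$time_h == 24)
  colnames(X) <- c("intercept", "t24")
  fit <- fit_models(e, X, list(t24 = c(intercept = 0, t24 = 1)))
  for (g in 1:10) {
    expect_equal(unname(fit$coefficients[g, ]),
                 unname(drop(oracle_ols(X, y[g, ]))), tolerance = 1e-10)
  }
})

test_that("rank-deficient designs are rejected listing aliased columns", {
  e <- toy_expr(matrix(rnorm(20), 5, 4))
  X <- cbind(a = rep(1, 4), b = rep(1, 4))
  expect_error(fit_models(e, X), "aliased.*b")
})

test_that("moderation limits behave as the theory dictates", {
  set.seed(2)
  y <- matrix(rnorm(200, sd = rep(c(0.5, 2), each = 10)), 20, 10)
  e <- toy_expr(y, toy_samples(10, diets = rep(c("CHO", "EtOH"), each = 5)))
  X <- group_design(e$samples)
  ctr <- list(d = make_contrast(X, "EtOH.untreated.t0", "CHO.untreated.t0"))
  fit <- fit_models(e, X, ctr)
  # d0 = 0: moderated t reduces exactly to the ordinary t
  m0 <- moderate(fit, prior_df = 0)
  se <- sqrt(fit$sigma2) * fit$contrast_sdu[, 1]
  expect_equal(m0$table$t, unname(fit$contrast_est[, 1] / se), tolerance = 1e-12)
  expect_equal(unique(m0$table$df_total), unique(fit$df))
  # all s2 equal: posterior variance is that common value for any d0
  fit_eq <- fit
  fit_eq$sigma2 <- rep(1.7, 20)
  m_eq <- moderate(fit_eq, prior_df = 4)
  expect_equal(m_eq$params$posterior_var, rep(1.7, 20), tolerance = 1e-12)
  # shrinkage direction: posterior lies between s2 and s02
  m <- moderate(fit)
  lo <- pmin(fit$sigma2, m$params$s02) - 1e-12
  hi <- pmax(fit$sigma2, m$params$s02) + 1e-12
  expect_true(all(m$params$posterior_var >= lo & m$params$posterior_var <= hi))
})

test_that("moderated statistics agree with the reference implementation", {
  skip_if_not_installed("limma")
  set.seed(5)
  y <- matrix(rnorm(100 * 8, sd = sqrt(rchisq(100, 4) / 4)), 100, 8)
  e <- toy_expr(y, toy_samples(8, diets = rep(c("CHO", "EtOH"), each = 4)))
  X <- model.matrix(~ factor(e$samples$diet))
  colnames(X) <- c("intercept", "etoh")
  fit <- fit_models(e, X, list(etoh = c(intercept = 0, etoh = 1)))
  mod <- moderate(fit)
  lf <- limma::eBayes(limma::lmFit(y, X))
  expect_equal(mod$params$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(mod$params$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(mod$table$t, unname(lf$t[, "etoh"]), tolerance = 1e-8)
  expect_equal(mod$table$p, unname(lf$p.value[, "etoh"]), tolerance = 1e-8)
})

test_that("BH adjustment matches its closed forms and the step-up oracle", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(11)
  for (i in 1:100) {
    p <- runif(sample(3:50, 1))
    expect_equal(adjust_bh(p), oracle_bh(p), tolerance = 1e-12)
  }
})

test_that("DE calls respect thresholds, boundaries, and monotonicity", {
  de <- data.frame(mirna_id = c("a", "b", "c", "d"),
                   contrast = "x",
                   log2fc = c(1.5, 3, -2, 0.2),
                   adj_p = c(0.04, 0.2, 0.01, 0.001))
  calls <- call_de(de, lfc_min = 1.5, alpha = 0.05)
  expect_equal(calls$x$up, "a")          # boundary equality counts
  expect_equal(calls$x$down, "c")        # b fails on adj p
  # fc-only switch ignores p
  expect_setequal(call_de(de, fc_only = TRUE)$x$up, c("a", "b"))
  # raising lfc_min never adds calls
  stricter <- call_de(de, lfc_min = 2.5, alpha = 0.05)
  expect_true(all(stricter$x$up %in% calls$x$up))
  expect_true(all(stricter$x$down %in% calls$x$down))
})

test_that("planted effects are recovered with controlled error", {
  recall <- numeric(20); fdr <- numeric(20)
  for (s in 1:20) {
    pat <- lapply(sprintf("miR-sim-%03d", 1:15), function(m) {
      list(mirna = m, delta = 2, pattern = list(EtOH = c(0L, 1L, 1L)))
    })
    # the stated noise condition: NB dispersion 0.1 as the only noise layer
    cfg <- synthetic_config(planted_patterns = pat,
                            pos_corr_ids = character(),
                            neg_corr_ids = character(),
                            dispersion_phi = 0.1,
                            biological_sd_log2 = 0, seed = s)
    sim <- generate_counts(study_design(panel_size = 120), cfg)
    expr <- log_cpm(sim$counts, tmm_factors(sim$counts))
    smp <- expr$samples
    unt <- smp$treatment == "untreated"
    e <- expression_matrix(expr$values[, smp$sample_id[unt]], smp[unt, ])
    X <- group_design(e$samples)
    ctr <- list(etoh72 = make_contrast(X, "EtOH.untreated.t72",
                                       "EtOH.untreated.t0"))
    mod <- moderate(fit_models(e, X, ctr))
    called <- unlist(call_de(mod$table, lfc_min = 1.5, alpha = 0.05)$etoh72)
    planted <- sprintf("miR-sim-%03d", 1:15)
    recall[s] <- mean(planted %in% called)
    fdr[s] <- if (length(called)) mean(!called %in% planted) else 0
  }
  expect_gte(mean(recall), 0.8)
  expect_lte(mean(fdr), 0.1)
})
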