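test_that("signature overlap reproduces the curated panel arithmetic", {
  sigs <- load_packaged_signatures()
  by_name <- setNames(sigs$signatures,
                      sapply(sigs$signatures, `[[`, "name"))
  ov <- lapply(by_name, signature_overlap, panel = sigs$panel)
  expect_equal(ov$LSEC$n_overlapping, 30)
  expect_equal(ov$LSEC$n_nonoverlapping, 36)
  expect_equal(ov$KC$n_overlapping, 7)
  expect_equal(ov$KC$n_nonoverlapping, 13)
  expect_equal(ov$HSC_up$n_overlapping, 16)
  expect_equal(ov$HSC_down$n_overlapping, 23)
  # empty panel case: everything nonoverlapping
  none <- signature_overlap(by_name$KC, "miR-not-on-panel")
  expect_equal(none$n_overlapping, 0)
  expect_equal(none$n_nonoverlapping, 20)
  # overlap + nonoverlap partitions the signature
  expect_setequal(c(ov$LSEC$overlapping, ov$LSEC$nonoverlapping),
                  normalize_mirna_ids(by_name$LSEC$members))
})

test_that("ranking is deterministic, ordered, and metric-correct", {
  de <- data.frame(mirna_id = c("a", "b", "c"), contrast = "x",
                   log2fc = c(3, 1, 2), t = c(3, 1, 2),
                   p = c(0.001, 0.5, 0.01))
  rk <- rank_mirnas(de, metric = "moderated_t")
  expect_equal(rk$mirna_id, c("a", "c", "b"))
  expect_warning(rank_mirnas(transform(de, t = 1)), "lexicographic")
  # signal-to-noise against the hand formula
  set.seed(61)
  v <- matrix(rnorm(4 * 8), 4, 8, dimnames = list(paste0("miR-", 1:4), NULL))
  labels <- rep(c("g1", "g2"), each = 4)
  e <- toy_expr(v, toy_samples(8))
  rk2 <- rank_mirnas(metric = "signal2noise", expr = e, labels = labels)
  for (i in 1:4) {
    id <- paste0("miR-", i)
    hand <- (mean(v[i, 1:4]) - mean(v[i, 5:8])) /
      (sd(v[i, 1:4]) + sd(v[i, 5:8]))
    expect_equal(rk2$score[rk2$mirna_id == id], hand, tolerance = 1e-12)
  }
  expect_error(rank_mirnas(metric = "signal2noise"), "requires expr")
})

test_that("enrichment score matches construction and the exhaustive oracle", {
  ranked <- data.frame(mirna_id = paste0("miR-t-", 1:100),
                       score = seq(5, -5, length.out = 100))
  # all members at the top, weight 0: ES = 1 by construction
  sig_top <- mirna_signature("top", paste0("miR-t-", 1:10))
  es_top <- enrichment_score(ranked, sig_top, weight_p = 0)
  expect_equal(es_top$es, 1, tolerance = 1e-12)
  expect_setequal(es_top$leading_edge, paste0("miR-t-", 1:10))
  # evenly spaced members in a tie-free list: small |ES|
  sig_even <- mirna_signature("even", paste0("miR-t-", seq(5, 95, by = 10)))
  expect_lt(abs(enrichment_score(ranked, sig_even, weight_p = 0)$es), 0.2)
  # random instances against the step-by-step oracle
  set.seed(63)
  for (i in 1:20) {
    ids <- paste0("miR-o-", sample(100, 20))
    scores <- sort(rnorm(20), decreasing = TRUE)
    members <- sample(ids, 5)
    rk <- data.frame(mirna_id = ids, score = scores)
    for (wp in c(0, 1)) {
      expect_equal(enrichment_score(rk, members, weight_p = wp)$es,
                   oracle_es(ids, scores, members, wp), tolerance = 1e-12)
    }
  }
})

test_that("enrichment score agrees with the reference implementation", {
  skip_if_not_installed("fgsea")
  set.seed(67)
  for (i in 1:10) {
    scores <- sort(rnorm(50), decreasing = TRUE)
    ids <- paste0("miR-f-", 1:50)
    members <- sample(ids, 8)
    got <- enrichment_score(data.frame(mirna_id = ids, score = scores),
                            members, weight_p = 1)$es
    ref <- fgsea::calcGseaStat(setNames(scores, ids),
                               selectedStats = match(members, ids),
                               gseaParam = 1)
    expect_equal(got, ref, tolerance = 1e-10)
  }
})

test_that("degenerate signatures are rejected", {
  rk <- data.frame(mirna_id = paste0("miR-d-", 1:10), score = 10:1)
  expect_error(enrichment_score(rk, paste0("miR-d-", 1:10)), "entire")
  expect_error(enrichment_score(rk, "miR-elsewhere"), "no overlap")
})

test_that("weight-0 ES is invariant to monotone transforms and negates on reversal", {
  set.seed(71)
  ids <- paste0("miR-m-", 1:40)
  scores <- sort(rexp(40), decreasing = TRUE)
  members <- sample(ids, 6)
  rk1 <- data.frame(mirna_id = ids, score = scores)
  rk2 <- data.frame(mirna_id = ids, score = log(scores + 1))  # same order
  e1 <- enrichment_score(rk1, members, weight_p = 0)$es
  expect_equal(enrichment_score(rk2, members, weight_p = 0)$es, e1,
               tolerance = 1e-15)
  rev_rk <- rk1[40:1, ]
  expect_equal(enrichment_score(rev_rk, members, weight_p = 0)$es, -e1,
               tolerance = 1e-15)
})

test_that("permutation GSEA detects planted enrichment deterministically", {
  set.seed(73)
  ranked <- data.frame(mirna_id = paste0("miR-g-", 1:200),
                       score = sort(rnorm(200, sd = 2), decreasing = TRUE))
  sig <- mirna_signature("planted", paste0("miR-g-", 1:10))
  r1 <- gsea(ranked, sig, mode = "gene_set", n_perm = 1000, seed = 99)
  expect_lte(r1$p, 0.01)
  expect_gte(r1$p, 1 / 1001)
  r2 <- gsea(ranked, sig, mode = "gene_set", n_perm = 1000, seed = 99)
  expect_identical(r1[c("es", "nes", "p")], r2[c("es", "nes", "p")])
  expect_error(gsea(ranked, sig, mode = "gene_set", n_perm = 10), "seed")
})

test_that("phenotype mode with few relabelings reports the exact p", {
  set.seed(79)
  v <- matrix(rnorm(30 * 6), 30, 6,
              dimnames = list(paste0("miR-p-", 1:30), NULL))
  e <- toy_expr(v, toy_samples(6))
  sig <- mirna_signature("s", paste0("miR-p-", 1:5))
  labels <- rep(c("a", "b"), each = 3)   # C(6,3) = 20 >= 10: sampled perms
  r <- gsea(sig = sig, mode = "phenotype", n_perm = 50, seed = 3,
            expr = e, labels = labels)
  expect_true(r$p > 0 && r$p <= 1)
  labels2 <- c("a", "a", "b", "b", "b", "b")  # C(6,2) = 15... still >= 10
  labels3 <- c("a", "a", "b", "b")
  e3 <- toy_expr(v[, 1:4], toy_samples(4))
  expect_warning(r3 <- gsea(sig = sig, mode = "phenotype", n_perm = 50,
                            seed = 3, expr = e3, labels = labels3),
                 "exact permutation")
  expect_equal(r3$n_perm, choose(4, 2))
})

test_that("signature derivation applies the FDR filter and top-k rule", {
  set.seed(83)
  de <- data.frame(mirna_id = sprintf("miR-k-%02d", 1:40),
                   log2fc = c(seq(5, 0.2, length.out = 25), rnorm(15, sd = 0.1)),
                   adj_p = c(rep(0.01, 25), rep(0.5, 15)))
  sig <- derive_signature(de, fdr_max = 0.1, top_k = 20)
  expect_length(sig$members, 20)
  expect_setequal(sig$members, sprintf("miR-k-%02d", 1:20))  # largest |FC|
  w <- capture_warnings(empty <- derive_signature(transform(de, adj_p = 0.9)))
  expect_true(any(grepl("no miRNAs pass", w)))
  expect_length(empty$members, 0)
  # hand-ordered toy: membership matches hand selection
  de2 <- data.frame(mirna_id = c("a", "b", "c", "d"),
                    log2fc = c(-3, 1, 2, 0.5), adj_p = c(0.05, 0.05, 0.5, 0.05))
  expect_equal(derive_signature(de2, top_k = 2)$members, c("a", "b"))
})
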