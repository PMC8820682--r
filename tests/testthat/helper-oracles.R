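# Independent brute-force oracles used to check the package's computations.
# Each is written directly from the published formula it checks and shares no
# code with the implementation.

# step-by-step trimmed weighted-mean TMM factor oracle
oracle_tmm <- function(mat, m_trim = 0.30, a_trim = 0.05) {
  lib <- colSums(mat)
  uq <- sapply(seq_len(ncol(mat)), function(j) {
    unname(quantile(mat[, j] / lib[j], 0.75))
  })
  r <- which.min(abs(uq - mean(uq)))
  f <- numeric(ncol(mat))
  for (j in seq_len(ncol(mat))) {
    o <- mat[, j]; rf <- mat[, r]
    keep0 <- o > 0 & rf > 0
    M <- log2((o[keep0] / lib[j]) / (rf[keep0] / lib[r]))
    A <- 0.5 * log2((o[keep0] / lib[j]) * (rf[keep0] / lib[r]))
    w <- (lib[j] - o[keep0]) / (lib[j] * o[keep0]) +
         (lib[r] - rf[keep0]) / (lib[r] * rf[keep0])
    if (length(M) == 0 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
    sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
    f[j] <- 2^(sum(M[sel] / w[sel]) / sum(1 / w[sel]))
  }
  f / exp(mean(log(f)))
}

# Benjamini-Hochberg step-up written from the definition
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- Inf
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Pearson r and two-sided p from the covariance formula and the t CDF
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# exhaustive weighted-KS running-sum evaluation, one element at a time
oracle_es <- function(ids, scores, members, weight_p = 1) {
  N <- length(ids)
  hits <- ids %in% members
  denom_hit <- sum(abs(scores[hits])^weight_p)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hits[i]) {
      run <- run + abs(scores[i])^weight_p / denom_hit
    } else {
      run <- run - 1 / (N - sum(hits))
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# pooled-variance two-sample t from the textbook formula
oracle_pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = tt, df = nx + ny - 2, p = 2 * pt(-abs(tt), nx + ny - 2))
}

# ordinary least squares through explicit normal equations
oracle_ols <- function(X, y) {
  solve(t(X) %*% X) %*% t(X) %*% y
}

# small random count matrix for oracle sweeps
random_count_matrix <- function(n_mir = 20, n_smp = 6, lambda = 50) {
  m <- matrix(rpois(n_mir * n_smp, lambda), n_mir, n_smp,
              dimnames = list(paste0("miR-x-", seq_len(n_mir)),
                              paste0("S", seq_len(n_smp))))
  m
}

# minimal sample table for n samples
toy_samples <- function(n, diets = rep("CHO", n), times = rep(0, n),
                        trt = rep("untreated", n)) {
  data.frame(sample_id = paste0("S", seq_len(n)), diet = diets,
             time_h = times, treatment = trt,
             replicate = ave(seq_len(n),
                             paste(diets, times, trt), FUN = seq_along),
             stringsAsFactors = FALSE)
}

# expression matrix straight from a value matrix
toy_expr <- function(values, samples = NULL) {
  if (is.null(colnames(values))) colnames(values) <- paste0("S", seq_len(ncol(values)))
  if (is.null(rownames(values))) rownames(values) <- paste0("miR-y-", seq_len(nrow(values)))
  if (is.null(samples)) samples <- toy_samples(ncol(values))
  expression_matrix(values, samples)
}

# a null generator configuration: no planted structure at all
null_config <- function(seed, phi = 0, baseline_sd = 1, bio_sd = 0.3) {
  synthetic_config(planted_patterns = list(),
                   pos_corr_ids = character(), neg_corr_ids = character(),
                   dispersion_phi = phi, baseline_sd_log2 = baseline_sd,
                   biological_sd_log2 = bio_sd,
                   am21_knockdown_log2 = 0, seed = seed)
}
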