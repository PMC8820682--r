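#' Trimmed mean of M-values (TMM) scaling factors
#'
#' Between-sample scaling factors per the published TMM definition. The
#' reference sample is the column whose upper quartile of counts-per-million
#' is closest to the mean upper quartile. For every other sample the factor is
#' 2 to the weighted mean of doubly trimmed M-values (log ratios of
#' library-size-scaled counts against the reference), with inverse asymptotic
#' variance weights; genes with a zero in either column are excluded; the
#' factors are rescaled so their geometric mean is 1.
#'
#' @param counts a [count_matrix()] or plain nonnegative matrix.
#' @param m_trim total tail fraction trimmed from each side of the M-values
#'   (default 0.30).
#' @param a_trim tail fraction trimmed from each side of the A-values
#'   (default 0.05).
#' @param ref_column optional explicit reference column index; default is the
#'   upper-quartile rule.
#' @return object of class `norm_factors`: list with `factors` (named, one per
#'   sample, geometric mean 1), `reference_sample`, `m_trim`, `a_trim`.
#' @export
tmm_factors <- function(counts, m_trim = 0.30, a_trim = 0.05,
                        ref_column = NULL) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  if (ncol(m) < 2) stop("TMM requires >= 2 samples")
  lib <- colSums(m)
  if (any(lib <= 0)) stop("library sizes must be > 0")
  if (is.null(ref_column)) {
    f75 <- apply(sweep(m, 2, lib, "/"), 2, stats::quantile, p = 0.75)
    ref_column <- which.min(abs(f75 - mean(f75)))
  }
  f <- vapply(seq_len(ncol(m)), function(j) {
    tmm_pair(m[, j], m[, ref_column], lib[j], lib[ref_column],
             m_trim, a_trim, colnames(m)[j])
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(m)
  structure(list(factors = f,
                 reference_sample = colnames(m)[ref_column],
                 m_trim = m_trim, a_trim = a_trim),
            class = "norm_factors")
}

# one-sample-vs-reference doubly trimmed weighted mean of M-values
tmm_pair <- function(obs, ref, n_obs, n_ref, m_trim, a_trim, label) {
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A)
  if (!any(fin)) {
    warning("sample '", label, "' shares no nonzero genes with the reference; factor set to 1")
    return(1)
  }
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * m_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * a_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Log2 counts-per-million transform
#'
#' \code{value = log2((count + prior) / (library_size * factor + 1) * 1e6)}.
#' Finite everywhere for `prior > 0`.
#'
#' @param counts a [count_matrix()].
#' @param factors a `norm_factors` object (or NULL for factors of 1).
#' @param prior prior count added to every cell (default 0.5).
#' @return an [expression_matrix()] of log2-cpm values.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(inherits(counts, "count_matrix"), prior > 0)
  f <- if (is.null(factors)) rep(1, ncol(counts$counts)) else factors$factors
  eff_lib <- counts$library_size * f
  vals <- log2(sweep(counts$counts + prior, 2, eff_lib + 1, "/") * 1e6)
  expression_matrix(vals, counts$samples)
}

#' Mean-variance precision weights for log2-cpm
#'
#' Fits a per-miRNA linear model to the log2-cpm values, smooths the square
#' root of the residual standard deviation against the average log2 count
#' with lowess, and converts the trend into observation-level inverse-variance
#' weights: the weight is the predicted value to the power -4 at each
#' observation's fitted log2 count, clamped to the range of the trend.
#'
#' @param counts a [count_matrix()].
#' @param factors a `norm_factors` object (or NULL).
#' @param design_matrix full-rank model matrix (rows = samples).
#' @param span lowess span (default 0.5).
#' @param prior prior count for the log-cpm transform.
#' @return an [expression_matrix()] carrying a `weights` matrix.
#' @export
precision_weights <- function(counts, factors = NULL, design_matrix,
                              span = 0.5, prior = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  design_matrix <- as.matrix(design_matrix)
  if (qr(design_matrix)$rank < ncol(design_matrix)) {
    stop("design matrix is not full rank")
  }
  n <- ncol(counts$counts)
  p <- ncol(design_matrix)
  if (n - p < 1) stop("weights require replication (residual df >= 1)")
  expr <- log_cpm(counts, factors, prior)
  y <- expr$values
  f <- if (is.null(factors)) rep(1, n) else factors$factors
  eff_lib <- counts$library_size * f

  fit <- stats::lm.fit(design_matrix, t(y))
  resid_sd <- sqrt(colSums(as.matrix(fit$residuals)^2) / fit$df.residual)
  # average log2 count: mean log-cpm shifted back to the count scale
  sx <- rowMeans(y) + mean(log2(eff_lib + 1)) - log2(1e6)
  sy <- sqrt(resid_sd)
  ok <- resid_sd > 0
  if (sum(ok) < 2) stop("cannot fit a mean-variance trend: no residual variation")
  lo <- stats::lowess(sx[ok], sy[ok], f = span)
  trend <- stats::approxfun(lo$x, lo$y, rule = 2)   # rule 2 clamps to range

  fitted_logcpm <- t(as.matrix(fit$fitted.values))
  fitted_logcount <- sweep(fitted_logcpm, 2, log2(eff_lib + 1) - log2(1e6), "+")
  w <- trend(fitted_logcount)^-4
  w <- matrix(w, nrow(y), n, dimnames = dimnames(y))
  w[!is.finite(w) | w <= 0] <- min(w[is.finite(w) & w > 0])
  expression_matrix(y, counts$samples, weights = w)
}
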