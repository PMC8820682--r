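#' Group-mean design matrix and contrasts
#'
#' One indicator column per (diet, time, treatment) group, in the order the
#' groups appear in the sample table.
#'
#' @param samples sample metadata table.
#' @return model matrix (rows = samples, columns = groups).
#' @export
group_design <- function(samples) {
  g <- factor(paste(samples$diet, samples$treatment,
                    paste0("t", samples$time_h), sep = "."),
              levels = unique(paste(samples$diet, samples$treatment,
                                    paste0("t", samples$time_h), sep = ".")))
  X <- stats::model.matrix(~ 0 + g)
  colnames(X) <- levels(g)
  rownames(X) <- samples$sample_id
  X
}

#' Build a contrast vector over design-matrix columns
#'
#' Average of `plus` columns minus average of `minus` columns.
#'
#' @param design_matrix model matrix whose columns are named.
#' @param plus,minus column names entering with +/- sign.
#' @return named numeric contrast vector.
#' @export
make_contrast <- function(design_matrix, plus, minus = character()) {
  cn <- colnames(design_matrix)
  miss <- setdiff(c(plus, minus), cn)
  if (length(miss)) stop("unknown design column(s): ", paste(miss, collapse = ", "))
  v <- stats::setNames(numeric(length(cn)), cn)
  v[plus] <- 1 / length(plus)
  if (length(minus)) v[minus] <- v[minus] - 1 / length(minus)
  v
}

#' Per-miRNA (weighted) least-squares fits
#'
#' Ordinary or precision-weighted least squares of each miRNA's log2-cpm on
#' the design matrix; contrast log2 fold changes are linear combinations of
#' the coefficients.
#'
#' @param expr an [expression_matrix()] (weights used when present).
#' @param design_matrix full-rank model matrix, rows matching samples.
#' @param contrasts named list of contrast vectors (see [make_contrast()]),
#'   or NULL to keep only coefficients.
#' @return object of class `mirna_fit`: per-miRNA `coefficients`, residual
#'   variance `sigma2`, residual `df`, `amean` (average log2-cpm), and for
#'   each contrast the estimate and its unscaled standard deviation.
#' @export
fit_models <- function(expr, design_matrix, contrasts = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  X <- as.matrix(design_matrix)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("design matrix is rank deficient; aliased column(s): ",
         paste(aliased, collapse = ", "))
  }
  n <- nrow(X); p <- ncol(X)
  if (n <= p) stop("more coefficients than samples")
  y <- expr$values
  G <- nrow(y)
  w <- expr$weights
  coefs <- matrix(NA_real_, G, p, dimnames = list(rownames(y), colnames(X)))
  sigma2 <- numeric(G)
  cov_un <- vector("list", G)   # unscaled covariance (X'WX)^-1 per miRNA
  if (is.null(w)) {
    fit <- stats::lm.fit(X, t(y))
    coefs[] <- t(as.matrix(fit$coefficients))
    res <- as.matrix(fit$residuals)
    sigma2 <- colSums(res^2) / (n - p)
    XtXi <- chol2inv(chol(crossprod(X)))
    cov_un <- rep(list(XtXi), G)
  } else {
    for (g in seq_len(G)) {
      fg <- stats::lm.wfit(X, y[g, ], w[g, ])
      coefs[g, ] <- fg$coefficients
      sigma2[g] <- sum(w[g, ] * fg$residuals^2) / (n - p)
      cov_un[[g]] <- chol2inv(chol(crossprod(X * sqrt(w[g, ]))))
    }
  }
  out <- list(coefficients = coefs, sigma2 = sigma2, df = rep(n - p, G),
              amean = rowMeans(y), design = X)
  if (!is.null(contrasts)) {
    stopifnot(is.list(contrasts), !is.null(names(contrasts)))
    est <- sapply(contrasts, function(cv) drop(coefs %*% cv))
    sdu <- sapply(contrasts, function(cv) {
      vapply(cov_un, function(V) sqrt(drop(t(cv) %*% V %*% cv)), numeric(1))
    })
    out$contrast_est <- matrix(est, G, length(contrasts),
                               dimnames = list(rownames(y), names(contrasts)))
    out$contrast_sdu <- matrix(sdu, G, length(contrasts),
                               dimnames = list(rownames(y), names(contrasts)))
  }
  structure(out, class = "mirna_fit")
}

#' Empirical-Bayes variance moderation and moderated t statistics
#'
#' Estimates a scaled inverse-chi-square prior (prior df d0, prior variance
#' s0^2) for the residual variances by the closed-form moment estimator on
#' log s^2 (digamma/trigamma inversion), forms the posterior variance
#' \code{(d0*s0^2 + d*s^2) / (d0 + d)}, and computes moderated t statistics
#' and two-sided p-values on d0 + d degrees of freedom for every contrast.
#'
#' @param fit a `mirna_fit` with contrasts.
#' @param prior_df optional manual prior df override (0 recovers the ordinary
#'   t exactly; Inf pools completely).
#' @return list with `params` (`d0`, `s02`) and `table`, a data frame with one
#'   row per (miRNA, contrast): `mirna_id`, `contrast`, `log2fc`, `ave_expr`,
#'   `t`, `df_total`, `p`, `adj_p` (BH within contrast).
#' @export
moderate <- function(fit, prior_df = NULL) {
  stopifnot(inherits(fit, "mirna_fit"))
  if (is.null(fit$contrast_est)) stop("fit has no contrasts")
  s2 <- fit$sigma2
  d <- fit$df
  if (all(s2 == 0)) {
    warning("all residual variances are zero; moderation skipped, ordinary t reported")
    d0 <- 0; s02 <- 0
  } else if (!is.null(prior_df)) {
    d0 <- prior_df
    s02 <- if (d0 > 0) mean(s2[s2 > 0]) else 0
  } else {
    mp <- fit_f_dist(s2, d)
    d0 <- mp$d0; s02 <- mp$s02
  }
  post <- if (is.infinite(d0)) {
    rep(s02, length(s2))
  } else {
    (d0 * s02 + d * s2) / (d0 + d)
  }
  df_total <- d0 + d
  tabs <- lapply(colnames(fit$contrast_est), function(cn) {
    est <- fit$contrast_est[, cn]
    se <- sqrt(post) * fit$contrast_sdu[, cn]
    tstat <- est / se
    p <- 2 * stats::pt(-abs(tstat), df_total)
    p[se == 0] <- ifelse(est[se == 0] == 0, 1, 0)
    data.frame(mirna_id = rownames(fit$contrast_est), contrast = cn,
               log2fc = est, ave_expr = fit$amean, t = tstat,
               df_total = df_total, p = p, adj_p = adjust_bh(p),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  table <- do.call(rbind, tabs)
  list(params = list(d0 = d0, s02 = s02, posterior_var = post), table = table)
}

# moment estimator of the scaled-F prior on residual variances
fit_f_dist <- function(s2, d) {
  ok <- s2 > 0 & d > 0
  if (sum(ok) < 2) stop("moderation requires >= 2 miRNAs with positive variance")
  z <- log(s2[ok])
  dk <- d[ok]
  e <- z - digamma(dk / 2) + log(dk / 2)
  emean <- mean(e)
  evar <- sum((e - emean)^2) / (length(e) - 1) - mean(trigamma(dk / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- mean(s2[ok])
  }
  list(d0 = d0, s02 = s02)
}

# Newton inversion of the trigamma function
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Benjamini-Hochberg adjustment
#'
#' Validating wrapper around the standard step-up procedure.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted p-values (monotone, <= 1).
#' @export
adjust_bh <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call differentially expressed miRNAs
#'
#' up = log2FC >= `lfc_min` and adjusted p <= `alpha`; down symmetric with
#' -`lfc_min`. Boundary equality is included. With `fc_only = TRUE` the
#' p-value condition is dropped (fold-change-only rule).
#'
#' @param de moderated result table (from [moderate()]`$table`).
#' @param lfc_min absolute log2-fold-change threshold (default 1.5).
#' @param alpha BH-adjusted p threshold (default 0.05).
#' @param fc_only ignore the p-value condition.
#' @return named list per contrast with `up` and `down` miRNA id vectors.
#' @export
call_de <- function(de, lfc_min = 1.5, alpha = 0.05, fc_only = FALSE) {
  stopifnot(lfc_min >= 0, alpha >= 0)
  sig <- if (fc_only) rep(TRUE, nrow(de)) else de$adj_p <= alpha
  out <- lapply(split(seq_len(nrow(de)), de$contrast), function(idx) {
    d <- de[idx, ]
    s <- sig[idx]
    list(up = d$mirna_id[d$log2fc >= lfc_min & s],
         down = d$mirna_id[d$log2fc <= -lfc_min & s])
  })
  out[unique(de$contrast)]
}
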