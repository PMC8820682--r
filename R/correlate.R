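#' Pearson correlation screen against a reference miRNA
#'
#' Sample Pearson correlation of every miRNA's log2-cpm with the reference
#' miRNA (miR-21 in the study design) across a sample subset, with two-sided
#' p-values from \code{t = r * sqrt((n - 2) / (1 - r^2))} on n - 2 degrees of
#' freedom. Zero-variance miRNAs have undefined r: they are flagged and
#' excluded from the BH adjustment.
#'
#' @param expr an [expression_matrix()].
#' @param ref_id reference miRNA id (must be a row of `expr`).
#' @param sample_subset sample ids to use (default: all samples).
#' @return data frame of class `correlation_screen`: `mirna_id`, `r`, `n`,
#'   `p`, `adj_p`, `degenerate` (logical). The reference is excluded from its
#'   own screen.
#' @export
correlate_to_reference <- function(expr, ref_id, sample_subset = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!ref_id %in% rownames(expr$values)) {
    stop("reference miRNA '", ref_id, "' not found in expression matrix")
  }
  ids <- if (is.null(sample_subset)) expr$samples$sample_id else sample_subset
  stopifnot(all(ids %in% expr$samples$sample_id))
  if (length(ids) < 3) stop("correlation screen requires >= 3 samples")
  v <- expr$values[, ids, drop = FALSE]
  ref <- v[ref_id, ]
  if (stats::sd(ref) == 0) stop("reference miRNA has zero variance in the subset")
  others <- setdiff(rownames(v), ref_id)
  n <- length(ids)
  sds <- apply(v[others, , drop = FALSE], 1, stats::sd)
  r <- rep(NA_real_, length(others))
  ok <- sds > 0
  r[ok] <- drop(stats::cor(t(v[others[ok], , drop = FALSE]), ref))
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), n - 2)
  adj <- rep(NA_real_, length(others))
  adj[ok] <- adjust_bh(p[ok])
  structure(data.frame(mirna_id = others, r = r, n = n, p = p, adj_p = adj,
                       degenerate = !ok, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("correlation_screen", "data.frame"),
            reference = ref_id)
}

#' Significant positive and negative correlation partners
#'
#' pos = \{r > 0, p < alpha\}, neg = \{r < 0, p < alpha\}. The headline rule
#' uses the raw p-value at 0.05 (as the screen was defined); set
#' `use_adjusted = TRUE` for the BH-adjusted variant. The two lists are
#' always disjoint.
#'
#' @param res a [correlate_to_reference()] result.
#' @param alpha significance level in (0, 1].
#' @param use_adjusted use BH-adjusted p instead of raw p.
#' @return list with `pos` and `neg` miRNA id vectors.
#' @export
significant_partners <- function(res, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(alpha > 0, alpha <= 1)
  if (nrow(res) == 0) return(list(pos = character(), neg = character()))
  p <- if (use_adjusted) res$adj_p else res$p
  ok <- !res$degenerate & !is.na(p)
  list(pos = res$mirna_id[ok & res$r > 0 & p < alpha],
       neg = res$mirna_id[ok & res$r < 0 & p < alpha])
}

#' Full pairwise Pearson correlation matrix
#'
#' @param expr an [expression_matrix()].
#' @param sample_subset sample ids to use (default all; >= 3 required).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
pairwise_matrix <- function(expr, sample_subset = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  ids <- if (is.null(sample_subset)) expr$samples$sample_id else sample_subset
  if (length(ids) < 3) stop("pairwise correlation requires >= 3 samples")
  stats::cor(t(expr$values[, ids, drop = FALSE]))
}
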