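#' Overlap of a signature with an assay panel
#'
#' Set intersection under the identifier-normalization policy of
#' [normalize_mirna_ids()]. Overlapping and nonoverlapping members partition
#' the signature.
#'
#' @param sig a [mirna_signature()].
#' @param panel character vector of panel miRNA ids (nonempty).
#' @return list with `overlapping`, `nonoverlapping`, `n_overlapping`,
#'   `n_nonoverlapping`.
#' @export
signature_overlap <- function(sig, panel) {
  stopifnot(inherits(sig, "mirna_signature"), length(panel) > 0)
  members <- normalize_mirna_ids(sig$members)
  npanel <- normalize_mirna_ids(panel)
  ov <- members[members %in% npanel]
  nov <- members[!members %in% npanel]
  list(overlapping = ov, nonoverlapping = nov,
       n_overlapping = length(ov), n_nonoverlapping = length(nov))
}

#' Rank miRNAs for enrichment analysis
#'
#' Builds the ranked list from a moderated DE table (metrics `moderated_t`,
#' `signed_logp`, `log2fc`) or from an expression matrix with a two-group
#' label vector (`signal2noise`, \eqn{(\mu_1 - \mu_2)/(\sigma_1 + \sigma_2)}).
#' Descending order; ties broken by lexicographic id order so the ranking is
#' deterministic.
#'
#' @param de moderated DE table restricted to one contrast (or NULL).
#' @param metric ranking metric.
#' @param expr an [expression_matrix()] (signal2noise only).
#' @param labels two-level sample label vector aligned to `expr` samples
#'   (signal2noise only).
#' @return data frame `mirna_id`, `score`, sorted by decreasing score.
#' @export
rank_mirnas <- function(de = NULL,
                        metric = c("moderated_t", "signed_logp", "log2fc",
                                   "signal2noise"),
                        expr = NULL, labels = NULL) {
  metric <- match.arg(metric)
  if (metric == "signal2noise") {
    if (is.null(expr) || is.null(labels)) {
      stop("metric 'signal2noise' requires expr and labels")
    }
    score <- signal2noise(expr$values, labels)
    ids <- rownames(expr$values)
  } else {
    if (is.null(de)) stop("metric '", metric, "' requires a DE table")
    if (length(unique(de$contrast)) > 1) {
      stop("DE table spans several contrasts; subset to one first")
    }
    ids <- de$mirna_id
    score <- switch(metric,
      moderated_t = de$t,
      signed_logp = sign(de$log2fc) * -log10(pmax(de$p, .Machine$double.xmin)),
      log2fc = de$log2fc)
  }
  if (length(unique(score)) == 1L) {
    warning("all ranking scores equal; order is lexicographic by id")
  }
  ord <- order(-score, ids)
  data.frame(mirna_id = ids[ord], score = score[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

signal2noise <- function(values, labels) {
  lv <- unique(labels)
  if (length(lv) != 2) stop("signal2noise requires exactly two groups")
  a <- values[, labels == lv[1], drop = FALSE]
  b <- values[, labels == lv[2], drop = FALSE]
  (rowMeans(a) - rowMeans(b)) /
    (apply(a, 1, stats::sd) + apply(b, 1, stats::sd))
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' The canonical running-sum statistic over a ranked list: at each signature
#' hit the sum increments by \code{|score|^weight_p / sum(|score|^weight_p)}
#' over hits, at each miss it decrements by \code{1 / (N - |S|)}. The
#' enrichment score is the extremum by absolute value; the leading edge is
#' the set of hits at or before the extremum for positive ES, at or after it
#' for negative ES.
#'
#' @param ranked ranked data frame from [rank_mirnas()] (columns `mirna_id`,
#'   `score`).
#' @param sig a [mirna_signature()] or character vector of member ids.
#' @param weight_p score weighting exponent (default 1; 0 gives the classic
#'   unweighted KS statistic).
#' @return list with `es`, `running` (the running-sum vector), and
#'   `leading_edge` (miRNA ids).
#' @export
enrichment_score <- function(ranked, sig, weight_p = 1) {
  members <- if (inherits(sig, "mirna_signature")) sig$members else sig
  members <- normalize_mirna_ids(members)
  ids <- normalize_mirna_ids(ranked$mirna_id)
  hit <- ids %in% members
  n_hit <- sum(hit)
  N <- length(ids)
  if (n_hit == 0) {
    stop("signature has no overlap with the ranked list (0 of ",
         length(members), " members present)")
  }
  if (n_hit == N) stop("signature covers the entire ranked list")
  w <- abs(ranked$score)^weight_p
  running <- cumsum(ks_increments(w, hit))
  i_ext <- which.max(abs(running))
  es <- running[i_ext]
  le <- if (es >= 0) ranked$mirna_id[hit & seq_len(N) <= i_ext]
        else ranked$mirna_id[hit & seq_len(N) >= i_ext]
  list(es = es, running = running, leading_edge = le)
}

#' Permutation GSEA of a miRNA signature
#'
#' Computes the observed weighted-KS enrichment score and a permutation null:
#' `gene_set` mode redraws the signature uniformly from the panel,
#' `phenotype` mode permutes the two-group sample labels and re-ranks with
#' the given metric. The nominal p-value follows the canonical sign-stratified
#' rule, \code{(1 + #(|ES_perm| >= |ES_obs|, same sign)) / (1 + #(same
#' sign))}, so it is approximately uniform under the null, and
#' NES = ES / mean(|same-sign permuted ES|). Deterministic given `seed`.
#'
#' With fewer than 10 distinct label permutations available, phenotype mode
#' warns and reports the exact-permutation p over all distinct relabelings.
#'
#' @param ranked ranked list (gene_set mode) from [rank_mirnas()].
#' @param sig a [mirna_signature()].
#' @param mode permutation mode.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed (required).
#' @param weight_p score weighting exponent.
#' @param expr,labels,metric inputs for phenotype mode re-ranking.
#' @return list of class `enrichment_result`: `signature`, `es`, `nes`, `p`,
#'   `mode`, `n_perm`, `seed`, `leading_edge`, `overlap` (panel overlap
#'   report).
#' @export
gsea <- function(ranked = NULL, sig, mode = c("gene_set", "phenotype"),
                 n_perm = 1000, seed, weight_p = 1,
                 expr = NULL, labels = NULL, metric = "signal2noise") {
  mode <- match.arg(mode)
  if (missing(seed)) stop("seed is required")
  set.seed(as.integer(seed))
  if (mode == "gene_set") {
    stopifnot(!is.null(ranked))
    obs <- enrichment_score(ranked, sig, weight_p)
    N <- nrow(ranked)
    k <- sum(normalize_mirna_ids(ranked$mirna_id) %in%
               normalize_mirna_ids(sig$members))
    w <- abs(ranked$score)^weight_p
    perm_es <- vapply(seq_len(n_perm), function(i) {
      hit <- logical(N)
      hit[sample.int(N, k)] <- TRUE
      es_kernel(w, hit)
    }, numeric(1))
  } else {
    if (is.null(expr) || is.null(labels)) {
      stop("phenotype mode requires expr and labels")
    }
    lv <- unique(labels)
    if (length(lv) != 2 || min(table(labels)) < 2) {
      stop("phenotype mode requires two groups with >= 2 samples each")
    }
    ranked <- rank_mirnas(metric = metric, expr = expr, labels = labels)
    obs <- enrichment_score(ranked, sig, weight_p)
    n1 <- sum(labels == lv[1])
    n_distinct <- choose(length(labels), n1)
    if (n_distinct < 10) {
      warning("fewer than 10 distinct label permutations; reporting the exact permutation p")
      combs <- utils::combn(seq_along(labels), n1)
      perm_es <- apply(combs, 2, function(idx) {
        pl <- rep(lv[2], length(labels)); pl[idx] <- lv[1]
        rk <- rank_mirnas(metric = metric, expr = expr, labels = pl)
        enrichment_score(rk, sig, weight_p)$es
      })
      n_perm <- length(perm_es)
      same <- perm_es[sign(perm_es) == sign(obs$es)]
      p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
      nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
      return(enrichment_result(sig, obs, nes, p, mode, n_perm, seed))
    }
    perm_es <- vapply(seq_len(n_perm), function(i) {
      pl <- sample(labels)
      rk <- rank_mirnas(metric = metric, expr = expr, labels = pl)
      enrichment_score(rk, sig, weight_p)$es
    }, numeric(1))
  }
  same <- perm_es[sign(perm_es) == sign(obs$es)]
  p <- (1 + sum(abs(same) >= abs(obs$es))) / (1 + length(same))
  nes <- if (length(same)) obs$es / mean(abs(same)) else NA_real_
  enrichment_result(sig, obs, nes, p, mode, n_perm, seed)
}

ks_increments <- function(w, hit) {
  inc <- numeric(length(w))
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (length(w) - sum(hit))
  inc
}

# running-sum extremum without id bookkeeping (permutation inner loop)
es_kernel <- function(w, hit) {
  running <- cumsum(ks_increments(w, hit))
  running[which.max(abs(running))]
}

enrichment_result <- function(sig, obs, nes, p, mode, n_perm, seed) {
  structure(list(signature = sig$name, es = obs$es, nes = nes, p = p,
                 mode = mode, n_perm = n_perm, seed = seed,
                 leading_edge = obs$leading_edge),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("GSEA %s: ES = %.3f, NES = %.3f, p = %.4g (%s, %d perms)\n",
              x$signature, x$es, x$nes, x$p, x$mode, x$n_perm))
  invisible(x)
}

#' Derive a signature from a differential-expression table
#'
#' Members are the miRNAs passing the FDR filter (adjusted p < `fdr_max`),
#' ranked by |log2FC| and truncated to the `top_k` largest — the rule used to
#' build the Kupffer-cell post-hepatectomy signature.
#'
#' @param de moderated DE table for one contrast (columns `mirna_id`,
#'   `log2fc`, `adj_p`).
#' @param fdr_max FDR threshold (default 0.1).
#' @param top_k maximum signature size (default 20).
#' @param name signature name.
#' @param cell_type,direction signature annotations.
#' @return a [mirna_signature()] (possibly smaller than `top_k`, with a
#'   warning if nothing passes the filter).
#' @export
derive_signature <- function(de, fdr_max = 0.1, top_k = 20,
                             name = "derived", cell_type = "other",
                             direction = "enriched") {
  stopifnot(all(c("mirna_id", "log2fc", "adj_p") %in% names(de)))
  pass <- de[de$adj_p < fdr_max, ]
  pass <- pass[order(-abs(pass$log2fc), pass$mirna_id), ]
  members <- utils::head(pass$mirna_id, top_k)
  if (length(members) == 0) {
    warning("no miRNAs pass the FDR filter; empty signature")
  }
  mirna_signature(name = name, members = members, cell_type = cell_type,
                  direction = direction,
                  description = sprintf("adj_p<%g, top %d |log2FC|", fdr_max, top_k))
}
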