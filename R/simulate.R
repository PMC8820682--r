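#' Generate NanoString-like synthetic miRNA counts with ground truth
#'
#' Counts follow a gamma-Poisson (negative-binomial) law with
#' variance \eqn{\mu + \phi\mu^2}. The expected count of miRNA i in sample s
#' is \code{lib_s * p_i * 2^(planted log2 effect for that diet/time/treatment)}
#' where p_i is the baseline panel proportion. Correlated miRNAs share a
#' per-sample latent Gaussian factor with the reference miRNA (positive
#' loading for the positive class, negative for the negative class); the AM21
#' arm applies a fixed log2 knockdown to the reference that propagates to the
#' partners through the same factor. The whole draw is deterministic given
#' `cfg$seed`.
#'
#' @param design a [study_design()].
#' @param cfg a [synthetic_config()].
#' @return list with `counts` (a [count_matrix()]) and `truth`, the recorded
#'   ground truth: `pattern_by_mirna_diet` (planted discretized pattern per
#'   miRNA per diet), `corr_class` (pos/neg/null per non-reference miRNA),
#'   `de_effects` (planted log2 fold change per miRNA, diet, time), and the
#'   reference id.
#' @export
generate_counts <- function(design = study_design(), cfg = synthetic_config()) {
  stopifnot(inherits(design, "study_design"), inherits(cfg, "synthetic_config"))
  samples <- generate_design(design)
  panel <- panel_ids(design, cfg)
  n_mir <- length(panel)
  n_smp <- nrow(samples)

  set.seed(cfg$seed)
  # 1. baseline abundances (log2 scale); planted miRNAs sit mid-to-high
  b <- stats::rnorm(n_mir, cfg$baseline_mean_log2, cfg$baseline_sd_log2)
  names(b) <- panel
  planted_ids <- vapply(cfg$planted_patterns, `[[`, "", "mirna")
  special <- unique(c(planted_ids, cfg$reference_mirna,
                      cfg$pos_corr_ids, cfg$neg_corr_ids))
  b[special] <- cfg$baseline_mean_log2 + 1 +
    stats::rnorm(length(special), 0, 0.25)
  p_i <- 2^b / sum(2^b)

  # 2. library sizes
  lib <- round(stats::runif(n_smp, cfg$library_size_range[1],
                            cfg$library_size_range[2]))

  # 3. latent factor and idiosyncratic noise
  z0 <- stats::rnorm(n_smp)
  eps <- matrix(stats::rnorm(n_mir * n_smp), n_mir, n_smp)
  lambda <- numeric(n_mir)
  names(lambda) <- panel
  lambda[cfg$reference_mirna] <- 1
  lambda[cfg$pos_corr_ids] <- cfg$corr_strength
  lambda[cfg$neg_corr_ids] <- -cfg$corr_strength
  am21 <- as.numeric(samples$treatment == "AM21")
  # deterministic AM21 pull on the latent axis + stochastic part
  latent <- outer(lambda, -cfg$am21_knockdown_log2 * am21) +
    cfg$biological_sd_log2 *
      (outer(lambda, z0) + sqrt(1 - lambda^2) * eps)

  # 4. planted diet/time effects
  delta <- planted_effect_matrix(panel, samples, design, cfg)

  mu <- (lib[col(delta)] * p_i[row(delta)]) * 2^(delta + latent)

  # 5. gamma-Poisson draw
  phi <- cfg$dispersion_phi
  rate <- if (phi > 0) {
    stats::rgamma(length(mu), shape = 1 / phi, scale = phi * mu)
  } else {
    mu
  }
  counts <- matrix(stats::rpois(length(mu), rate), n_mir, n_smp,
                   dimnames = list(panel, samples$sample_id))

  truth <- ground_truth(panel, design, cfg)
  list(counts = count_matrix(counts, samples), truth = truth)
}

# panel id universe: planted + reference/partners + packaged pseudo-panel,
# padded with synthetic filler ids up to panel_size
panel_ids <- function(design, cfg) {
  planted <- vapply(cfg$planted_patterns, `[[`, "", "mirna")
  base <- unique(c(planted, cfg$reference_mirna,
                   cfg$pos_corr_ids, cfg$neg_corr_ids))
  pp <- system.file("extdata", "pseudo_panel.txt", package = "regenmir")
  if (nzchar(pp)) base <- unique(c(base, readLines(pp)))
  if (design$panel_size < length(base)) {
    stop(sprintf("panel_size (%d) smaller than the %d planted/named miRNAs",
                 design$panel_size, length(base)))
  }
  n_fill <- design$panel_size - length(base)
  fill <- setdiff(sprintf("miR-bg-%04d", seq_len(n_fill + length(base))), base)
  c(base, fill[seq_len(n_fill)])
}

# planted log2 effect per (miRNA, sample); baseline time has effect 0
planted_effect_matrix <- function(panel, samples, design, cfg) {
  delta <- matrix(0, length(panel), nrow(samples),
                  dimnames = list(panel, samples$sample_id))
  nb_times <- design$times_h[-1]
  for (p in cfg$planted_patterns) {
    if (!p$mirna %in% panel) next
    for (diet in names(p$pattern)) {
      pat <- p$pattern[[diet]]
      stopifnot(length(pat) == length(nb_times))
      for (k in seq_along(nb_times)) {
        sel <- samples$diet == diet & samples$time_h == nb_times[k]
        delta[p$mirna, sel] <- pat[k] * p$delta
      }
    }
  }
  delta
}

ground_truth <- function(panel, design, cfg) {
  nb_times <- design$times_h[-1]
  code <- c("D", "0", "U")
  pats <- do.call(rbind, lapply(cfg$planted_patterns, function(p) {
    do.call(rbind, lapply(names(p$pattern), function(diet) {
      data.frame(mirna = p$mirna, diet = diet,
                 pattern = paste(code[p$pattern[[diet]] + 2L], collapse = ""),
                 delta = p$delta, stringsAsFactors = FALSE)
    }))
  }))
  de <- do.call(rbind, lapply(cfg$planted_patterns, function(p) {
    do.call(rbind, lapply(names(p$pattern), function(diet) {
      data.frame(mirna = p$mirna, diet = diet, time_h = nb_times,
                 log2fc = p$pattern[[diet]] * p$delta,
                 stringsAsFactors = FALSE)
    }))
  }))
  corr <- rep("null", length(panel))
  names(corr) <- panel
  corr[cfg$pos_corr_ids] <- "pos"
  corr[cfg$neg_corr_ids] <- "neg"
  corr <- corr[names(corr) != cfg$reference_mirna]
  list(pattern_by_mirna_diet = pats, corr_class = corr, de_effects = de,
       reference_mirna = cfg$reference_mirna, config = cfg)
}

#' Generate a synthetic qPCR CT table
#'
#' CT values are drawn as \code{base CT - planted log2 effect + noise}: a
#' planted log2 change of +x lowers the mean target CT by x cycles relative
#' to the control (first) group. Reference miRNAs must have no planted effect
#' in any group — they are the endogenous normalizers.
#'
#' @param groups group labels; the first is the control.
#' @param effects_log2 numeric matrix of planted log2 changes,
#'   rows = target ids, columns = group labels (0 for the control column).
#' @param ref_mirnas endogenous reference miRNA ids (>= 1, conventionally 3).
#' @param n_reps replicates per (group, target).
#' @param ct_noise_sd CT measurement noise SD, cycles (>= 0).
#' @param seed integer seed.
#' @return `qpcr_table` data frame (`group`, `target`, `replicate`, `ct`).
#' @export
generate_qpcr <- function(groups,
                          effects_log2,
                          ref_mirnas = c("hsa-miR-99b-5p", "hsa-miR-23a-3p",
                                         "hsa-miR-100-5p"),
                          n_reps = 4,
                          ct_noise_sd = 0.2,
                          seed = 1L) {
  if (ct_noise_sd < 0) stop("ct_noise_sd must be >= 0")
  if (length(ref_mirnas) < 1) stop("at least one reference miRNA required")
  effects_log2 <- as.matrix(effects_log2)
  if (is.null(colnames(effects_log2))) colnames(effects_log2) <- groups
  stopifnot(all(colnames(effects_log2) %in% groups))
  bad_ref <- intersect(rownames(effects_log2)[rowSums(effects_log2 != 0) > 0],
                       ref_mirnas)
  if (length(bad_ref)) {
    stop("reference miRNA(s) with a planted effect: ",
         paste(bad_ref, collapse = ", "))
  }
  targets <- unique(c(rownames(effects_log2), ref_mirnas))
  set.seed(as.integer(seed))
  base_ct <- stats::runif(length(targets), 22, 28)
  names(base_ct) <- targets
  base_ct[ref_mirnas] <- seq(19, 21, length.out = length(ref_mirnas))
  rows <- expand.grid(replicate = seq_len(n_reps), target = targets,
                      group = groups, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("group", "target", "replicate")]
  eff <- mapply(function(tg, gr) {
    if (tg %in% rownames(effects_log2) && gr %in% colnames(effects_log2)) {
      effects_log2[tg, gr]
    } else 0
  }, rows$target, rows$group)
  rows$ct <- base_ct[rows$target] - eff +
    stats::rnorm(nrow(rows), 0, ct_noise_sd)
  rownames(rows) <- NULL
  validate_qpcr(rows)
}
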