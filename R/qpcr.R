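#' Per-replicate delta-CT normalization
#'
#' For every (group, target, replicate) well, \code{dCT = CT_target - mean(CT
#' of the reference miRNAs in the same group and replicate)}. The arithmetic
#' mean of reference CTs is equivalent to geometric-mean normalization in
#' linear expression space.
#'
#' @param table a `qpcr_table` (columns `group`, `target`, `replicate`, `ct`).
#' @param ref_targets one or more endogenous reference miRNA ids.
#' @return data frame `group`, `target`, `replicate`, `dct` (reference
#'   targets excluded).
#' @export
delta_ct <- function(table, ref_targets) {
  table <- validate_qpcr(table)
  stopifnot(length(ref_targets) >= 1)
  miss_ref <- setdiff(ref_targets, table$target)
  if (length(miss_ref)) stop("reference target(s) absent: ",
                             paste(miss_ref, collapse = ", "))
  key <- paste(table$group, table$replicate, sep = "\r")
  out <- lapply(unique(key), function(k) {
    wells <- table[key == k, ]
    refs <- wells[wells$target %in% ref_targets, ]
    if (!setequal(refs$target, ref_targets)) {
      m <- setdiff(ref_targets, refs$target)
      stop(sprintf("missing reference well: group '%s', replicate %s, ref '%s'",
                   wells$group[1], wells$replicate[1], m[1]))
    }
    ref_mean <- mean(refs$ct)
    tg <- wells[!wells$target %in% ref_targets, , drop = FALSE]
    if (nrow(tg) == 0) return(NULL)
    data.frame(group = tg$group, target = tg$target, replicate = tg$replicate,
               dct = tg$ct - ref_mean, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Delta-delta-CT fold changes against a control group
#'
#' Per (target, group): \code{ddCT = mean dCT(group) - mean dCT(control)} and
#' relative fold change \code{2^(-ddCT)}; the control group's own fold change
#' is exactly 1. The fold-change standard error is propagated from the dCT
#' scale by the delta method; the p-value is the unpaired two-sample t-test
#' of the group's dCT replicates against the control's (see [group_ttest()]).
#'
#' @param dct a [delta_ct()] table.
#' @param control_group label of the control group.
#' @param welch use Welch's t instead of pooled-variance Student's t.
#' @return data frame per (target, group): `n`, `mean_dct`, `se_dct`, `ddct`,
#'   `fold_change`, `se_fold_change`, `p`, `stars`.
#' @export
ddct_fold_change <- function(dct, control_group, welch = FALSE) {
  if (!control_group %in% dct$group) {
    stop("control group '", control_group, "' not present")
  }
  rows <- list()
  for (tg in unique(dct$target)) {
    d <- dct[dct$target == tg, ]
    ctrl <- d$dct[d$group == control_group]
    if (length(ctrl) == 0) stop("control group missing for target ", tg)
    for (gr in unique(d$group)) {
      x <- d$dct[d$group == gr]
      n <- length(x)
      se <- if (n > 1) stats::sd(x) / sqrt(n) else NA_real_
      if (gr == control_group) {
        ddct <- 0
        se_dd <- se
        p <- NA_real_
      } else {
        ddct <- mean(x) - mean(ctrl)
        se_c <- if (length(ctrl) > 1) stats::sd(ctrl) / sqrt(length(ctrl)) else NA_real_
        se_dd <- sqrt(se^2 + se_c^2)
        p <- if (n >= 2 && length(ctrl) >= 2) {
          group_ttest(d, gr, control_group, welch = welch)$p
        } else NA_real_
      }
      fc <- 2^(-ddct)
      rows[[length(rows) + 1L]] <- data.frame(
        target = tg, group = gr, n = n, mean_dct = mean(x), se_dct = se,
        ddct = ddct, fold_change = fc,
        se_fold_change = fc * log(2) * se_dd,
        p = p, stars = p_stars(p), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

p_stars <- function(p) {
  vapply(p, function(x) {
    if (is.na(x)) "" else if (x < 1e-4) "****" else if (x < 1e-3) "***"
    else if (x < 1e-2) "**" else if (x < 0.05) "*" else "ns"
  }, "")
}

#' Unpaired two-sample t-test on delta-CT replicates
#'
#' Student's pooled-variance t by default (the conventional unpaired test),
#' Welch optional. With zero variance in both groups and equal means the test
#' is degenerate: p = 1 is reported with a flag.
#'
#' @param dct a [delta_ct()] table for a single target (or containing one).
#' @param group_a,group_b group labels.
#' @param welch use Welch's unequal-variance t.
#' @return list `t`, `df`, `p`, `degenerate`.
#' @export
group_ttest <- function(dct, group_a, group_b, welch = FALSE) {
  if (length(unique(dct$target)) > 1) {
    stop("dct table spans several targets; subset to one first")
  }
  x <- dct$dct[dct$group == group_a]
  y <- dct$dct[dct$group == group_b]
  if (length(x) < 2 || length(y) < 2) stop("t-test requires n >= 2 per group")
  if (stats::sd(x) == 0 && stats::sd(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2, p = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, var.equal = !welch)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, degenerate = FALSE)
}
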