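#' Log2 fold changes of each time point against baseline, per condition
#'
#' For each level of the conditioning variable (default diet), the log2 fold
#' change of every miRNA at each non-baseline time is the mean log2-cpm over
#' replicates at that (condition, time) minus the mean over replicates at the
#' condition's baseline.
#'
#' @param expr an [expression_matrix()].
#' @param baseline_time baseline time in hours (default 0).
#' @param condition sample-table column defining the conditions (default
#'   "diet").
#' @param treatment restrict to this treatment arm (default "untreated";
#'   NULL keeps all samples).
#' @return object of class `fold_change_cube`: 3-d array
#'   (miRNA x time x condition) of log2 fold changes plus axis metadata.
#' @export
fold_change_vs_baseline <- function(expr, baseline_time = 0,
                                    condition = "diet",
                                    treatment = "untreated") {
  stopifnot(inherits(expr, "expression_matrix"))
  smp <- expr$samples
  keep <- if (is.null(treatment)) rep(TRUE, nrow(smp)) else smp$treatment == treatment
  smp <- smp[keep, , drop = FALSE]
  vals <- expr$values[, smp$sample_id, drop = FALSE]
  conds <- unique(smp[[condition]])
  times <- sort(unique(smp$time_h))
  if (!baseline_time %in% times) stop("no samples at baseline time ", baseline_time)
  nb_times <- setdiff(times, baseline_time)
  fc <- array(NA_real_,
              dim = c(nrow(vals), length(nb_times), length(conds)),
              dimnames = list(rownames(vals), paste0("t", nb_times), conds))
  for (cv in conds) {
    base_sel <- smp[[condition]] == cv & smp$time_h == baseline_time
    if (!any(base_sel)) stop(sprintf("missing cell: (%s, t=%g)", cv, baseline_time))
    base_mean <- rowMeans(vals[, base_sel, drop = FALSE])
    for (k in seq_along(nb_times)) {
      sel <- smp[[condition]] == cv & smp$time_h == nb_times[k]
      if (!any(sel)) stop(sprintf("missing cell: (%s, t=%g)", cv, nb_times[k]))
      fc[, k, cv] <- rowMeans(vals[, sel, drop = FALSE]) - base_mean
    }
  }
  structure(list(fc = fc, baseline_time = baseline_time,
                 times_h = nb_times, conditions = conds,
                 aggregation = "mean log2-cpm over replicates"),
            class = "fold_change_cube")
}

#' Discretize fold-change trajectories into pattern codes
#'
#' Per condition, each miRNA's trajectory is encoded over \{D, 0, U\}:
#' log2FC >= `tau` is U, <= -`tau` is D, otherwise 0. Equality at the
#' threshold counts as regulated.
#'
#' @param cube a [fold_change_vs_baseline()] result.
#' @param tau discretization threshold in log2 units (> 0; default 1.5).
#' @return character matrix of pattern codes (rows = miRNAs,
#'   columns = conditions).
#' @export
discretize <- function(cube, tau = 1.5) {
  stopifnot(inherits(cube, "fold_change_cube"), tau > 0)
  cols <- lapply(cube$conditions, function(cv) {
    m <- cube$fc[, , cv, drop = FALSE]
    dim(m) <- dim(cube$fc)[1:2]
    codes <- matrix("0", nrow(m), ncol(m))
    codes[m >= tau] <- "U"
    codes[m <= -tau] <- "D"
    apply(codes, 1, paste, collapse = "")
  })
  matrix(unlist(cols), ncol = length(cube$conditions),
         dimnames = list(dimnames(cube$fc)[[1]], cube$conditions))
}

#' Enumerate all pattern codes of a given length
#'
#' Canonical order: positions vary fastest on the right, alphabet D < 0 < U.
#'
#' @param n_times number of non-baseline time points.
#' @return character vector of 3^n_times codes.
#' @export
all_patterns <- function(n_times) {
  g <- do.call(expand.grid, c(rep(list(c("D", "0", "U")), n_times),
                              list(stringsAsFactors = FALSE)))
  g <- g[, rev(seq_len(n_times)), drop = FALSE]  # expand.grid varies col 1 fastest
  apply(g, 1, paste, collapse = "")
}

#' COMPACT pattern-count matrix between two conditions
#'
#' Counts miRNAs by their joint (pattern in condition A, pattern in condition
#' B) and records the membership of every cell. The cell counts sum to the
#' number of miRNAs analyzed, and membership lists form a partition of the
#' input universe.
#'
#' @param patterns_a,patterns_b named character vectors of pattern codes over
#'   the same miRNA universe (e.g. columns of [discretize()]).
#' @param condition_names length-2 labels for the two conditions.
#' @return object of class `compact_result`: `counts` (3^T x 3^T integer
#'   matrix, rows = condition A patterns), `membership` (named list,
#'   "rowcode|colcode" -> miRNA ids), `conditions`.
#' @export
pattern_counts <- function(patterns_a, patterns_b,
                           condition_names = c("A", "B")) {
  ua <- names(patterns_a); ub <- names(patterns_b)
  if (!setequal(ua, ub)) {
    d <- union(setdiff(ua, ub), setdiff(ub, ua))
    stop("pattern maps cover different miRNA universes; symmetric difference: ",
         paste(d, collapse = ", "))
  }
  patterns_b <- patterns_b[ua]
  n_times <- nchar(patterns_a[1])
  codes <- all_patterns(n_times)
  stopifnot(all(patterns_a %in% codes), all(patterns_b %in% codes))
  counts <- matrix(0L, length(codes), length(codes),
                   dimnames = list(codes, codes))
  key <- paste(patterns_a, patterns_b, sep = "|")
  tab <- table(key)
  membership <- split(ua, key)
  for (k in names(tab)) {
    ab <- strsplit(k, "|", fixed = TRUE)[[1]]
    counts[ab[1], ab[2]] <- as.integer(tab[[k]])
  }
  structure(list(counts = counts, membership = membership,
                 conditions = condition_names, n_times = n_times),
            class = "compact_result")
}

#' @export
print.compact_result <- function(x, ...) {
  cat(sprintf("COMPACT result: %d x %d pattern cells (%s rows, %s columns), %d miRNAs\n",
              nrow(x$counts), ncol(x$counts), x$conditions[1], x$conditions[2],
              sum(x$counts)))
  occ <- which(x$counts > 0, arr.ind = TRUE)
  occ <- occ[order(-x$counts[occ]), , drop = FALSE]
  for (i in seq_len(min(10, nrow(occ)))) {
    cat(sprintf("  %s | %s : %d\n", rownames(x$counts)[occ[i, 1]],
                colnames(x$counts)[occ[i, 2]],
                x$counts[occ[i, 1], occ[i, 2]]))
  }
  invisible(x)
}

#' Extract the miRNAs of one COMPACT cell
#'
#' @param result a [pattern_counts()] result.
#' @param pattern_a pattern code in condition A (rows).
#' @param pattern_b pattern code in condition B (columns).
#' @return character vector of member miRNA ids (empty for unoccupied cells).
#' @export
extract_cluster <- function(result, pattern_a, pattern_b) {
  stopifnot(inherits(result, "compact_result"))
  codes <- rownames(result$counts)
  if (!pattern_a %in% codes || !pattern_b %in% codes) {
    stop("malformed pattern code: ",
         paste(setdiff(c(pattern_a, pattern_b), codes), collapse = ", "))
  }
  m <- result$membership[[paste(pattern_a, pattern_b, sep = "|")]]
  if (is.null(m)) character() else m
}
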