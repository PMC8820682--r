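#' Construct a validated miRNA count matrix
#'
#' The raw input of the pipeline: a miRNA-by-sample matrix of nonnegative
#' integer counts plus the sample metadata table describing the study design
#' (diet, hours post partial hepatectomy, treatment arm, replicate).
#'
#' @param counts integer matrix, rows = miRNAs (rownames required),
#'   columns = samples (colnames required).
#' @param samples data frame with columns `sample_id`, `diet`, `time_h`,
#'   `treatment`, `replicate`; one row per column of `counts`, same order.
#' @return object of class `count_matrix`: list with elements `counts`,
#'   `samples`, and `library_size` (column sums).
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have miRNA rownames and sample colnames")
  }
  bad <- which(counts < 0 | counts != round(counts) | !is.finite(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "non-integer or negative count at row '%s', column '%s' (value %s)",
      rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]],
      format(counts[bad[1, , drop = FALSE]])))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated miRNA ids")
  samples <- validate_sample_table(samples)
  extra_m <- setdiff(colnames(counts), samples$sample_id)
  extra_s <- setdiff(samples$sample_id, colnames(counts))
  if (length(extra_m)) {
    stop("sample(s) in count matrix absent from metadata: ",
         paste(extra_m, collapse = ", "))
  }
  if (length(extra_s)) {
    stop("sample(s) in metadata absent from count matrix: ",
         paste(extra_s, collapse = ", "))
  }
  counts <- counts[, samples$sample_id, drop = FALSE]  # normalize order
  structure(
    list(counts = counts, samples = samples, library_size = colSums(counts)),
    class = "count_matrix")
}

validate_sample_table <- function(samples) {
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  need <- c("sample_id", "diet", "time_h", "treatment", "replicate")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("metadata missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicated sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", "))
  }
  key <- interaction(samples$diet, samples$time_h, samples$treatment,
                     samples$replicate, drop = TRUE)
  if (anyDuplicated(key)) stop("duplicated (diet, time_h, treatment, replicate) tuple")
  if (any(samples$time_h < 0)) stop("time_h must be >= 0")
  if (any(samples$replicate < 1)) stop("replicate index must be >= 1")
  samples
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d miRNAs x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("library sizes:", paste(range(x$library_size), collapse = " - "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Construct a log2-CPM expression matrix
#'
#' @param values numeric matrix of log2 counts-per-million, rows = miRNAs.
#' @param samples sample metadata table (see [count_matrix()]).
#' @param weights optional positive precision-weight matrix, same shape.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, weights = NULL) {
  values <- as.matrix(values)
  if (!all(is.finite(values))) stop("expression values must be finite")
  samples <- validate_sample_table(samples)
  if (!identical(colnames(values), samples$sample_id)) {
    values <- values[, samples$sample_id, drop = FALSE]
  }
  if (!is.null(weights)) {
    weights <- as.matrix(weights)
    if (!identical(dim(weights), dim(values))) stop("weights shape mismatch")
    if (any(!is.finite(weights) | weights <= 0)) stop("weights must be positive and finite")
  }
  structure(list(values = values, samples = samples, weights = weights),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' Read / write count matrices as tab-delimited text
#'
#' The matrix file has miRNA ids in the first column and sample ids in the
#' header; the metadata file is a tab-delimited sample table. Samples are
#' reconciled by id and reordered to metadata order.
#'
#' @param path matrix file path.
#' @param metadata_path sample-metadata file path.
#' @return [count_matrix()] object.
#' @export
read_counts <- function(path, metadata_path) {
  for (p in c(path, metadata_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  storage.mode(mat) <- "double"
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  count_matrix(mat, meta)
}

#' @rdname read_counts
#' @param x `count_matrix` to write.
#' @export
write_counts <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(mirna_id = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read / write an expression matrix as tab-delimited text
#' @inheritParams read_counts
#' @export
read_expression <- function(path, metadata_path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  mat <- as.matrix(tab[, -1, drop = FALSE])
  rownames(mat) <- tab[[1]]
  meta <- utils::read.delim(metadata_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_matrix(mat, meta)
}

#' @rdname read_expression
#' @param x `expression_matrix` to write.
#' @export
write_expression <- function(x, path, metadata_path) {
  stopifnot(inherits(x, "expression_matrix"))
  df <- data.frame(mirna_id = rownames(x$values),
                   signif(x$values, 12),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$samples, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(x)
}

#' Read miRNA signatures from a GMT file
#'
#' One set per line: name, description, then member ids, tab-separated. The
#' description field may carry `cell_type=<HSC|LSEC|KC|other>` and
#' `direction=<up|down|enriched>` tags. Members are de-duplicated preserving
#' order and normalized with [normalize_mirna_ids()].
#'
#' @param path GMT file path.
#' @return list of `mirna_signature` objects (fields `name`, `cell_type`,
#'   `direction`, `members`, `description`).
#' @export
read_signatures <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty signature file: ", path)
    return(list())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields", short[1]))
  }
  names_ <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(names_)) {
    stop("duplicate signature names: ",
         paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  lapply(fields, function(f) {
    desc <- f[2]
    members <- unique(normalize_mirna_ids(f[-(1:2)]))
    mirna_signature(name = f[1], members = members,
                    cell_type = parse_tag(desc, "cell_type", "other"),
                    direction = parse_tag(desc, "direction", "enriched"),
                    description = desc)
  })
}

parse_tag <- function(desc, tag, default) {
  m <- regmatches(desc, regexpr(paste0(tag, "=[^;]+"), desc))
  if (length(m) == 0L) return(default)
  sub(paste0(tag, "="), "", m)
}

#' Construct a miRNA signature
#' @param name set name.
#' @param members unique nonempty character vector of member ids.
#' @param cell_type one of HSC, LSEC, KC, other.
#' @param direction one of up, down, enriched.
#' @param description free-text description.
#' @export
mirna_signature <- function(name, members, cell_type = "other",
                            direction = "enriched", description = "") {
  members <- unique(as.character(members))
  if (length(members) == 0L) warning("signature '", name, "' is empty")
  stopifnot(cell_type %in% c("HSC", "LSEC", "KC", "other"),
            direction %in% c("up", "down", "enriched"))
  structure(list(name = name, cell_type = cell_type, direction = direction,
                 members = members, description = description),
            class = "mirna_signature")
}

#' Load the packaged nonparenchymal-cell signature fixtures
#'
#' Four curated liver nonparenchymal cell-type miRNA signatures (hepatic
#' stellate cells up/down with culture activation, LSEC-enriched, Kupffer
#' cell post-hepatectomy) together with the pseudo-panel of assay miRNAs
#' they are screened against.
#'
#' @return list with `signatures` (list of [mirna_signature()]) and `panel`
#'   (character vector of panel ids).
#' @export
load_packaged_signatures <- function() {
  gmt <- system.file("extdata", "npc_mirna_signatures.gmt", package = "regenmir")
  panel <- system.file("extdata", "pseudo_panel.txt", package = "regenmir")
  list(signatures = read_signatures(gmt),
       panel = normalize_mirna_ids(readLines(panel)))
}

#' Read / write qPCR CT tables
#'
#' Tidy delimited table with columns `group`, `target`, `replicate`, `ct`.
#'
#' @param path file path.
#' @return data frame of class `qpcr_table`.
#' @export
read_qpcr <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_qpcr(tab)
}

#' @rdname read_qpcr
#' @param x qPCR table to write.
#' @export
write_qpcr <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

validate_qpcr <- function(tab) {
  need <- c("group", "target", "replicate", "ct")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("CT table missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(tab$ct))) stop("CT values must be finite")
  structure(tab, class = c("qpcr_table", "data.frame"))
}

#' Counts per million
#'
#' @param counts `count_matrix` or plain matrix.
#' @return numeric matrix of counts per million (no log, no prior).
#' @export
cpm <- function(counts) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  sweep(m, 2, colSums(m), "/") * 1e6
}

#' Filter miRNAs by minimum expression
#'
#' Keeps miRNAs with cpm >= `min_cpm` in at least `min_samples` samples;
#' row order is preserved. With `min_cpm = 0` or `min_samples = 0` this is
#' the identity.
#'
#' @param counts a [count_matrix()].
#' @param min_cpm minimum counts-per-million (default 1).
#' @param min_samples minimum number of samples meeting `min_cpm` (default 3).
#' @return filtered `count_matrix`.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_samples = 3) {
  stopifnot(inherits(counts, "count_matrix"), min_cpm >= 0,
            min_samples >= 0, min_samples <= ncol(counts$counts))
  if (min_cpm == 0 || min_samples == 0) return(counts)
  keep <- rowSums(cpm(counts) >= min_cpm) >= min_samples
  if (!any(keep)) warning("expression filter removed every miRNA")
  count_matrix(counts$counts[keep, , drop = FALSE], counts$samples)
}
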