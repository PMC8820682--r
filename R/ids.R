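#' Normalize miRNA identifiers
#'
#' Identifier matching across the pipeline is exact-string after trimming
#' whitespace and case-folding the family prefix ("miR"/"let"), with an
#' optional curated alias table to resolve typographical variants that arise
#' when rat, mouse and human naming conventions are mixed (for example
#' \code{"miR-3405p"} for \code{"miR-340-5p"}). Species prefixes such as
#' \code{"rno-"} or \code{"hsa-"} are preserved: they are part of the name.
#'
#' @param ids character vector of miRNA identifiers.
#' @param aliases optional two-column data frame (\code{alias},
#'   \code{canonical}); defaults to the packaged curated table.
#' @return character vector of normalized identifiers, same length as `ids`.
#' @examples
#' normalize_mirna_ids(c(" mir-21", "LET-7a", "miR-3405p"))
#' @export
normalize_mirna_ids <- function(ids, aliases = default_aliases()) {
  stopifnot(is.character(ids))
  out <- trimws(ids)
  # case-fold the family prefix only; the suffix (arm, star, numbering) is
  # case-sensitive in mirBase-style names
  out <- sub("^(([a-zA-Z]{3})-)?[mM][iI][rR]([-0-9])", "\\1miR\\3", out)
  out <- sub("^(([a-zA-Z]{3})-)?[lL][eE][tT]-", "\\1let-", out)
  if (!is.null(aliases) && nrow(aliases) > 0L) {
    hit <- match(out, aliases$alias)
    out[!is.na(hit)] <- aliases$canonical[hit[!is.na(hit)]]
  }
  out
}

#' @rdname normalize_mirna_ids
#' @export
default_aliases <- function() {
  path <- system.file("extdata", "mirna_aliases.tsv", package = "regenmir")
  if (!nzchar(path)) {
    return(data.frame(alias = character(), canonical = character()))
  }
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Match identifiers against a panel, reporting what did not resolve
#'
#' Unresolved identifiers are reported, never silently dropped.
#'
#' @param ids identifiers to look up.
#' @param panel reference identifier universe.
#' @param aliases alias table passed to [normalize_mirna_ids()].
#' @return list with `matched` (ids found in the panel, normalized),
#'   `unmatched` (normalized ids not in the panel).
#' @export
match_mirna_ids <- function(ids, panel, aliases = default_aliases()) {
  nid <- normalize_mirna_ids(ids, aliases)
  npanel <- normalize_mirna_ids(panel, aliases)
  keep <- nid %in% npanel
  list(matched = nid[keep], unmatched = nid[!keep])
}
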