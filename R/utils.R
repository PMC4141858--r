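# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_data <- function(...) stop(..., call. = FALSE)

# number of alleles shared (with multiplicity) between two sorted diploid
# pairs; vectorised over loci. Missing entries give NA.
shared_alleles <- function(a1, a2, b1, b2) {
  s <- pmax((a1 == b1) + (a2 == b2), (a1 == b2) + (a2 == b1))
  s[is.na(a1) | is.na(b1)] <- NA_integer_
  s
}

# deterministic zero-padded ids: "MLG01".."MLG36", "MLL1".."MLL5", ...
pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))
}

# resolve a grouping spec (metadata column name or named vector keyed by
# individual id) to a factor aligned with panel rows
resolve_grouping <- function(panel, grouping) {
  ids <- panel$meta$individual
  if (is.character(grouping) && length(grouping) == 1 &&
      grouping %in% names(panel$meta)) {
    g <- as.character(panel$meta[[grouping]])
  } else {
    if (is.null(names(grouping)))
      stop_data("grouping must be a metadata column name or a vector named by individual id")
    if (!all(ids %in% names(grouping)))
      stop_data("grouping is missing individuals: ",
                paste(utils::head(setdiff(ids, names(grouping))), collapse = ", "))
    g <- as.character(grouping[ids])
  }
  factor(g, levels = unique(g))
}
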