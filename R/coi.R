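#' Read an aligned FASTA of COI barcode sequences
#'
#' Sequences must all have the same length (an alignment); the alphabet is
#' `A,C,G,T,N,-` (case-insensitive). Duplicate ids are rejected.
#'
#' @param path FASTA file.
#' @return object of class `haplotype_panel`: list with `length` (alignment
#'   length in bp) and `seqs` (named uppercase character vector).
#' @export
read_fasta_alignment <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  dna <- tryCatch(suppressWarnings(ape::read.FASTA(path)),
                  error = function(e) NULL)
  if (is.null(dna) || length(dna) == 0) stop_data("empty FASTA: ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1)
    stop_data("ragged alignment: sequence lengths ",
              paste(unique(lens), collapse = ", "))
  ids <- names(dna)
  if (anyDuplicated(ids)) stop_data("duplicate sequence ids")
  seqs <- vapply(as.character(dna), function(x) paste(toupper(x), collapse = ""), "")
  names(seqs) <- ids
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop_data("unexpected characters in sequences: ",
              paste(utils::head(ids[bad]), collapse = ", "))
  haplotype_panel(seqs)
}

#' Construct a haplotype panel from aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences.
#' @param annotations optional data frame with an `id` column (MLL, host...).
#' @return a `haplotype_panel`.
#' @export
haplotype_panel <- function(seqs, annotations = NULL) {
  if (length(seqs) == 0) stop_data("no sequences")
  if (is.null(names(seqs))) stop_data("sequences must be named")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop_data("ragged alignment")
  structure(list(length = unname(lens[1]), seqs = toupper(seqs),
                 annotations = annotations),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat("haplotype_panel:", length(x$seqs), "aligned sequences of",
      x$length, "bp\n")
  invisible(x)
}

#' Collapse aligned sequences to distinct haplotypes
#'
#' Exact-match collapse of identical sequences. Haplotype ids are assigned
#' by first occurrence (`H1`, `H2`, ...), so the operation is deterministic
#' and idempotent.
#'
#' @param panel a [haplotype_panel()].
#' @return data frame: `haplotype`, `sequence`, `count`, `members`
#'   (semicolon-joined sequence ids).
#' @export
collapse_haplotypes <- function(panel) {
  key <- panel$seqs
  uniq <- unique(key)
  ids <- paste0("H", seq_along(uniq))
  hap <- ids[match(key, uniq)]
  data.frame(
    haplotype = ids,
    sequence = uniq,
    count = as.integer(table(factor(hap, levels = ids))),
    members = vapply(ids, function(h)
      paste(names(panel$seqs)[hap == h], collapse = ";"), ""),
    row.names = NULL)
}

seq_matrix <- function(seqs) {
  do.call(rbind, strsplit(unname(seqs), ""))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among the positions where both sequences
#' carry an unambiguous base (`A/C/G/T`); `N` and gaps are excluded
#' pairwise, the standard convention for barcode data.
#'
#' @param seq_a,seq_b equal-length sequence strings.
#' @return proportion in `[0, 1]`.
#' @export
pairwise_p_distance <- function(seq_a, seq_b) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop_data("sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok)) stop_data("no mutually unambiguous site")
  sum(a[ok] != b[ok]) / sum(ok)
}

#' Mean pairwise divergence of an alignment
#'
#' Averages uncorrected p-distances over all pairs of individual sequences
#' (`by_individual`, so common haplotypes weigh more) or over pairs of
#' distinct haplotypes (`by_haplotype`).
#'
#' @param panel a [haplotype_panel()].
#' @param weighting `"by_individual"` (default) or `"by_haplotype"`.
#' @return list: `mean`, `min`, `max` (proportions).
#' @export
mean_pairwise_divergence <- function(panel,
                                     weighting = c("by_individual",
                                                   "by_haplotype")) {
  weighting <- match.arg(weighting)
  seqs <- panel$seqs
  if (weighting == "by_haplotype") seqs <- unique(seqs)
  n <- length(seqs)
  if (n < 2) stop_data("need at least 2 sequences")
  m <- seq_matrix(seqs)
  isbase <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  d <- numeric(n * (n - 1) / 2)
  k <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- isbase[i, ] & isbase[j, ]
    k <- k + 1
    d[k] <- sum(m[i, ok] != m[j, ok]) / sum(ok)
  }
  list(mean = mean(d), min = min(d), max = max(d))
}

#' Minimum spanning network over COI haplotypes
#'
#' Collapses the alignment to distinct haplotypes, computes the pairwise
#' substitution-count distance matrix (differing sites among mutually
#' unambiguous positions) and delegates to [build_msn()]. Node annotations
#' carry each haplotype's copy number.
#'
#' @param panel a [haplotype_panel()].
#' @return a `spanning_network` whose nodes are haplotype ids.
#' @export
haplotype_network <- function(panel) {
  hap <- collapse_haplotypes(panel)
  if (nrow(hap) < 2) stop_data("need at least 2 distinct haplotypes")
  m <- seq_matrix(hap$sequence)
  n <- nrow(hap)
  isbase <- matrix(m %in% c("A", "C", "G", "T"), nrow = n)
  d <- matrix(0L, n, n, dimnames = list(hap$haplotype, hap$haplotype))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- isbase[i, ] & isbase[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, ok] != m[j, ok])
  }
  build_msn(d, annotations = data.frame(id = hap$haplotype,
                                        count = hap$count))
}
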