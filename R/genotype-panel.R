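#' Construct a codominant diploid genotype panel
#'
#' A `genotype_panel` holds allele-size calls (in bp) for a set of diploid
#' individuals scored at the same microsatellite loci, together with the
#' sampling metadata the clonal analysis needs. A *sample* groups individuals
#' collected from the same host plant in one locality on one date; clonal
#' copies of a genotype within a sample are assumed to derive from local
#' asexual reproduction.
#'
#' Alleles are stored canonically with `a1 <= a2` at every locus. Missing
#' data is represented by `NA` in both slots of a pair (a half-called locus
#' is rejected).
#'
#' @param meta data frame with columns `individual`, `sample`, `locality`,
#'   `host` (further columns are kept). Individual ids must be unique.
#' @param a1,a2 integer matrices, individuals x loci, with the smaller and
#'   larger allele of each pair. Dimnames are ignored; `loci` fixes the order.
#' @param loci character vector of locus names, one per column of `a1`.
#' @return An object of class `genotype_panel`: a list with elements `loci`,
#'   `meta`, `a1`, `a2`.
#' @examples
#' p <- genotype_panel(
#'   meta = data.frame(individual = c("i1", "i2"), sample = "s1",
#'                     locality = "loc1", host = "sorghum"),
#'   a1 = matrix(c(189L, 189L), 2, 1), a2 = matrix(c(203L, 189L), 2, 1),
#'   loci = "CIR-Ms-C08")
#' p
#' @export
genotype_panel <- function(meta, a1, a2, loci) {
  meta <- as.data.frame(meta)
  for (col in c("individual", "sample", "locality", "host"))
    if (!col %in% names(meta)) stop_data("meta lacks column '", col, "'")
  meta$individual <- as.character(meta$individual)
  meta$sample <- as.character(meta$sample)
  a1 <- as.matrix(a1); storage.mode(a1) <- "integer"
  a2 <- as.matrix(a2); storage.mode(a2) <- "integer"
  panel <- structure(
    list(loci = as.character(loci), meta = meta, a1 = a1, a2 = a2),
    class = "genotype_panel")
  validate_genotype_panel(panel)
}

validate_genotype_panel <- function(panel) {
  n <- nrow(panel$meta)
  L <- length(panel$loci)
  if (!all(dim(panel$a1) == c(n, L)) || !all(dim(panel$a2) == c(n, L)))
    stop_data("allele matrices must be ", n, " x ", L)
  if (anyDuplicated(panel$meta$individual))
    stop_data("duplicate individual ids: ",
              paste(unique(panel$meta$individual[duplicated(panel$meta$individual)]),
                    collapse = ", "))
  half <- is.na(panel$a1) != is.na(panel$a2)
  if (any(half))
    stop_data("half-called allele pairs (one allele missing) are not allowed")
  bad <- !is.na(panel$a1) & (panel$a1 <= 0L | panel$a2 <= 0L)
  if (any(bad)) stop_data("allele sizes must be positive integers")
  swap <- !is.na(panel$a1) & panel$a1 > panel$a2
  if (any(swap)) {  # enforce canonical a1 <= a2
    tmp <- panel$a1[swap]
    panel$a1[swap] <- panel$a2[swap]
    panel$a2[swap] <- tmp
  }
  dimnames(panel$a1) <- dimnames(panel$a2) <-
    list(panel$meta$individual, panel$loci)
  panel
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", nrow(x$meta), " individuals, ",
      length(x$loci), " loci, ",
      length(unique(x$meta$sample)), " samples\n", sep = "")
  cat("loci:", paste(x$loci, collapse = ", "), "\n")
  miss <- sum(is.na(x$a1))
  if (miss > 0) cat("missing allele pairs:", miss, "\n")
  invisible(x)
}

#' Number of individuals / loci in a panel
#' @param panel a [genotype_panel()]
#' @return integer count
#' @export
n_individuals <- function(panel) nrow(panel$meta)

#' @rdname n_individuals
#' @export
n_loci <- function(panel) length(panel$loci)

#' Subset a panel by individual
#' @param panel a [genotype_panel()]
#' @param i row index, logical mask, or vector of individual ids
#' @return a `genotype_panel` with the selected records, in the given order
#' @export
subset_panel <- function(panel, i) {
  if (is.character(i)) i <- match(i, panel$meta$individual)
  genotype_panel(panel$meta[i, , drop = FALSE],
                 panel$a1[i, , drop = FALSE],
                 panel$a2[i, , drop = FALSE],
                 panel$loci)
}

#' Extract one individual's genotype as a 2 x L allele matrix
#' @param panel a [genotype_panel()]
#' @param id individual id or row index
#' @return integer matrix with rows `a1`, `a2` and one column per locus
#' @export
panel_genotype <- function(panel, id) {
  i <- if (is.character(id)) match(id, panel$meta$individual) else id
  if (is.na(i)) stop_data("unknown individual: ", id)
  rbind(a1 = panel$a1[i, ], a2 = panel$a2[i, ])
}

# string key identifying a multilocus genotype; NA rendered as the text "NA"
# so keys are stable. Padding keeps lexicographic order equal to numeric order.
genotype_keys <- function(panel) {
  n <- nrow(panel$a1)
  fmt <- function(m) {
    s <- sprintf("%04d", m)
    s[is.na(m)] <- "????"
    matrix(s, nrow = n)
  }
  k1 <- fmt(panel$a1); k2 <- fmt(panel$a2)
  apply(matrix(paste0(k1, ".", k2), nrow = n), 1, paste, collapse = "|")
}
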