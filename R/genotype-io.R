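#' Parse a diploid allele-pair cell
#'
#' Parses a genotype-table cell of the form `"189/203"` into a canonical
#' sorted allele pair. The doubled separator `"//"` occasionally produced by
#' table formatting is tolerated, as is surrounding whitespace. A cell equal
#' to the missing-data code (by default `"0"`, `"0/0"` or an empty string)
#' yields a fully missing pair.
#'
#' @param text character scalar, e.g. `"189/203"` or `"214//216"`.
#' @param missing_code integer allele value standing for missing data
#'   (default 0); `"0"`, `"0/0"` and `""` all parse to missing.
#' @param where optional label (e.g. `"row 3, locus CIR-Ms-G01"`) used in
#'   error messages.
#' @return integer vector `c(a1, a2)` with `a1 <= a2`, or `c(NA, NA)` for
#'   missing data.
#' @examples
#' parse_allele_pair("189/203")
#' parse_allele_pair("214//216")  # "//" treated as "/"
#' parse_allele_pair("203/189")   # canonical sort
#' @export
parse_allele_pair <- function(text, missing_code = 0L, where = NULL) {
  ctx <- if (is.null(where)) "" else paste0(" at ", where)
  txt <- trimws(as.character(text))
  if (length(txt) != 1 || is.na(txt))
    stop_data("allele pair must be a single string", ctx)
  if (txt == "" || txt == as.character(missing_code) ||
      txt == paste0(missing_code, "/", missing_code))
    return(c(NA_integer_, NA_integer_))
  txt <- gsub("//", "/", txt, fixed = TRUE)
  toks <- trimws(strsplit(txt, "/", fixed = TRUE)[[1]])
  toks <- toks[toks != ""]
  if (length(toks) != 2)
    stop_data("expected two alleles separated by '/' in '", text, "'", ctx)
  if (!all(grepl("^[0-9]+$", toks)))
    stop_data("non-integer allele token in '", text, "'", ctx)
  a <- as.integer(toks)
  if (all(a == missing_code)) return(c(NA_integer_, NA_integer_))
  if (any(a == missing_code))
    stop_data("half-missing allele pair '", text, "'", ctx)
  sort(a)
}

format_allele_pair <- function(a1, a2, missing_code = 0L) {
  out <- paste0(a1, "/", a2)
  out[is.na(a1)] <- paste0(missing_code, "/", missing_code)
  out
}

#' Read a codominant genotype table
#'
#' Two dialects are supported. `"wide_csv"` is the native layout: columns
#' `individual,sample,locality,host` followed by one `a1/a2` column per
#' locus. `"genalex"` is a GenAlEx-like layout with two header rows (a counts
#' row `n_loci,n_individuals,n_samples`, then locus names spanning two
#' columns each) and two integer allele columns per locus.
#'
#' @param path file to read.
#' @param dialect `"wide_csv"` (default) or `"genalex"`.
#' @param missing_code integer missing-data allele code (default 0).
#' @return a [genotype_panel()].
#' @seealso [write_genotype_table()] for the inverse operation.
#' @export
read_genotype_table <- function(path, dialect = c("wide_csv", "genalex"),
                                missing_code = 0L) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (dialect == "wide_csv") {
    tab <- utils::read.csv(path, check.names = FALSE,
                           colClasses = "character")
    meta_cols <- c("individual", "sample", "locality", "host")
    if (!all(meta_cols %in% names(tab)))
      stop_data("wide_csv header must contain columns ",
                paste(meta_cols, collapse = ", "))
    loci <- setdiff(names(tab), meta_cols)
    if (length(loci) == 0) stop_data("no locus columns in ", path)
    if (nrow(tab) == 0) stop_data("no records in ", path)
    n <- nrow(tab)
    a1 <- a2 <- matrix(NA_integer_, n, length(loci))
    for (j in seq_along(loci)) {
      for (i in seq_len(n)) {
        p <- parse_allele_pair(tab[[loci[j]]][i], missing_code,
                               where = paste0("row ", i, ", locus ", loci[j]))
        a1[i, j] <- p[1]; a2[i, j] <- p[2]
      }
    }
    panel <- genotype_panel(tab[meta_cols], a1, a2, loci)
  } else {
    lines <- readLines(path)
    if (length(lines) < 3) stop_data("no records in ", path)
    counts <- as.integer(strsplit(lines[1], ",", fixed = TRUE)[[1]])
    hdr <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
    L <- counts[1]
    loci <- hdr[4 + 2 * seq_len(L) - 1]   # locus name on first of its 2 cols
    body <- utils::read.csv(text = lines[-(1:2)], header = FALSE,
                            colClasses = "character")
    if (nrow(body) == 0) stop_data("no records in ", path)
    if (ncol(body) != 4 + 2 * L)
      stop_data("ragged genalex rows: expected ", 4 + 2 * L, " columns")
    n <- nrow(body)
    a1 <- a2 <- matrix(NA_integer_, n, L)
    for (j in seq_len(L)) {
      x <- as.integer(body[[4 + 2 * j - 1]])
      y <- as.integer(body[[4 + 2 * j]])
      miss <- x == missing_code & y == missing_code
      if (any(xor(x == missing_code, y == missing_code)))
        stop_data("half-missing pair at locus ", loci[j])
      a1[, j] <- ifelse(miss, NA_integer_, pmin(x, y))
      a2[, j] <- ifelse(miss, NA_integer_, pmax(x, y))
    }
    meta <- data.frame(individual = body[[1]], sample = body[[2]],
                       locality = body[[3]], host = body[[4]])
    panel <- genotype_panel(meta, a1, a2, loci)
  }
  message("read ", n_individuals(panel), " individuals x ",
          n_loci(panel), " loci from ", path)
  panel
}

#' Write a genotype panel to disk
#'
#' Writing then reading back (same dialect) reproduces the panel exactly,
#' including the position of missing pairs.
#'
#' @param panel a [genotype_panel()].
#' @param path output file.
#' @inheritParams read_genotype_table
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(panel, path,
                                 dialect = c("wide_csv", "genalex"),
                                 missing_code = 0L) {
  dialect <- match.arg(dialect)
  meta <- panel$meta[c("individual", "sample", "locality", "host")]
  if (dialect == "wide_csv") {
    cells <- matrix(format_allele_pair(panel$a1, panel$a2, missing_code),
                    nrow = nrow(meta))
    out <- cbind(meta, as.data.frame(cells))
    names(out) <- c(names(meta), panel$loci)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  } else {
    L <- n_loci(panel); n <- n_individuals(panel)
    con <- file(path, "w"); on.exit(close(con))
    writeLines(paste(L, n, length(unique(meta$sample)), sep = ","), con)
    hdr <- c("individual", "sample", "locality", "host",
             as.vector(rbind(panel$loci, "")))
    writeLines(paste(hdr, collapse = ","), con)
    fill <- function(m) { m[is.na(m)] <- missing_code; m }
    A1 <- fill(panel$a1); A2 <- fill(panel$a2)
    allele_cols <- matrix(NA_integer_, n, 2 * L)
    allele_cols[, 2 * seq_len(L) - 1] <- A1
    allele_cols[, 2 * seq_len(L)] <- A2
    body <- cbind(meta, as.data.frame(allele_cols))
    utils::write.table(body, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Published 36-MLG reference genotype table
#'
#' Loads the worldwide *Melanaphis sacchari* reference set of 36 unique
#' multilocus genotypes (Ms1 ... Ms315) scored at 10 microsatellite loci,
#' shipped with the package, together with the published multilocus-lineage
#' label (A-E) of each MLG.
#'
#' Each MLG is loaded as one individual in its own sample, which is the
#' layout the lineage-delimitation pipeline expects when re-analysing the
#' reference table.
#'
#' @return a [genotype_panel()] of 36 records x 10 loci with an `mll`
#'   attribute: a character vector of published lineage labels named by MLG id.
#' @examples
#' p <- load_table1_fixture()
#' table(attr(p, "mll"))
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_mlg.csv", package = "clonepart",
                      mustWork = TRUE)
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  loci <- setdiff(names(tab), c("individual", "sample", "locality", "host", "mll"))
  n <- nrow(tab)
  a1 <- a2 <- matrix(NA_integer_, n, length(loci))
  for (j in seq_along(loci)) for (i in seq_len(n)) {
    p <- parse_allele_pair(tab[[loci[j]]][i],
                           where = paste0(tab$individual[i], ", ", loci[j]))
    a1[i, j] <- p[1]; a2[i, j] <- p[2]
  }
  panel <- genotype_panel(tab[c("individual", "sample", "locality", "host")],
                          a1, a2, loci)
  attr(panel, "mll") <- stats::setNames(tab$mll, tab$individual)
  panel
}

#' Published distribution of retained representatives by region and host
#'
#' Counts of the 98 retained representative individuals (one per MLG per
#' sample) broken down by country/province, host plant and multilocus
#' lineage, with the number of samples contributing to each row.
#'
#' @return data frame with columns `state`, `host`, `mll`, `individuals`
#'   plus a per-(state, host) `samples` count.
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_distribution.csv",
                      package = "clonepart", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
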