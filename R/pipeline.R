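#' Run the full clonal-diversity analysis
#'
#' Orchestrates the whole workflow in order: read (or accept) the genotype
#' panel, collapse to MLGs, retain one representative per (sample, MLG),
#' recompute MLGs on the retained set, build the allelic-distance matrix
#' and its histogram, detect (or accept) the lineage threshold, assign
#' MLLs, compute p_sex per lineage and clonal richness, build the minimum
#' spanning network, run the clone-aware population-genetic tests between
#' MLLs, optionally analyse a COI alignment, and cross-tabulate lineages by
#' host and locality.
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{input}{path to a genotype table, or a [genotype_panel()]}
#'     \item{dialect}{`"wide_csv"` (default) or `"genalex"`}
#'     \item{threshold}{`"auto"` (default) or an integer}
#'     \item{n_perm}{permutations for the tests (default 999)}
#'     \item{seed}{integer seed (default 1)}
#'     \item{fasta}{optional path to an aligned COI FASTA}
#'     \item{out_dir}{optional directory; when set, all stage outputs are
#'       written there as CSV/TSV/GraphML files}
#'     \item{run_popgen}{run the permutation tests (default `TRUE`)}
#'   }
#' @return object of class `clonal_analysis_report`: list with elements
#'   `input_summary`, `mlg`, `retained`, `histogram`, `threshold`,
#'   `threshold_mode`, `mll`, `richness` (`r_mlg`, `r_mll`), `psex`,
#'   `network`, `popgen`, `coi`, `cross_host`, `cross_locality`,
#'   `parameters`.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$input))
    stop_data("config must name an input panel (config$input)")
  dialect <- config$dialect %||% "wide_csv"
  n_perm <- config$n_perm %||% 999
  seed <- config$seed %||% 1
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_data("stage '", name, "' failed: ", conditionMessage(e)))
  }

  panel <- stage("read", {
    if (inherits(config$input, "genotype_panel")) config$input
    else read_genotype_table(config$input, dialect)
  })
  mlgs_all <- stage("collapse", collapse_mlg(panel))
  retained <- stage("representatives",
                    representative_per_sample(panel, mlgs_all))
  mlgs <- stage("collapse_retained", collapse_mlg(retained))
  d <- stage("distances", distance_matrix(mlgs))
  h <- stage("histogram", distance_histogram(d))
  threshold_mode <- if (identical(config$threshold %||% "auto", "auto"))
    "auto" else "manual"
  threshold <- stage("threshold", {
    if (threshold_mode == "auto") detect_threshold(h)
    else {
      warning("using manually supplied threshold ", config$threshold)
      as.integer(config$threshold)
    }
  })
  mll <- stage("mll", assign_mll(d, threshold))
  psex <- stage("psex", psex_report(retained, mlgs, mll))
  N <- n_individuals(retained)
  r_mlg <- stage("richness", clonal_richness(length(mlgs$mlg_ids), N))
  r_mll <- clonal_richness(length(mll$mll_ids), N)
  net <- stage("network", build_msn(d, annotations = data.frame(
    id = names(mll$membership), mll = unname(mll$membership))))

  mll_of_individual <- stats::setNames(
    unname(mll$membership[mlgs$membership[retained$meta$individual]]),
    retained$meta$individual)
  popgen <- NULL
  if (isTRUE(config$run_popgen %||% TRUE) && length(mll$mll_ids) >= 2) {
    popgen <- stage("popgen", {
      multi_mll <- names(table(mll_of_individual))[
        table(mll_of_individual) >= 2]
      list(
        fis = fis_estimate(retained, mll_of_individual),
        heterozygosity = heterozygosity(retained, mll_of_individual),
        fst = pairwise_fst(retained, mll_of_individual),
        g_test = g_test_differentiation(retained, mll_of_individual,
                                        n_perm = n_perm, seed = seed),
        hwe_excess = stats::setNames(lapply(multi_mll, function(pop)
          hwe_test(retained, mll_of_individual, pop,
                   alternative = "excess", n_perm = max(n_perm, 100),
                   seed = seed)$p), multi_mll))
    })
  }
  coi <- NULL
  if (!is.null(config$fasta)) {
    coi <- stage("coi", {
      hp <- read_fasta_alignment(config$fasta)
      list(haplotypes = collapse_haplotypes(hp),
           divergence = mean_pairwise_divergence(hp),
           network = if (length(unique(hp$seqs)) >= 2)
             haplotype_network(hp) else NULL)
    })
  }
  cross_host <- stage("cross_tabulate",
                      cross_tabulate(retained, mll, mlgs, by = "host"))
  cross_locality <- cross_tabulate(retained, mll, mlgs, by = "locality")

  report <- structure(list(
    input_summary = list(individuals = n_individuals(panel),
                         samples = length(unique(panel$meta$sample)),
                         loci = n_loci(panel)),
    mlg = mlgs, retained = retained, histogram = h,
    threshold = threshold, threshold_mode = threshold_mode,
    mll = mll, richness = list(r_mlg = r_mlg, r_mll = r_mll),
    psex = psex, network = net, popgen = popgen, coi = coi,
    cross_host = cross_host, cross_locality = cross_locality,
    parameters = list(dialect = dialect, threshold = config$threshold %||% "auto",
                      n_perm = n_perm, seed = seed)),
    class = "clonal_analysis_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Cross-tabulate retained individuals by lineage and metadata
#'
#' Counts retained representatives per (group, MLL); row and column sums
#' equal the retained-representative count, so composition tables always
#' reconcile with the headline counts.
#'
#' @param panel the retained representative panel.
#' @param mll an [assign_mll()] partition.
#' @param mlgs the [collapse_mlg()] partition linking individuals to MLGs.
#' @param by metadata column: `"host"`, `"locality"` or `"sample"`.
#' @return integer contingency matrix, groups x MLLs.
#' @export
cross_tabulate <- function(panel, mll, mlgs, by = c("host", "locality",
                                                    "sample")) {
  by <- match.arg(by)
  if (!by %in% names(panel$meta)) stop_data("no metadata column '", by, "'")
  mll_of <- mll$membership[mlgs$membership[panel$meta$individual]]
  tab <- table(factor(panel$meta[[by]],
                      levels = unique(panel$meta[[by]])),
               factor(mll_of, levels = mll$mll_ids))
  m <- unclass(tab)
  names(dimnames(m)) <- c(by, "mll")
  m
}

#' @export
print.clonal_analysis_report <- function(x, ...) {
  cat("clonal analysis report\n")
  cat("  input: ", x$input_summary$individuals, " individuals, ",
      x$input_summary$samples, " samples, ", x$input_summary$loci,
      " loci\n", sep = "")
  cat("  MLGs:", length(x$mlg$mlg_ids),
      "| retained representatives:", n_individuals(x$retained), "\n")
  cat("  threshold:", x$threshold, paste0("(", x$threshold_mode, ")"),
      "| MLLs:", length(x$mll$mll_ids), "\n")
  cat("  R_MLG =", x$richness$r_mlg$R, "| R_MLL =", x$richness$r_mll$R, "\n")
  invisible(x)
}

# write all stage outputs under out_dir (CSV/TSV/GraphML)
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  write_genotype_table(report$retained, fp("retained_panel.csv"))
  utils::write.csv(data.frame(mlg = names(report$mlg$counts),
                              count = report$mlg$counts,
                              row.names = NULL),
                   fp("mlg_counts.csv"), row.names = FALSE)
  d <- distance_matrix(report$mlg)
  utils::write.table(d, fp("distance_matrix.tsv"), sep = "\t", quote = FALSE)
  utils::write.table(data.frame(distance = names(report$histogram),
                                count = report$histogram),
                     fp("distance_histogram.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(mlg = names(report$mll$membership),
                              mll = report$mll$membership,
                              row.names = NULL),
                   fp("mll_membership.csv"), row.names = FALSE)
  utils::write.csv(report$psex, fp("psex_report.csv"), row.names = FALSE)
  export_network(report$network, fp("msn.graphml"), "graphml")
  export_network(report$network, fp("msn_edges.tsv"), "edge_list")
  summary_lines <- c(
    paste("individuals:", report$input_summary$individuals),
    paste("samples:", report$input_summary$samples),
    paste("loci:", report$input_summary$loci),
    paste("n_mlg:", length(report$mlg$mlg_ids)),
    paste("retained:", n_individuals(report$retained)),
    paste("threshold:", report$threshold, paste0("(", report$threshold_mode, ")")),
    paste("n_mll:", length(report$mll$mll_ids)),
    paste("r_mlg:", report$richness$r_mlg$R),
    paste("r_mll:", report$richness$r_mll$R),
    paste("seed:", report$parameters$seed),
    paste("n_perm:", report$parameters$n_perm))
  writeLines(summary_lines, fp("report_summary.txt"))
  invisible(out_dir)
}
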