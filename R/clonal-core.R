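#' Collapse individuals to unique multilocus genotypes (MLGs)
#'
#' Two individuals share an MLG iff their allele pairs are identical at every
#' locus (missing pairs compare equal only to missing pairs). Individuals
#' missing data at every locus carry no genotype information and are dropped
#' with a warning.
#'
#' MLG ids are assigned deterministically in lexicographic order of the
#' genotype (allele sizes locus by locus), so the same set of genotypes
#' always receives the same ids regardless of input order.
#'
#' @param panel a [genotype_panel()].
#' @return an object of class `mlg_partition`: list with
#'   \describe{
#'     \item{mlg_ids}{character vector of MLG ids}
#'     \item{representatives}{a `genotype_panel` with one (first-seen)
#'       individual per MLG, rows in MLG-id order; the original individual
#'       id is kept in the `source_individual` metadata column}
#'     \item{membership}{named character vector, individual id -> MLG id}
#'     \item{counts}{named integer vector of copies per MLG}
#'     \item{counts_by_sample}{integer matrix, MLG x sample}
#'   }
#' @export
collapse_mlg <- function(panel) {
  if (n_individuals(panel) == 0) stop_data("empty panel")
  all_missing <- rowSums(!is.na(panel$a1)) == 0
  if (any(all_missing)) {
    warning("excluding ", sum(all_missing),
            " individual(s) with missing data at every locus")
    panel <- subset_panel(panel, !all_missing)
    if (n_individuals(panel) == 0) stop_data("no scorable individuals left")
  }
  keys <- genotype_keys(panel)
  uniq <- sort(unique(keys))                 # lexicographic = allele order
  ids <- pad_ids("MLG", length(uniq))
  key2id <- stats::setNames(ids, uniq)
  membership <- stats::setNames(key2id[keys], panel$meta$individual)
  first <- match(uniq, keys)
  reps <- subset_panel(panel, first)
  reps$meta$source_individual <- reps$meta$individual
  reps$meta$individual <- ids
  rownames(reps$a1) <- rownames(reps$a2) <- ids
  counts <- table(factor(membership, levels = ids))
  by_sample <- table(factor(membership, levels = ids),
                     factor(panel$meta$sample,
                            levels = unique(panel$meta$sample)))
  structure(list(mlg_ids = ids, representatives = reps,
                 membership = membership,
                 counts = stats::setNames(as.integer(counts), ids),
                 counts_by_sample = unclass(by_sample)),
            class = "mlg_partition")
}

#' @export
print.mlg_partition <- function(x, ...) {
  cat("mlg_partition:", length(x$mlg_ids), "MLGs from",
      length(x$membership), "individuals\n")
  invisible(x)
}

#' Retain one representative of each MLG in each sample
#'
#' Repeated copies of an MLG inside one sample are taken to result from
#' local clonal reproduction; keeping a single (first-seen) copy per
#' (sample, MLG) pair removes this pseudo-replication before diversity and
#' population-genetic analysis. The operation is idempotent.
#'
#' @param panel a [genotype_panel()] with sample ids.
#' @param mlgs the [collapse_mlg()] partition of `panel`.
#' @return a reduced `genotype_panel`, rows in original panel order.
#' @export
representative_per_sample <- function(panel, mlgs) {
  ids <- panel$meta$individual
  keep <- ids %in% names(mlgs$membership)
  key <- paste(panel$meta$sample, mlgs$membership[ids], sep = "\r")
  keep <- keep & !duplicated(key)
  subset_panel(panel, keep)
}

#' Allelic-difference distance between two diploid genotypes
#'
#' The distance is the number of allelic differences: at each locus the two
#' allele pairs are compared as multisets and `2 - (shared alleles)` is
#' accumulated, so `206/210` vs `204/206` counts one difference, not two.
#' The result is an integer in `[0, 2L]`, zero iff the genotypes are
#' identical, and satisfies the triangle inequality.
#'
#' Loci where either genotype is missing are skipped; when `rescale_missing`
#' is `TRUE` (default) the sum over the `L - m` scored loci is rescaled by
#' `L/(L - m)` and rounded to the nearest integer, so distances remain
#' comparable across genotypes with different amounts of missing data.
#'
#' @param g1,g2 genotypes as returned by [panel_genotype()]: 2 x L allele
#'   matrices over the same loci.
#' @param rescale_missing rescale for skipped loci (default `TRUE`).
#' @return non-negative integer distance.
#' @examples
#' p <- load_table1_fixture()
#' pairwise_allele_distance(panel_genotype(p, "Ms1"), panel_genotype(p, "Ms2"))
#' @export
pairwise_allele_distance <- function(g1, g2, rescale_missing = TRUE) {
  if (ncol(g1) != ncol(g2) ||
      (!is.null(colnames(g1)) && !is.null(colnames(g2)) &&
       !identical(colnames(g1), colnames(g2))))
    stop_data("genotypes are scored at different locus sets")
  s <- shared_alleles(g1[1, ], g1[2, ], g2[1, ], g2[2, ])
  L <- ncol(g1)
  scored <- !is.na(s)
  m <- L - sum(scored)
  if (m == L) stop_data("no locus scored in both genotypes")
  d <- sum(2L - s[scored])
  if (rescale_missing && m > 0) d <- as.integer(round(d * L / (L - m)))
  as.integer(d)
}

#' Pairwise allelic-difference matrix between MLGs
#'
#' @param mlgs an [collapse_mlg()] partition (its MLG representatives are
#'   used), or a [genotype_panel()] whose rows are the units to compare.
#' @param rescale_missing see [pairwise_allele_distance()].
#' @return symmetric integer matrix with zero diagonal, dimnames = unit ids.
#' @export
distance_matrix <- function(mlgs, rescale_missing = TRUE) {
  panel <- if (inherits(mlgs, "mlg_partition")) mlgs$representatives else mlgs
  n <- n_individuals(panel)
  if (n < 2) stop_data("need at least 2 genotypes")
  ids <- panel$meta$individual
  d <- matrix(0L, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    gi1 <- panel$a1[i, ]; gi2 <- panel$a2[i, ]
    for (j in (i + 1):n) {
      s <- shared_alleles(gi1, gi2, panel$a1[j, ], panel$a2[j, ])
      scored <- !is.na(s)
      L <- length(s); m <- L - sum(scored)
      if (m == L) stop_data("no shared scored locus between ", ids[i],
                            " and ", ids[j])
      dij <- sum(2L - s[scored])
      if (rescale_missing && m > 0) dij <- as.integer(round(dij * L / (L - m)))
      d[i, j] <- d[j, i] <- dij
    }
  }
  d
}

#' Histogram of pairwise distances
#'
#' Counts the off-diagonal upper-triangle distances of a distance matrix,
#' zero-filling empty integer bins so the distribution can be scanned for
#' local minima. Distances of zero (impossible between distinct MLGs) get a
#' separate leading bin only if present.
#'
#' @param d symmetric integer distance matrix from [distance_matrix()].
#' @return named integer vector; names are the integer distances `1..max`.
#' @export
distance_histogram <- function(d) {
  ut <- d[upper.tri(d)]
  if (length(ut) == 0) stop_data("empty distance matrix")
  if (any(ut == 0))
    warning("zero distances between supposedly distinct genotypes")
  h <- tabulate(ut, nbins = max(ut))
  stats::setNames(as.integer(h), seq_len(max(ut)))
}

#' Detect the lineage-delimitation threshold from a distance histogram
#'
#' In a clonal dataset the pairwise allelic-distance distribution is
#' multimodal: a low-distance mode of within-lineage pairs (somatic
#' mutations, scoring errors) is separated from between-lineage pairs by a
#' gap. The threshold is the first local minimum of the zero-filled
#' histogram: the smallest distance `t >= 2` with `count(t) < count(t-1)`
#' and `count(t) <= count(t+1)` (ties resolved toward smaller `t`). MLGs
#' whose chain distance is strictly below the returned value belong to one
#' multilocus lineage (see [assign_mll()]).
#'
#' @param histogram named counts from [distance_histogram()].
#' @return integer threshold (the location of the first minimum).
#' @examples
#' h <- distance_histogram(distance_matrix(collapse_mlg(load_table1_fixture())))
#' detect_threshold(h)  # 5
#' @export
detect_threshold <- function(histogram) {
  h <- as.integer(histogram)
  if (length(h) < 3)
    stop_data("no threshold detectable: histogram support too short; supply one")
  for (d in 2:(length(h) - 1)) {
    if (h[d] < h[d - 1] && h[d] <= h[d + 1]) return(d)
  }
  stop_data("no threshold detectable: histogram has no interior local ",
            "minimum; supply a threshold explicitly")
}

#' Group MLGs into multilocus lineages (MLLs)
#'
#' Single-linkage grouping: two MLGs belong to the same MLL iff they are
#' connected by a chain of pairwise distances strictly below the threshold.
#' MLL ids are assigned deterministically, ordered by each component's
#' smallest member MLG id.
#'
#' @param d distance matrix from [distance_matrix()].
#' @param threshold integer cutoff; MLGs differing by `1 .. threshold-1`
#'   alleles (possibly through intermediates) are grouped.
#' @return an object of class `mll_partition`: list with `threshold`,
#'   `membership` (named MLG id -> MLL id), `mll_ids`, `members` (list of
#'   MLG ids per MLL).
#' @export
assign_mll <- function(d, threshold) {
  threshold <- as.integer(threshold)
  if (threshold < 1) stop_data("threshold must be >= 1")
  ids <- rownames(d)
  n <- nrow(d)
  adj <- d < threshold
  diag(adj) <- FALSE
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0L) next
    cid <- cid + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (comp[v] > 0L) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & comp == 0L))
    }
  }
  # order components by their smallest member MLG id
  first_member <- vapply(seq_len(cid), function(k) min(ids[comp == k]), "")
  ord <- order(first_member)
  relabel <- integer(cid); relabel[ord] <- seq_len(cid)
  comp <- relabel[comp]
  mll_ids <- pad_ids("MLL", max(comp))
  membership <- stats::setNames(mll_ids[comp], ids)
  structure(list(threshold = threshold, membership = membership,
                 mll_ids = mll_ids,
                 members = split(ids, membership)),
            class = "mll_partition")
}

#' @export
print.mll_partition <- function(x, ...) {
  cat("mll_partition:", length(x$mll_ids), "MLLs at threshold",
      x$threshold, "\n")
  sizes <- lengths(x$members)
  cat(paste0(names(sizes), " (", sizes, " MLGs)", collapse = ", "), "\n")
  invisible(x)
}

#' Probability of a multilocus genotype under sexual reproduction
#'
#' `p_gen` is the probability of drawing the given diploid genotype from the
#' population allele frequencies under random mating, optionally corrected
#' for a departure from Hardy-Weinberg proportions via the inbreeding
#' coefficient `f_is`: homozygotes have probability
#' `f_i^2 + f_i (1 - f_i) f_is`, heterozygotes `2 f_i f_j (1 - f_is)`.
#' With `f_is = 0` this reduces to the Hardy-Weinberg product
#' `prod(f_i f_j) * 2^h` over the used loci (`h` = heterozygous loci).
#'
#' @param genotype 2 x L allele matrix (see [panel_genotype()]).
#' @param freqs named list, one element per locus: a named numeric vector of
#'   allele frequencies (names = allele sizes). See
#'   [round_robin_frequencies()].
#' @param f_is inbreeding coefficient in `[-1, 1]` (default 0).
#' @param loci_used character vector of loci to include (default: all loci
#'   of `genotype` that appear in `freqs`).
#' @return probability in `[0, 1]`.
#' @export
p_gen <- function(genotype, freqs, f_is = 0, loci_used = NULL) {
  loci <- colnames(genotype) %||% names(freqs)
  loci_used <- loci_used %||% intersect(loci, names(freqs))
  if (!all(loci_used %in% names(freqs)))
    stop_data("no frequencies for loci: ",
              paste(setdiff(loci_used, names(freqs)), collapse = ", "))
  prob <- 1
  for (l in loci_used) {
    j <- match(l, loci)
    a <- genotype[1, j]; b <- genotype[2, j]
    if (is.na(a)) next
    f <- freqs[[l]]
    fa <- f[as.character(a)]; fb <- f[as.character(b)]
    if (is.na(fa) || is.na(fb))
      stop_data("allele ", a, "/", b, " at ", l, " absent from the ",
                "frequency table; estimate frequencies on a dataset ",
                "containing the genotype")
    prob <- prob * if (a == b) fa^2 + fa * (1 - fa) * f_is
                   else 2 * fa * fb * (1 - f_is)
  }
  min(max(unname(prob), 0), 1)
}

#' Probability that repeated genotype copies arose from distinct sexual events
#'
#' Given `p_gen`, the probability of producing the genotype in one sexual
#' reproductive event, `p_sex` is the binomial upper-tail probability of
#' observing at least `n_copies` occurrences among `N` sampled individuals:
#' `sum_{i >= n_copies} C(N, i) p_gen^i (1 - p_gen)^(N - i)`. Values below
#' 0.01 support a common clonal origin of the copies.
#'
#' @param p_gen probability from [p_gen()].
#' @param n_copies observed number of copies (>= 2).
#' @param N number of analysis units in the dataset.
#' @return probability in `[0, 1]`.
#' @export
p_sex <- function(p_gen, n_copies, N) {
  if (n_copies < 2) stop_data("a repeated genotype requires n_copies >= 2")
  if (n_copies > N) stop_data("n_copies cannot exceed N")
  stats::pbinom(n_copies - 1, N, p_gen, lower.tail = FALSE)
}

#' Round-robin allele frequencies
#'
#' Estimates allele frequencies at each locus from the unique multilocus
#' genotypes obtained when that locus is ignored (one representative per
#' distinct genotype over the remaining loci). This avoids inflating the
#' frequency of alleles carried by heavily replicated clones, which would
#' bias `p_gen` upward in clonal datasets.
#'
#' @param panel a [genotype_panel()] (typically the one-representative-per-
#'   sample reduction).
#' @param method `"round_robin"` (default) or `"overall"` (plain counts over
#'   all rows).
#' @return named list, one per locus, of named allele-frequency vectors.
#' @export
round_robin_frequencies <- function(panel, method = c("round_robin", "overall")) {
  method <- match.arg(method)
  L <- n_loci(panel)
  out <- vector("list", L)
  names(out) <- panel$loci
  for (j in seq_len(L)) {
    rows <- seq_len(n_individuals(panel))
    if (method == "round_robin" && L > 1) {
      reduced <- subset_panel(panel, rows)
      reduced$loci <- panel$loci[-j]
      reduced$a1 <- panel$a1[, -j, drop = FALSE]
      reduced$a2 <- panel$a2[, -j, drop = FALSE]
      rows <- rows[!duplicated(genotype_keys(reduced))]
    }
    alleles <- c(panel$a1[rows, j], panel$a2[rows, j])
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) stop_data("no scored allele at ", panel$loci[j])
    tab <- table(alleles)
    out[[j]] <- stats::setNames(as.numeric(tab) / sum(tab), names(tab))
  }
  out
}

#' p_sex report for each multilocus lineage
#'
#' Treats each MLL as one repeated genotype observed `n_copies` times (its
#' member observations among the analysis units) and evaluates [p_gen()] on
#' the *identical loci* of the lineage: the loci at which all member MLGs
#' carry the same allele pair. Lineages with a single observation carry no
#' repeat signal and get `NA`.
#'
#' @param panel the analysis-unit panel (e.g. one representative per
#'   sample); used for frequencies and `N`.
#' @param mlgs [collapse_mlg()] partition of `panel`.
#' @param mll [assign_mll()] partition of the MLG distance matrix.
#' @param freq_method passed to [round_robin_frequencies()].
#' @param f_is inbreeding coefficient used in [p_gen()]; `"estimate"`
#'   (default) uses the multilocus Weir-Cockerham estimate over the whole
#'   panel, or supply a number (0 gives the plain Hardy-Weinberg variant).
#' @return data frame with one row per MLL: `mll`, `n_mlg`, `n_copies`,
#'   `n_loci_used`, `p_gen`, `p_sex`.
#' @export
psex_report <- function(panel, mlgs, mll,
                        freq_method = c("round_robin", "overall"),
                        f_is = "estimate") {
  freq_method <- match.arg(freq_method)
  freqs <- round_robin_frequencies(panel, freq_method)
  if (identical(f_is, "estimate")) {
    grouping <- stats::setNames(rep("all", n_individuals(panel)),
                                panel$meta$individual)
    est <- fis_estimate(panel, grouping)$multilocus$fis
    f_is <- if (is.finite(est)) est else 0
  }
  N <- n_individuals(panel)
  reps <- mlgs$representatives
  rows <- lapply(mll$mll_ids, function(id) {
    members <- mll$members[[id]]
    idx <- match(members, reps$meta$individual)
    same <- rep(TRUE, n_loci(panel))
    for (j in seq_len(n_loci(panel))) {
      a1 <- reps$a1[idx, j]; a2 <- reps$a2[idx, j]
      same[j] <- length(unique(paste(a1, a2))) == 1 && !anyNA(a1)
    }
    loci_used <- panel$loci[same]
    n_copies <- sum(mlgs$membership %in% members)
    pg <- p_gen(panel_genotype(reps, members[1]), freqs, f_is,
                loci_used = loci_used)
    data.frame(mll = id, n_mlg = length(members), n_copies = n_copies,
               n_loci_used = length(loci_used), p_gen = pg,
               p_sex = if (n_copies >= 2) p_sex(pg, n_copies, N) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Clonal richness R = (G - 1) / (N - 1)
#'
#' Scales the number of distinct genotypes `G` (MLGs or MLLs) by the number
#' of analysis units `N`: 0 for a monoclonal dataset, 1 when every unit is
#' distinct. Reported rounded to 3 decimals.
#'
#' @param G number of genotypes detected (MLG or MLL count).
#' @param N number of analysis units (retained representatives).
#' @return object of class `clonal_richness`: list `G`, `N`, `R`.
#' @examples
#' clonal_richness(36, 98)$R  # 0.361
#' @export
clonal_richness <- function(G, N) {
  if (N < 2) stop_data("richness undefined for N < 2")
  if (G < 1 || G > N) stop_data("need 1 <= G <= N")
  structure(list(G = as.integer(G), N = as.integer(N),
                 R = round((G - 1) / (N - 1), 3)),
            class = "clonal_richness")
}

#' @export
print.clonal_richness <- function(x, ...) {
  cat("clonal richness R = (", x$G, "- 1)/(", x$N, "- 1) =", x$R, "\n")
  invisible(x)
}
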