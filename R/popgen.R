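#' Allele frequencies per population and locus
#'
#' Counts gene copies (2 per scored individual) and returns frequencies with
#' alleles ordered by size. Populations are defined by `grouping`, either a
#' metadata column name (`"sample"`, `"host"`, ...) or a vector of labels
#' named by individual id (e.g. an MLL assignment).
#'
#' @param panel a [genotype_panel()].
#' @param grouping population labels (column name or named vector).
#' @return data frame: `pop`, `locus`, `allele`, `count`, `freq`, `n_genes`.
#' @export
allele_frequencies <- function(panel, grouping) {
  g <- resolve_grouping(panel, grouping)
  out <- list()
  for (pop in levels(g)) {
    rows <- which(g == pop)
    if (length(rows) == 0) stop_data("empty population: ", pop)
    for (j in seq_along(panel$loci)) {
      alleles <- c(panel$a1[rows, j], panel$a2[rows, j])
      alleles <- alleles[!is.na(alleles)]
      if (length(alleles) == 0) next
      tab <- table(alleles)
      out[[length(out) + 1]] <- data.frame(
        pop = pop, locus = panel$loci[j],
        allele = as.integer(names(tab)), count = as.integer(tab),
        freq = as.numeric(tab) / length(alleles),
        n_genes = length(alleles))
    }
  }
  do.call(rbind, out)
}

#' Observed and unbiased expected heterozygosity
#'
#' `Ho` is the fraction of scored individuals heterozygous at the locus;
#' `He` is Nei's unbiased expected heterozygosity
#' `2n/(2n - 1) * (1 - sum(f_k^2))`. `He` is undefined (`NA`) for a single
#' individual.
#'
#' @inheritParams allele_frequencies
#' @return data frame: `pop`, `locus`, `n`, `Ho`, `He`.
#' @export
heterozygosity <- function(panel, grouping) {
  g <- resolve_grouping(panel, grouping)
  out <- list()
  for (pop in levels(g)) {
    rows <- which(g == pop)
    for (j in seq_along(panel$loci)) {
      a1 <- panel$a1[rows, j]; a2 <- panel$a2[rows, j]
      ok <- !is.na(a1)
      n <- sum(ok)
      if (n == 0) next
      ho <- mean(a1[ok] != a2[ok])
      f <- table(c(a1[ok], a2[ok])) / (2 * n)
      he <- if (n > 1) (2 * n / (2 * n - 1)) * (1 - sum(f^2)) else NA_real_
      out[[length(out) + 1]] <- data.frame(
        pop = pop, locus = panel$loci[j], n = n, Ho = ho, He = he)
    }
  }
  do.call(rbind, out)
}

# Weir & Cockerham (1984) variance components for one locus across r
# populations. Returns per-allele components a (among populations),
# b (among individuals within populations), c (within individuals).
# With a single population only b and c are meaningful.
wc_components <- function(a1_by_pop, a2_by_pop) {
  r <- length(a1_by_pop)
  ni <- vapply(a1_by_pop, function(x) sum(!is.na(x)), 0)
  keep <- ni > 0
  a1_by_pop <- a1_by_pop[keep]; a2_by_pop <- a2_by_pop[keep]; ni <- ni[keep]
  r <- length(ni)
  if (r == 0) return(NULL)
  alleles <- sort(unique(stats::na.omit(unlist(c(a1_by_pop, a2_by_pop)))))
  if (length(alleles) < 2) return(NULL)   # monomorphic locus: no information
  nbar <- mean(ni)
  nc <- if (r > 1) (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1) else NA_real_
  comp <- matrix(NA_real_, length(alleles), 3,
                 dimnames = list(alleles, c("a", "b", "c")))
  for (k in seq_along(alleles)) {
    A <- alleles[k]
    pi <- hi <- numeric(r)
    for (i in seq_len(r)) {
      x1 <- a1_by_pop[[i]]; x2 <- a2_by_pop[[i]]
      ok <- !is.na(x1)
      pi[i] <- (sum(x1[ok] == A) + sum(x2[ok] == A)) / (2 * ni[i])
      hi[i] <- mean(x1[ok] != x2[ok] & (x1[ok] == A | x2[ok] == A))
    }
    pbar <- sum(ni * pi) / sum(ni)
    hbar <- sum(ni * hi) / sum(ni)
    s2 <- if (r > 1) sum(ni * (pi - pbar)^2) / ((r - 1) * nbar) else 0
    inner <- pbar * (1 - pbar) - (r - 1) / r * s2
    a <- if (r > 1)
      (nbar / nc) * (s2 - (inner - hbar / 4) / (nbar - 1)) else NA_real_
    b <- if (nbar > 1)
      (nbar / (nbar - 1)) * (inner - (2 * nbar - 1) / (4 * nbar) * hbar)
      else NA_real_
    comp[k, ] <- c(a, b, hbar / 2)
  }
  comp
}

#' Weir-Cockerham F_IS estimates
#'
#' Per-locus and multilocus within-population inbreeding coefficient `f`
#' (Weir & Cockerham 1984), computed separately for each population. The
#' multilocus estimate is the ratio of summed variance components over
#' polymorphic loci; monomorphic loci carry no information and are
#' excluded. Long-term clonal populations show strongly negative `f`
#' (fixed heterozygosity).
#'
#' @inheritParams allele_frequencies
#' @return list with `per_locus` (data frame `pop`, `locus`, `fis`) and
#'   `multilocus` (data frame `pop`, `fis`).
#' @export
fis_estimate <- function(panel, grouping) {
  g <- resolve_grouping(panel, grouping)
  per <- list(); multi <- list()
  for (pop in levels(g)) {
    rows <- which(g == pop)
    sb <- sc <- 0
    for (j in seq_along(panel$loci)) {
      comp <- wc_components(list(panel$a1[rows, j]), list(panel$a2[rows, j]))
      fis <- NA_real_
      if (!is.null(comp)) {
        b <- sum(comp[, "b"]); cc <- sum(comp[, "c"])
        if (is.finite(b) && b + cc > 0) {
          fis <- 1 - cc / (b + cc)
          sb <- sb + b; sc <- sc + cc
        }
      }
      per[[length(per) + 1]] <- data.frame(pop = pop, locus = panel$loci[j],
                                           fis = fis)
    }
    multi[[length(multi) + 1]] <- data.frame(
      pop = pop, fis = if (sb + sc > 0) 1 - sc / (sb + sc) else NA_real_)
  }
  list(per_locus = do.call(rbind, per), multilocus = do.call(rbind, multi))
}

#' Monte-Carlo exact test of Hardy-Weinberg proportions
#'
#' Alleles within the population (and locus) are randomly re-paired into
#' diploid genotypes, which samples the exact null distribution conditional
#' on the allele counts. The two-sided statistic is the conditional
#' probability of the genotype table (tables no more probable than the
#' observed one count as extreme); the one-sided statistics are the
#' heterozygote count (`"excess"`: permuted Ho >= observed counts as
#' extreme; `"deficit"`: <=). The p-value uses the add-one estimator
#' `(1 + k)/(1 + n_perm)`, so it is never exactly zero. With `locus = NULL`
#' the statistic is summed over all polymorphic loci (alleles re-paired
#' independently per locus), giving a multilocus test.
#'
#' @inheritParams allele_frequencies
#' @param pop population label to test.
#' @param locus locus name, or `NULL` for the multilocus version.
#' @param alternative `"two_sided"`, `"excess"` or `"deficit"`.
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed; the test is reproducible given `(seed, n_perm)`.
#' @return list: `p`, `statistic`, `alternative`, `n_perm`, `loci`.
#' @export
hwe_test <- function(panel, grouping, pop, locus = NULL,
                     alternative = c("two_sided", "excess", "deficit"),
                     n_perm = 1000, seed = 1) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stop_data("n_perm must be >= 100")
  g <- resolve_grouping(panel, grouping)
  rows <- which(g == pop)
  if (length(rows) == 0) stop_data("empty population: ", pop)
  loci <- locus %||% panel$loci
  if (!all(loci %in% panel$loci)) stop_data("unknown locus: ", locus)

  # per-locus allele vectors; drop monomorphic or unscored loci
  allele_sets <- list()
  for (l in loci) {
    j <- match(l, panel$loci)
    a1 <- panel$a1[rows, j]; a2 <- panel$a2[rows, j]
    ok <- !is.na(a1)
    if (sum(ok) == 0) next
    if (length(unique(c(a1[ok], a2[ok]))) < 2) next
    allele_sets[[l]] <- rbind(a1[ok], a2[ok])
  }
  if (length(allele_sets) == 0) {
    warning("monomorphic at the tested loci; p = 1 by convention")
    return(list(p = 1, statistic = NA_real_, alternative = alternative,
                n_perm = n_perm, loci = character(0)))
  }

  stat_fun <- switch(alternative,
    excess = ,
    deficit = function(x1, x2) sum(x1 != x2),
    two_sided = function(x1, x2) {
      # log conditional probability of the genotype table given allele
      # counts, up to a constant: H*log(2) - sum(log(n_ij!))
      het <- sum(x1 != x2)
      key <- paste(pmin(x1, x2), pmax(x1, x2))
      het * log(2) - sum(lgamma(table(key) + 1))
    })

  obs <- sum(vapply(allele_sets, function(m) stat_fun(m[1, ], m[2, ]), 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  perm_stat <- numeric(n_perm)
  pooled <- lapply(allele_sets, function(m) as.vector(m))
  for (b in seq_len(n_perm)) {
    s <- 0
    for (x in pooled) {
      xp <- x[sample.int(length(x))]
      half <- length(xp) / 2
      s <- s + stat_fun(xp[seq_len(half)], xp[half + seq_len(half)])
    }
    perm_stat[b] <- s
  }
  eps <- 1e-9
  k <- switch(alternative,
    excess = sum(perm_stat >= obs - eps),
    deficit = sum(perm_stat <= obs + eps),
    two_sided = sum(perm_stat <= obs + eps))
  list(p = (1 + k) / (1 + n_perm), statistic = obs,
       alternative = alternative, n_perm = n_perm,
       loci = names(allele_sets))
}

#' Weir-Cockerham pairwise F_ST (theta)
#'
#' Multi-allelic, multilocus theta as the ratio of summed variance
#' components (Weir & Cockerham 1984). With `popA`/`popB` given, returns
#' the scalar estimate for that pair; otherwise the full symmetric matrix
#' over all populations in `grouping`.
#'
#' @inheritParams allele_frequencies
#' @param popA,popB optional pair of population labels.
#' @return numeric scalar, or matrix with population dimnames.
#' @export
pairwise_fst <- function(panel, grouping, popA = NULL, popB = NULL) {
  g <- resolve_grouping(panel, grouping)
  theta_pair <- function(p, q) {
    ra <- which(g == p); rb <- which(g == q)
    if (length(ra) == 0 || length(rb) == 0)
      stop_data("empty population in pair ", p, "/", q)
    sa <- stot <- 0
    usable <- FALSE
    for (j in seq_along(panel$loci)) {
      comp <- wc_components(
        list(panel$a1[ra, j], panel$a1[rb, j]),
        list(panel$a2[ra, j], panel$a2[rb, j]))
      if (is.null(comp) || anyNA(comp[, "a"])) next
      usable <- TRUE
      sa <- sa + sum(comp[, "a"])
      stot <- stot + sum(comp)
    }
    if (!usable || stot == 0) stop_data("no usable polymorphic locus for ",
                                        p, "/", q)
    sa / stot
  }
  if (!is.null(popA)) {
    if (is.null(popB)) stop_data("supply both popA and popB")
    return(theta_pair(popA, popB))
  }
  pops <- levels(g)
  th <- matrix(NA_real_, length(pops), length(pops),
               dimnames = list(pops, pops))
  diag(th) <- 0
  for (i in seq_along(pops)[-1]) for (j in seq_len(i - 1))
    th[i, j] <- th[j, i] <- theta_pair(pops[i], pops[j])
  th
}

#' Genic G-test of population differentiation
#'
#' Per locus, builds the alleles x populations contingency table of gene
#' copies and computes the log-likelihood-ratio statistic
#' `G = 2 * sum(o * ln(o/e))`. The global statistic sums G over loci
#' (Fisher's combination over independently segregating loci). Significance
#' is assessed by permuting individuals among populations, which preserves
#' the diploid structure of the data.
#'
#' @inheritParams allele_frequencies
#' @param n_perm permutations for the p-values.
#' @param seed integer seed.
#' @return list: `per_locus` (data frame `locus`, `G`, `df`, `p`),
#'   `global_G`, `global_df`, `global_p`, `n_perm`.
#' @export
g_test_differentiation <- function(panel, grouping, n_perm = 999, seed = 1) {
  g <- resolve_grouping(panel, grouping)
  if (nlevels(g) < 2) stop_data("need at least 2 populations")
  g_stat <- function(labels, j) {
    ok <- !is.na(panel$a1[, j])
    alle <- c(panel$a1[ok, j], panel$a2[ok, j])
    pops <- rep(labels[ok], 2)
    tab <- table(alle, pops)
    if (nrow(tab) < 2 || ncol(tab) < 2) return(c(G = 0, df = 0))
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    o <- as.numeric(tab)
    nz <- o > 0
    c(G = 2 * sum(o[nz] * log(o[nz] / as.numeric(e)[nz])),
      df = (nrow(tab) - 1) * (ncol(tab) - 1))
  }
  L <- length(panel$loci)
  obs <- vapply(seq_len(L), function(j) g_stat(g, j), c(G = 0, df = 0))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  k_locus <- numeric(L); k_global <- 0
  for (b in seq_len(n_perm)) {
    gp <- g[sample.int(length(g))]
    Gs <- vapply(seq_len(L), function(j) g_stat(gp, j)[["G"]], 0)
    k_locus <- k_locus + (Gs >= obs["G", ] - 1e-9)
    k_global <- k_global + (sum(Gs) >= sum(obs["G", ]) - 1e-9)
  }
  list(per_locus = data.frame(locus = panel$loci, G = obs["G", ],
                              df = obs["df", ],
                              p = (1 + k_locus) / (1 + n_perm)),
       global_G = sum(obs["G", ]), global_df = sum(obs["df", ]),
       global_p = (1 + k_global) / (1 + n_perm), n_perm = n_perm)
}
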