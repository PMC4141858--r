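# small builders and independent oracles shared across tests

# build a panel from a list of genotypes; each genotype is a list of
# c(a1, a2) pairs, one per locus
make_panel <- function(genotypes, sample = NULL, locality = "loc1",
                       host = "sorghum", loci = NULL) {
  n <- length(genotypes)
  L <- length(genotypes[[1]])
  loci <- loci %||% paste0("L", seq_len(L))
  a1 <- t(vapply(genotypes, function(g)
    vapply(g, function(p) as.integer(min(p)), 0L), integer(L)))
  a2 <- t(vapply(genotypes, function(g)
    vapply(g, function(p) as.integer(max(p)), 0L), integer(L)))
  if (L == 1) { a1 <- matrix(a1, ncol = 1); a2 <- matrix(a2, ncol = 1) }
  genotype_panel(
    data.frame(individual = paste0("ind", seq_len(n)),
               sample = sample %||% rep("s1", n),
               locality = locality, host = host),
    a1, a2, loci)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent allelic-distance oracle: per locus, count shared alleles via
# explicit multiset tabulation (different code path from the package)
oracle_distance <- function(panel, i, j) {
  total <- 0L
  for (l in seq_along(panel$loci)) {
    x <- c(panel$a1[i, l], panel$a2[i, l])
    y <- c(panel$a1[j, l], panel$a2[j, l])
    if (anyNA(x) || anyNA(y)) next
    shared <- 0L
    pool <- y
    for (a in x) {
      hit <- match(a, pool)
      if (!is.na(hit)) { shared <- shared + 1L; pool <- pool[-hit] }
    }
    total <- total + 2L - shared
  }
  total
}

# decode a Pruefer sequence into a tree edge list on nodes 1..n
pruefer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1, 2)
  k <- 0L
  for (v in seq) {
    leaf <- min(which(degree == 1L))
    k <- k + 1L
    edges[k, ] <- c(leaf, v)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  edges[n - 1, ] <- last
  edges
}

# enumerate all spanning trees of the complete graph on n nodes (n <= 7),
# returning the minimum weight and the set of edges occurring in some
# minimum spanning tree (as "i-j" labels with i < j)
all_mst_edges <- function(d) {
  n <- nrow(d)
  stopifnot(n <= 7)
  if (n == 2) return(list(weight = d[1, 2], edges = "1-2"))
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
  best <- Inf
  edge_set <- character(0)
  for (r in seq_len(nrow(seqs))) {
    ed <- pruefer_decode(seqs[r, ], n)
    w <- sum(d[ed])
    labs <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]), sep = "-")
    if (w < best - 1e-9) { best <- w; edge_set <- labs }
    else if (abs(w - best) < 1e-9) edge_set <- union(edge_set, labs)
  }
  list(weight = best, edges = sort(edge_set))
}

# random symmetric integer distance matrix with positive off-diagonal
random_distance_matrix <- function(n, max_d = 9) {
  d <- matrix(0L, n, n)
  ut <- upper.tri(d)
  d[ut] <- sample.int(max_d, sum(ut), replace = TRUE)
  d <- d + t(d)
  dimnames(d) <- list(pad_ids_test("N", n), pad_ids_test("N", n))
  d
}

pad_ids_test <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", nchar(n), "d"), seq_len(n))
}

# write a tiny aligned FASTA and return the path
write_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) writeLines(c(paste0(">", id), seqs[[id]]), con)
  path
}

# map an assigned partition onto reference labels and test for identity
same_partition <- function(a, b) {
  stopifnot(length(a) == length(b))
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
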