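table1 <- load_table1_fixture()
table1_mlgs <- collapse_mlg(table1)
table1_d <- distance_matrix(table1_mlgs)

test_that("identical genotypes collapse to one MLG with the right counts", {
  g <- list(c(189, 203), c(215, 215))
  panel <- make_panel(rep(list(g), 5))
  mlgs <- collapse_mlg(panel)
  expect_equal(length(mlgs$mlg_ids), 1)
  expect_equal(unname(mlgs$counts), 5L)

  base <- list(list(c(189, 203), c(215, 215)), list(c(189, 189), c(215, 215)),
               list(c(197, 199), c(213, 215)), list(c(197, 197), c(213, 213)))
  reps <- c(8, 6, 4, 2)
  panel2 <- make_panel(rep(base, reps))
  mlgs2 <- collapse_mlg(panel2)
  expect_equal(length(mlgs2$mlg_ids), 4)
  expect_equal(sort(unname(mlgs2$counts)), sort(reps))
  expect_equal(sum(mlgs2$counts), 20)
})

test_that("MLG ids are deterministic under row reordering", {
  set.seed(5)
  shuffled <- subset_panel(table1, sample.int(36))
  m1 <- collapse_mlg(table1); m2 <- collapse_mlg(shuffled)
  expect_identical(m1$mlg_ids, m2$mlg_ids)
  expect_identical(m1$representatives$a1, m2$representatives$a1)
  expect_identical(sort(names(m1$membership)), sort(names(m2$membership)))
  expect_identical(m1$membership[names(m2$membership)], m2$membership)
})

test_that("all-missing individuals are excluded with a warning", {
  panel <- make_panel(list(list(c(189, 203)), list(c(189, 189))))
  panel$a1[2, ] <- panel$a2[2, ] <- NA_integer_
  expect_warning(mlgs <- collapse_mlg(panel), "missing")
  expect_equal(length(mlgs$membership), 1)
})

test_that("one representative per (sample, MLG) is retained, idempotently", {
  g <- list(c(189, 203), c(215, 215))
  panel <- make_panel(rep(list(g), 5))
  red <- representative_per_sample(panel, collapse_mlg(panel))
  expect_equal(n_individuals(red), 1)

  panel2 <- make_panel(rep(list(g), 4), sample = c("s1", "s1", "s2", "s2"))
  red2 <- representative_per_sample(panel2, collapse_mlg(panel2))
  expect_equal(n_individuals(red2), 2)
  expect_equal(sort(unique(red2$meta$sample)), c("s1", "s2"))

  # idempotence and brute-force recount on a simulated multi-sample panel
  sim <- simulate_clonal_dataset(sim_config(seed = 21, n_samples = 57,
                                            total_individuals = 400,
                                            max_mutations_per_individual = 2))
  mlgs <- collapse_mlg(sim$panel)
  red3 <- representative_per_sample(sim$panel, mlgs)
  expected <- sum(vapply(split(mlgs$membership[sim$panel$meta$individual],
                               sim$panel$meta$sample),
                         function(x) length(unique(x)), 0L))
  expect_equal(n_individuals(red3), expected)
  red4 <- representative_per_sample(red3, collapse_mlg(red3))
  expect_identical(red4$meta, red3$meta)
})

test_that("allelic distance counts shared alleles per locus", {
  expect_equal(pairwise_allele_distance(panel_genotype(table1, "Ms1"),
                                        panel_genotype(table1, "Ms2")), 1L)
  expect_equal(pairwise_allele_distance(panel_genotype(table1, "Ms5"),
                                        panel_genotype(table1, "Ms30")), 2L)
  g <- panel_genotype(table1, "Ms11")
  expect_equal(pairwise_allele_distance(g, g), 0L)
  # one shared allele in shifted pairs counts a single difference
  a <- rbind(a1 = 206L, a2 = 210L); b <- rbind(a1 = 204L, a2 = 206L)
  expect_equal(pairwise_allele_distance(a, b), 1L)
  expect_error(pairwise_allele_distance(g, g[, 1:5]), "locus")
})

test_that("the distance matrix agrees with a brute-force oracle", {
  for (i in 1:35) for (j in (i + 1):36) {
    expect_equal(table1_d[i, j], oracle_distance(table1_mlgs$representatives, i, j))
  }
  expect_true(all(diag(table1_d) == 0))
  expect_identical(table1_d, t(table1_d))
  expect_equal(min(table1_d[upper.tri(table1_d)]), 1L)
  expect_true(all(table1_d <= 20))
})

test_that("the allelic distance is a metric on the reference genotypes", {
  # triangle inequality over all ordered triples via matrix comparison
  for (k in 1:36) {
    slack <- outer(table1_d[, k], table1_d[k, ], "+") - table1_d
    expect_true(all(slack >= 0))
  }
})

test_that("missing loci are skipped and the distance rescaled", {
  panel <- make_panel(list(
    list(c(189, 203), c(215, 215), c(213, 213), c(197, 199)),
    list(c(189, 205), c(215, 215), c(213, 213), c(197, 199))))
  panel$a1[2, 2] <- panel$a2[2, 2] <- NA_integer_
  g1 <- panel_genotype(panel, 1); g2 <- panel_genotype(panel, 2)
  # 1 difference over 3 scored loci, rescaled by 4/3 and rounded
  expect_equal(pairwise_allele_distance(g1, g2), round(1 * 4 / 3))
  expect_equal(pairwise_allele_distance(g1, g2, rescale_missing = FALSE), 1L)
})

test_that("the distance histogram tallies the upper triangle", {
  h <- distance_histogram(table1_d)
  expect_equal(sum(h), 36 * 35 / 2)
  brute <- table(factor(table1_d[upper.tri(table1_d)],
                        levels = seq_along(h)))
  expect_equal(unname(h), as.integer(brute))
  # single pair
  d2 <- matrix(c(0L, 3L, 3L, 0L), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(distance_histogram(d2), c("1" = 0L, "2" = 0L, "3" = 1L))
})

test_that("the first local minimum of the distance distribution is detected", {
  expect_equal(detect_threshold(distance_histogram(table1_d)), 5)
  expect_error(detect_threshold(c(1, 2, 3, 4, 5)), "no threshold")
  expect_equal(detect_threshold(c("1" = 10, "2" = 3, "3" = 0, "4" = 1,
                                  "5" = 8, "6" = 20)), 3)
  expect_error(detect_threshold(c(5, 4)), "no threshold")
})

test_that("MLL assignment is single-linkage below the threshold", {
  mll <- assign_mll(table1_d, 5)
  expect_equal(length(mll$mll_ids), 5)
  printed <- attr(table1, "mll")
  assigned <- mll$membership[table1_mlgs$membership[names(printed)]]
  expect_true(same_partition(unname(printed), unname(assigned)))
  expect_equal(sort(unname(lengths(mll$members))), c(2L, 2L, 4L, 8L, 20L))

  # threshold 1: minimum off-diagonal distance is 1, so no grouping at all
  mll1 <- assign_mll(table1_d, 1)
  expect_equal(length(mll1$mll_ids), 36)

  # chain grouping: A-B = 3, B-C = 3, A-C = 6 joins all three at threshold 4
  d <- matrix(c(0, 3, 6, 3, 0, 3, 6, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_equal(length(assign_mll(d, 4)$mll_ids), 1)
  expect_equal(length(assign_mll(d, 3)$mll_ids), 3)
})

test_that("within-lineage distances sit below, between-lineage above, the threshold", {
  printed <- attr(table1, "mll")
  lab <- printed[table1_mlgs$representatives$meta$source_individual]
  same <- outer(lab, lab, "==")
  ut <- upper.tri(table1_d)
  expect_lte(max(table1_d[ut & same]), 4)
  expect_gte(min(table1_d[ut & !same]), 5)
})

test_that("p_gen follows the inbreeding-corrected genotype probability", {
  g_het <- rbind(a1 = 189L, a2 = 203L)
  colnames(g_het) <- "L1"
  freqs <- list(L1 = c("189" = 0.5, "203" = 0.5))
  expect_equal(p_gen(g_het, freqs), 0.5)
  g_hom <- rbind(a1 = 189L, a2 = 189L); colnames(g_hom) <- "L1"
  expect_equal(p_gen(g_hom, list(L1 = c("189" = 1))), 1)
  g2 <- cbind(g_het, g_het); colnames(g2) <- c("L1", "L2")
  freqs2 <- list(L1 = freqs$L1, L2 = freqs$L1)
  expect_equal(p_gen(g2, freqs2), 0.25)
  # F_IS correction: heterozygote excess (negative F) raises het probability
  expect_equal(p_gen(g_het, freqs, f_is = -1), 1)
  expect_equal(p_gen(g_hom, list(L1 = c("189" = 0.5, "203" = 0.5)),
                     f_is = 0.5), 0.25 + 0.25 * 0.5)
  expect_error(p_gen(g_het, list(L1 = c("189" = 1))), "absent")
})

test_that("p_sex is the binomial upper tail and is monotone", {
  expect_equal(p_sex(0.5, 2, 2), 0.25)
  expect_equal(p_sex(0, 2, 10), 0)
  expect_equal(p_sex(1, 2, 10), 1)
  expect_error(p_sex(0.5, 1, 10), "n_copies")
  for (n_copies in c(2, 3, 5)) {
    grid_p <- seq(0.01, 0.9, length.out = 12)
    vals <- vapply(grid_p, p_sex, 0, n_copies = n_copies, N = 20)
    expect_true(all(diff(vals) >= 0))
    grid_N <- seq(n_copies, 60, by = 4)
    vals_N <- vapply(grid_N, function(N) p_sex(0.05, n_copies, N), 0)
    expect_true(all(diff(vals_N) >= -1e-12))
  }
})

test_that("round-robin frequencies are proper distributions", {
  freqs <- round_robin_frequencies(table1)
  expect_equal(names(freqs), table1$loci)
  for (f in freqs) expect_equal(sum(f), 1)
  overall <- round_robin_frequencies(table1, "overall")
  for (f in overall) expect_equal(sum(f), 1)
})

test_that("p_sex supports clonal identity of each reference lineage", {
  mll <- assign_mll(table1_d, 5)
  rep_report <- psex_report(table1, table1_mlgs, mll)
  expect_equal(nrow(rep_report), 5)
  expect_true(all(rep_report$p_sex < 0.01))
  expect_true(all(rep_report$p_gen >= 0 & rep_report$p_gen <= 1))
  expect_true(all(rep_report$n_loci_used >= 1))
})

test_that("clonal richness scales genotype counts by sample size", {
  expect_equal(clonal_richness(36, 98)$R, 0.361)
  expect_equal(clonal_richness(5, 98)$R, 0.041)
  expect_equal(clonal_richness(1, 50)$R, 0)
  expect_equal(clonal_richness(98, 98)$R, 1)
  expect_error(clonal_richness(5, 1), "N < 2")
  expect_error(clonal_richness(0, 10), "G")
})
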