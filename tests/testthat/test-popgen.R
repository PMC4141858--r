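test_that("allele frequencies count gene copies per population", {
  panel <- make_panel(list(list(c(189, 203)), list(c(189, 189))))
  f <- allele_frequencies(panel, "sample")
  expect_equal(f$freq[f$allele == 189], 0.75)
  expect_equal(f$freq[f$allele == 203], 0.25)
  expect_equal(unique(f$n_genes), 4)

  mono <- make_panel(rep(list(list(c(215, 215))), 4))
  fm <- allele_frequencies(mono, "sample")
  expect_equal(fm$freq, 1)

  # every published lineage-A genotype is 229/229 at the first locus
  p <- load_table1_fixture()
  a_rows <- names(attr(p, "mll"))[attr(p, "mll") == "A"]
  fa <- allele_frequencies(subset_panel(p, a_rows),
                           stats::setNames(rep("A", 20), a_rows))
  g08 <- fa[fa$locus == "CIR-Ms-G08", ]
  expect_equal(g08$allele, 229)
  expect_equal(g08$freq, 1)
})

test_that("observed and unbiased expected heterozygosity match closed forms", {
  panel <- make_panel(list(list(c(189, 203)), list(c(189, 189))))
  h <- heterozygosity(panel, "sample")
  expect_equal(h$Ho, 0.5)
  expect_equal(h$He, (4 / 3) * (1 - 0.75^2 - 0.25^2))

  allhet <- make_panel(rep(list(list(c(189, 203))), 6))
  expect_equal(heterozygosity(allhet, "sample")$Ho, 1)
  mono <- make_panel(rep(list(list(c(215, 215))), 4))
  hm <- heterozygosity(mono, "sample")
  expect_equal(hm$Ho, 0); expect_equal(hm$He, 0)
  single <- make_panel(list(list(c(189, 203))))
  expect_true(is.na(heterozygosity(single, "sample")$He))
})

test_that("F_IS is -1 under fixed heterozygosity and ~0 under random mating", {
  allhet <- make_panel(rep(list(list(c(189, 203))), 10))
  fis <- fis_estimate(allhet, "sample")
  expect_equal(fis$per_locus$fis, -1)
  expect_equal(fis$multilocus$fis, -1)

  pan <- simulate_panmictic_panel(500, n_loci = 4, n_alleles = 4, seed = 17)
  fis2 <- fis_estimate(pan, "locality")
  expect_lt(abs(fis2$multilocus$fis), 0.05)

  # monomorphic loci are excluded: lineage C is fixed 213/213 at CIR-Ms-B03
  p <- load_table1_fixture()
  c_rows <- names(attr(p, "mll"))[attr(p, "mll") == "C"]
  fc <- fis_estimate(subset_panel(p, c_rows),
                     stats::setNames(rep("C", 8), c_rows))
  expect_true(is.na(fc$per_locus$fis[fc$per_locus$locus == "CIR-Ms-B03"]))
  expect_true(is.finite(fc$multilocus$fis))
})

test_that("the heterozygote-excess permutation test flags fixed heterozygosity", {
  allhet <- make_panel(rep(list(list(c(189, 203))), 20))
  res <- hwe_test(allhet, "sample", "s1", "L1", alternative = "excess",
                  n_perm = 2000, seed = 3)
  expect_lte(res$p, 0.01)
  # deficit on the same data is non-significant
  res_def <- hwe_test(allhet, "sample", "s1", "L1", alternative = "deficit",
                      n_perm = 500, seed = 3)
  expect_gt(res_def$p, 0.5)
  # monomorphic convention
  mono <- make_panel(rep(list(list(c(215, 215))), 6))
  expect_warning(pm <- hwe_test(mono, "sample", "s1", "L1", n_perm = 100),
                 "monomorphic")
  expect_equal(pm$p, 1)
  # reproducible under (seed, n_perm); p in (0, 1]
  r1 <- hwe_test(allhet, "sample", "s1", "L1", n_perm = 300, seed = 9)
  r2 <- hwe_test(allhet, "sample", "s1", "L1", n_perm = 300, seed = 9)
  expect_identical(r1$p, r2$p)
  expect_true(r1$p > 0 && r1$p <= 1)
})

test_that("theta matches hand-computed Weir-Cockerham components", {
  # pop A: 10 AA + 10 aa; pop B: 10 Aa + 10 aa; A = 100 bp, a = 102 bp
  gts <- c(rep(list(list(c(100, 100))), 10), rep(list(list(c(102, 102))), 10),
           rep(list(list(c(100, 102))), 10), rep(list(list(c(102, 102))), 10))
  panel <- make_panel(gts, sample = rep(c("A", "B"), each = 20))
  th <- pairwise_fst(panel, "sample", "A", "B")
  # independent hand evaluation of the 1984 variance components:
  # nbar = 20, nc = 20, and per allele a = 0.023026316, b = 0.101973684,
  # c = 0.125, identical for both alleles, so theta = a/(a+b+c) = 7/76
  expect_equal(th, 7 / 76, tolerance = 1e-12)

  # full matrix form agrees with the scalar form
  m <- pairwise_fst(panel, "sample")
  expect_equal(m["A", "B"], th)
})

test_that("theta hits the boundary cases", {
  fixedA <- rep(list(list(c(100, 100), c(120, 120))), 10)
  fixedB <- rep(list(list(c(104, 104), c(126, 126))), 10)
  panel <- make_panel(c(fixedA, fixedB), sample = rep(c("A", "B"), each = 10))
  expect_equal(pairwise_fst(panel, "sample", "A", "B"), 1)

  pan <- simulate_panmictic_panel(400, n_loci = 8, n_alleles = 5, seed = 29,
                                  n_samples = 2)
  expect_lt(abs(pairwise_fst(pan, "sample", "S01", "S02")), 0.02)

  mono <- make_panel(rep(list(list(c(215, 215))), 8),
                     sample = rep(c("A", "B"), each = 4))
  expect_error(pairwise_fst(mono, "sample", "A", "B"), "polymorphic")
})

test_that("the genic G test matches the hand formula and its permutation null", {
  # identical allele counts in both populations
  g <- list(c(189, 203))
  panel <- make_panel(rep(list(g), 10), sample = rep(c("A", "B"), each = 5))
  res <- g_test_differentiation(panel, "sample", n_perm = 199, seed = 1)
  expect_equal(res$global_G, 0)
  expect_equal(res$global_p, 1)

  # fixed difference: pops contribute 20 copies of each private allele
  panel2 <- make_panel(c(rep(list(list(c(100, 100))), 10),
                         rep(list(list(c(104, 104))), 10)),
                       sample = rep(c("A", "B"), each = 10))
  res2 <- g_test_differentiation(panel2, "sample", n_perm = 1999, seed = 2)
  expect_equal(res2$global_G, 2 * (20 * log(2) + 20 * log(2)), tolerance = 1e-9)
  expect_lte(res2$global_p, 0.001)
  expect_error(g_test_differentiation(panel, "locality"), "2 populations")
})
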