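test_that("without mutation every individual carries its founder genotype", {
  cfg <- sim_config(seed = 2, n_lineages = 3, mutation_rate = 0,
                    n_samples = 6, total_individuals = 60,
                    lineage_weights = rep(1, 3))
  sim <- simulate_clonal_dataset(cfg)
  expect_equal(n_individuals(sim$panel), 60)
  mlgs <- collapse_mlg(sim$panel)
  expect_equal(length(mlgs$mlg_ids), 3)
  expect_equal(nrow(sim$truth$mutation_log), 0)
  # MLG partition coincides with the truth partition
  expect_true(same_partition(unname(mlgs$membership[sim$panel$meta$individual]),
                             unname(sim$truth$lineage[sim$panel$meta$individual])))
})

test_that("the generator is deterministic under (config, seed)", {
  cfg <- preset_study_scale(seed = 5)
  s1 <- simulate_clonal_dataset(cfg)
  s2 <- simulate_clonal_dataset(cfg)
  expect_identical(s1$panel$a1, s2$panel$a1)
  expect_identical(s1$panel$a2, s2$panel$a2)
  expect_identical(s1$panel$meta, s2$panel$meta)
  expect_identical(s1$truth$lineage, s2$truth$lineage)
  c1 <- simulate_coi(cfg, s1$truth)
  c2 <- simulate_coi(cfg, s2$truth)
  expect_identical(c1$seqs, c2$seqs)
  s3 <- simulate_clonal_dataset(preset_study_scale(seed = 6))
  expect_false(identical(s1$panel$a1, s3$panel$a1))
})

test_that("founders are spaced at least founder_min_distance apart", {
  for (seed in c(1, 8, 15)) {
    cfg <- sim_config(seed = seed, total_individuals = 50, n_samples = 5)
    sim <- simulate_clonal_dataset(cfg)
    f <- sim$truth$founders
    panel <- genotype_panel(
      data.frame(individual = paste0("L", seq_len(nrow(f$a1))),
                 sample = "f", locality = "f", host = "f"),
      f$a1, f$a2, sim$panel$loci)
    d <- distance_matrix(panel)
    expect_gte(min(d[upper.tri(d)]), cfg$founder_min_distance)
  }
})

test_that("scoring errors shift alleles at the configured binomial rate", {
  cfg <- sim_config(seed = 3, mutation_rate = 0, total_individuals = 1000,
                    n_samples = 10)
  sim <- simulate_clonal_dataset(cfg)
  expect_identical(apply_genotyping_error(sim$panel, 0), sim$panel)

  all_shift <- apply_genotyping_error(sim$panel, 1, seed = 4)
  delta <- abs(c(all_shift$a1, all_shift$a2) - c(sim$panel$a1, sim$panel$a2))
  # every call moved one motif; sorting within pairs can swap slots, so
  # compare multisets per pair instead of slots where sizes collide
  moved <- abs(all_shift$a1 - sim$panel$a1) + abs(all_shift$a2 - sim$panel$a2)
  expect_true(all(moved >= 2 | moved == 0))  # 0 only when +2/-2 swap collides
  expect_gt(mean(delta > 0), 0.9)

  err <- apply_genotyping_error(sim$panel, 0.01, seed = 5)
  n_changed <- sum(err$a1 != sim$panel$a1) + sum(err$a2 != sim$panel$a2)
  expected <- 2 * 1000 * 10 * 0.01
  sigma <- sqrt(expected * 0.99)
  expect_lt(abs(n_changed - expected), 3.5 * sigma)
})

test_that("the full pipeline recovers the simulated lineages", {
  for (seed in c(101, 102, 103)) {
    sim <- simulate_clonal_dataset(preset_study_scale(seed = seed))
    mlgs <- collapse_mlg(sim$panel)
    red <- representative_per_sample(sim$panel, mlgs)
    mlgs_r <- collapse_mlg(red)
    d <- distance_matrix(mlgs_r)
    h <- distance_histogram(d)
    thr <- detect_threshold(h)
    truth_of_mlg <- sim$truth$lineage[mlgs_r$representatives$meta$source_individual]
    same <- outer(truth_of_mlg, truth_of_mlg, "==")[upper.tri(d)]
    within_max <- max(d[upper.tri(d)][same])
    between_min <- min(d[upper.tri(d)][!same])
    expect_gt(thr, within_max)
    expect_lte(thr, between_min)
    mll <- assign_mll(d, thr)
    assigned <- mll$membership[mlgs_r$membership[red$meta$individual]]
    truth <- sim$truth$lineage[red$meta$individual]
    expect_true(same_partition(unname(assigned), unname(truth)))
    expect_equal(mclust::adjustedRandIndex(assigned, truth), 1)
  }
})

test_that("clonal panels show the fixed-heterozygosity signature", {
  sim <- simulate_clonal_dataset(sim_config(seed = 51, n_samples = 20,
                                            total_individuals = 400,
                                            lineage_weights = rep(1, 5),
                                            max_mutations_per_individual = 2))
  red <- representative_per_sample(sim$panel, collapse_mlg(sim$panel))
  fis <- fis_estimate(red, sim$truth$lineage[red$meta$individual])
  expect_equal(nrow(fis$multilocus), 5)
  expect_true(all(fis$multilocus$fis < 0))
})

test_that("simulated COI panels mirror the lineage structure", {
  cfg <- sim_config(seed = 23, n_lineages = 1, n_samples = 4,
                    total_individuals = 12, coi_substitutions = 0)
  sim <- simulate_clonal_dataset(cfg)
  hp <- simulate_coi(cfg, sim$truth)
  expect_equal(length(unique(hp$seqs)), 1)

  cfg5 <- sim_config(seed = 24, n_samples = 10, total_individuals = 96,
                     lineage_weights = rep(1, 5))
  sim5 <- simulate_clonal_dataset(cfg5)
  hp5 <- simulate_coi(cfg5, sim5$truth)
  expect_equal(length(hp5$seqs), 96)
  expect_equal(hp5$length, 658)
  haps <- collapse_haplotypes(hp5)
  expect_equal(nrow(haps), 5)
  # haplotype sharing follows lineage membership exactly
  hap_of <- stats::setNames(rep(haps$haplotype, lengths(strsplit(haps$members, ";"))),
                            unlist(strsplit(haps$members, ";")))
  expect_true(same_partition(unname(hap_of[names(sim5$truth$lineage)]),
                             unname(sim5$truth$lineage)))
  expect_error(simulate_coi(sim_config(coi_substitutions = rep(300, 5)),
                            sim5$truth), "exceed|length")
})
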