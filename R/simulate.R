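#' Configuration for the clonal-dataset simulator
#'
#' Defines the generative model: a small number of founder clones
#' (lineages) reproduce by apomictic parthenogenesis, so every individual
#' carries a copy of its founder's multilocus genotype modified only by
#' stepwise microsatellite mutation (gain/loss of single repeat motifs) and
#' optional allele-scoring error. Founders are spaced at least
#' `founder_min_distance` allelic differences apart, with their differing
#' alleles drawn from lineage-specific size bands so that small mutational
#' steps can never create allele sharing between lineages; within-lineage
#' variation therefore stays well below the between-lineage distances, the
#' regime in which lineage delimitation from the distance histogram is
#' expected to work.
#'
#' The defaults emulate the structure of the worldwide sugarcane-aphid
#' dataset the method was designed for: 5 lineages, 10 dinucleotide loci,
#' 57 samples from 2 main hosts totalling 1333 individuals, lineage weights
#' proportional to the published lineage sizes, founders heterozygous at
#' about half their loci (the fixed-heterozygosity clonal signature), and a
#' mutation regime leaving within-lineage genotypes 1-4 allele steps apart.
#'
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @param n_lineages number of founder clones.
#' @param n_loci microsatellite loci.
#' @param founder_min_distance minimum allelic distance between founders.
#' @param motif repeat-motif size in bp (mutation step).
#' @param het_prob probability a founder locus is heterozygous.
#' @param generations clonal generations between founder and sampled aphid.
#' @param mutation_rate per-allele per-generation stepwise mutation rate.
#' @param max_mutations_per_individual cap on mutation events per sampled
#'   individual (default `Inf`; the separable preset uses 2 so that
#'   within-lineage genotypes differ by at most 4 steps).
#' @param scoring_error_rate per-allele-call probability of a +/-1 motif
#'   scoring error.
#' @param n_samples number of samples (host x locality x date units).
#' @param n_localities number of localities the samples are spread over.
#' @param total_individuals total individuals (split as evenly as possible
#'   across samples); overridden by `individuals_per_sample`.
#' @param individuals_per_sample optional integer or vector of sample sizes.
#' @param lineage_weights mixing proportions of the lineages across samples.
#' @param hosts host-plant labels assigned to samples in rotation.
#' @param coi_length COI alignment length (bp).
#' @param coi_substitutions substitutions separating each lineage's founder
#'   haplotype from the root haplotype (disjoint sites per lineage).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1,
                       n_lineages = 5,
                       n_loci = 10,
                       founder_min_distance = 8,
                       motif = 2,
                       het_prob = 0.5,
                       generations = 125,
                       mutation_rate = 1e-4,
                       max_mutations_per_individual = Inf,
                       scoring_error_rate = 0,
                       n_samples = 57,
                       n_localities = 42,
                       total_individuals = 1333,
                       individuals_per_sample = NULL,
                       lineage_weights = c(0.40, 0.11, 0.35, 0.12, 0.02),
                       hosts = c("sorghum", "sugarcane"),
                       coi_length = 658,
                       coi_substitutions = NULL) {
  if (length(lineage_weights) != n_lineages)
    lineage_weights <- rep(1 / n_lineages, n_lineages)
  cfg <- list(seed = as.integer(seed), n_lineages = n_lineages,
              n_loci = n_loci, founder_min_distance = founder_min_distance,
              motif = motif, het_prob = het_prob,
              generations = generations, mutation_rate = mutation_rate,
              max_mutations_per_individual = max_mutations_per_individual,
              scoring_error_rate = scoring_error_rate,
              n_samples = n_samples, n_localities = n_localities,
              total_individuals = total_individuals,
              individuals_per_sample = individuals_per_sample,
              lineage_weights = lineage_weights / sum(lineage_weights),
              hosts = hosts, coi_length = coi_length,
              coi_substitutions = coi_substitutions %||%
                (seq_len(n_lineages) - 1))
  stopifnot(cfg$n_lineages >= 1, cfg$n_loci >= 1,
            cfg$mutation_rate >= 0, cfg$mutation_rate <= 1,
            cfg$scoring_error_rate >= 0, cfg$scoring_error_rate <= 1,
            cfg$founder_min_distance >= 1,
            cfg$founder_min_distance <= 2 * cfg$n_loci,
            sum(cfg$coi_substitutions) <= cfg$coi_length)
  structure(cfg, class = "sim_config")
}

#' Paper-scale separable preset
#'
#' The study-scale configuration: 5 lineages at founder spacing >= 8, 57
#' samples, 1333 individuals, and a mutation regime capped at 2 stepwise
#' events per individual so that within-lineage MLGs differ by 1-4 alleles
#' while between-lineage distances stay at 8 or more -- the regime in which
#' the distance histogram has a clean first minimum separating the two
#' supports.
#'
#' @param seed integer seed.
#' @return a [sim_config()].
#' @export
preset_study_scale <- function(seed = 1) {
  sim_config(seed = seed, max_mutations_per_individual = 2)
}

# founder genotypes: a1/a2 matrices (n_lineages x n_loci slots of 2 alleles).
# Lineage 1 is the base; other lineages replace >= founder_min_distance
# allele slots with alleles from a disjoint lineage-specific size band
# (bands 40 bp apart, 20 bp wide), so +/- a few motif steps cannot create
# sharing between lineages.
draw_founders <- function(cfg) {
  L <- cfg$n_loci
  base_grid <- 180 + cfg$motif * 0:9
  band_start <- function(k) 240 + 40 * k
  a1 <- a2 <- matrix(0L, cfg$n_lineages, L)
  for (j in seq_len(L)) {
    het <- stats::runif(1) < cfg$het_prob
    x <- if (het) sample(base_grid, 2) else rep(sample(base_grid, 1), 2)
    a1[, j] <- min(x); a2[, j] <- max(x)
  }
  if (cfg$n_lineages > 1) {
    n_slots <- 2 * L
    for (k in 2:cfg$n_lineages) {
      ndiff <- min(n_slots, cfg$founder_min_distance + sample(0:2, 1))
      slots <- sample.int(n_slots, ndiff)
      grid <- band_start(k) + cfg$motif * 0:9
      for (s in slots) {
        j <- (s - 1) %/% 2 + 1
        val <- sample(grid, 1)
        if (s %% 2 == 1) a1[k, j] <- val else a2[k, j] <- val
      }
      swap <- a1[k, ] > a2[k, ]
      tmp <- a1[k, swap]; a1[k, swap] <- a2[k, swap]; a2[k, swap] <- tmp
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Simulate a clonal microsatellite dataset with ground truth
#'
#' Generates founder genotypes, assigns lineages to samples according to
#' `lineage_weights` (each sample draws from a single lineage; every
#' lineage receives at least one sample), copies the founder genotype to
#' each individual, and applies stepwise mutations: per allele the number
#' of mutational events is Binomial(`generations`, `mutation_rate`), each
#' event shifting the allele by one motif up or down. Identical
#' configurations (including the seed) reproduce the dataset exactly.
#'
#' @param config a [sim_config()].
#' @return list with `panel` (a [genotype_panel()]) and `truth`: list with
#'   `lineage` (named individual -> lineage id), `founders` (allele
#'   matrices), `sample_lineage`, `mutation_log` (data frame of applied
#'   net allele shifts).
#' @export
simulate_clonal_dataset <- function(config) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))

  founders <- draw_founders(cfg)
  lineage_ids <- paste0("L", seq_len(cfg$n_lineages))

  # allocate samples to lineages: largest-remainder, at least one each
  alloc <- floor(cfg$lineage_weights * cfg$n_samples)
  alloc <- pmax(alloc, 1)
  while (sum(alloc) > cfg$n_samples) alloc[which.max(alloc)] <- max(alloc) - 1
  rem <- cfg$lineage_weights * cfg$n_samples - alloc
  while (sum(alloc) < cfg$n_samples) {
    i <- which.max(rem); alloc[i] <- alloc[i] + 1; rem[i] <- -1
  }
  sample_lineage <- rep(seq_len(cfg$n_lineages), alloc)

  sizes <- cfg$individuals_per_sample %||% {
    base <- cfg$total_individuals %/% cfg$n_samples
    extra <- cfg$total_individuals %% cfg$n_samples
    rep(base, cfg$n_samples) + rep(c(1L, 0L), c(extra, cfg$n_samples - extra))
  }
  if (length(sizes) == 1) sizes <- rep(sizes, cfg$n_samples)

  n <- sum(sizes)
  sample_id <- rep(sprintf("S%02d", seq_len(cfg$n_samples)), sizes)
  locality <- rep(sprintf("loc%02d",
                          (seq_len(cfg$n_samples) - 1) %% cfg$n_localities + 1),
                  sizes)
  host <- rep(cfg$hosts[(seq_len(cfg$n_samples) - 1) %% length(cfg$hosts) + 1],
              sizes)
  lin <- rep(sample_lineage, sizes)
  individual <- sprintf("ind%04d", seq_len(n))

  L <- cfg$n_loci
  a1 <- founders$a1[lin, , drop = FALSE]
  a2 <- founders$a2[lin, , drop = FALSE]

  # stepwise mutations: net shift per allele slot
  slots <- 2 * L
  events <- matrix(stats::rbinom(n * slots, cfg$generations, cfg$mutation_rate),
                   n, slots)
  if (is.finite(cfg$max_mutations_per_individual)) {
    over <- rowSums(events) > cfg$max_mutations_per_individual
    for (i in which(over)) {   # drop surplus events deterministically
      idx <- rep(seq_len(slots), events[i, ])
      keep <- idx[seq_len(cfg$max_mutations_per_individual)]
      events[i, ] <- tabulate(keep, nbins = slots)
    }
  }
  log_rows <- list()
  hit <- which(events > 0, arr.ind = TRUE)
  if (nrow(hit)) {
    for (r in seq_len(nrow(hit))) {
      i <- hit[r, 1]; s <- hit[r, 2]
      shift <- sum(sample(c(-1L, 1L), events[i, s], replace = TRUE)) * cfg$motif
      if (shift == 0) next
      j <- (s - 1) %/% 2 + 1
      if (s %% 2 == 1) a1[i, j] <- a1[i, j] + shift
      else a2[i, j] <- a2[i, j] + shift
      log_rows[[length(log_rows) + 1]] <-
        data.frame(individual = individual[i], locus = j,
                   slot = ifelse(s %% 2 == 1, "a1", "a2"), shift = shift)
    }
  }
  mutation_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(individual = character(0), locus = integer(0),
               slot = character(0), shift = integer(0))

  meta <- data.frame(individual = individual, sample = sample_id,
                     locality = locality, host = host)
  panel <- genotype_panel(meta, pmin(a1, a2), pmax(a1, a2),
                          sprintf("SSR%02d", seq_len(L)))
  if (cfg$scoring_error_rate > 0)
    panel <- apply_genotyping_error(panel, cfg$scoring_error_rate,
                                    seed = cfg$seed + 1L)
  truth <- list(
    lineage = stats::setNames(lineage_ids[lin], individual),
    founders = founders,
    sample_lineage = stats::setNames(lineage_ids[sample_lineage],
                                     sprintf("S%02d", seq_len(cfg$n_samples))),
    mutation_log = mutation_log)
  list(panel = panel, truth = truth)
}

#' Apply allele-scoring errors to a panel
#'
#' Each allele call is independently shifted by one repeat motif (up or
#' down with equal probability) with probability `rate`, emulating
#' fragment-size scoring errors.
#'
#' @param panel a [genotype_panel()].
#' @param rate per-allele error probability in `[0, 1]`.
#' @param seed integer seed.
#' @param motif motif size in bp (default 2).
#' @return a new `genotype_panel`.
#' @export
apply_genotyping_error <- function(panel, rate, seed = 1, motif = 2L) {
  if (rate < 0 || rate > 1) stop_data("rate must be in [0, 1]")
  if (rate == 0) return(panel)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  shift_mat <- function(m) {
    hitmask <- !is.na(m) & matrix(stats::runif(length(m)) < rate, nrow(m))
    dir <- matrix(sample(c(-1L, 1L), length(m), replace = TRUE), nrow(m))
    m[hitmask] <- m[hitmask] + motif * dir[hitmask]
    m
  }
  a1 <- shift_mat(panel$a1); a2 <- shift_mat(panel$a2)
  genotype_panel(panel$meta, pmin(a1, a2), pmax(a1, a2), panel$loci)
}

#' Simulate COI barcode sequences matching a clonal simulation
#'
#' Builds a random root sequence, derives one founder haplotype per lineage
#' by substituting the configured number of sites (disjoint sites across
#' lineages, so pairwise haplotype distances are sums of the per-lineage
#' counts), and assigns every individual its lineage's haplotype.
#'
#' @param config the [sim_config()] used for the clonal dataset.
#' @param truth the `truth` element returned by [simulate_clonal_dataset()].
#' @return a [haplotype_panel()] with one sequence per individual.
#' @export
simulate_coi <- function(config, truth) {
  cfg <- if (inherits(config, "sim_config")) config else do.call(sim_config, config)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(cfg$seed + 2L)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  bases <- c("A", "C", "G", "T")
  root <- sample(bases, cfg$coi_length, replace = TRUE)
  subs <- cfg$coi_substitutions
  if (sum(subs) > cfg$coi_length)
    stop_data("substitution counts exceed alignment length")
  sites <- sample.int(cfg$coi_length, sum(subs))
  site_of <- vector("list", length(subs))
  off <- 0
  for (k in seq_along(subs)) {
    site_of[[k]] <- sites[off + seq_len(subs[k])]
    off <- off + subs[k]
  }
  haps <- vapply(seq_len(cfg$n_lineages), function(k) {
    s <- root
    for (pos in site_of[[k]]) {
      s[pos] <- sample(setdiff(bases, s[pos]), 1)
    }
    paste(s, collapse = "")
  }, "")
  lin_index <- as.integer(sub("^L", "", truth$lineage))
  seqs <- stats::setNames(haps[lin_index], names(truth$lineage))
  haplotype_panel(seqs)
}

#' Simulate a panmictic (sexually reproducing) panel
#'
#' Draws each individual's two alleles per locus independently from the
#' given allele-frequency distribution (random mating), providing a
#' calibrated Hardy-Weinberg null for the permutation tests. This is the
#' sexual-admixture counterpart of the clonal generator.
#'
#' @param n individuals.
#' @param n_loci loci.
#' @param n_alleles alleles per locus (equifrequent by default).
#' @param freqs optional frequency vector recycled across loci.
#' @param seed integer seed.
#' @param n_samples number of sample labels to spread individuals over.
#' @return a [genotype_panel()].
#' @export
simulate_panmictic_panel <- function(n, n_loci = 1, n_alleles = 4,
                                     freqs = NULL, seed = 1, n_samples = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  freqs <- freqs %||% rep(1 / n_alleles, n_alleles)
  sizes <- 180 + 2 * seq_along(freqs)
  a1 <- a2 <- matrix(0L, n, n_loci)
  for (j in seq_len(n_loci)) {
    x <- sample(sizes, n, replace = TRUE, prob = freqs)
    y <- sample(sizes, n, replace = TRUE, prob = freqs)
    a1[, j] <- pmin(x, y); a2[, j] <- pmax(x, y)
  }
  meta <- data.frame(individual = sprintf("ind%04d", seq_len(n)),
                     sample = sprintf("S%02d",
                                      (seq_len(n) - 1) %% n_samples + 1),
                     locality = "sim", host = "sim")
  genotype_panel(meta, a1, a2, sprintf("SSR%02d", seq_len(n_loci)))
}
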