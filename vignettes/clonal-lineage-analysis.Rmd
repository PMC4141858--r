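---
title: "Delimiting clonal lineages from microsatellite genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delimiting clonal lineages from microsatellite genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepart)
```

## The problem

In organisms that reproduce by apomictic parthenogenesis — many aphids
among them — offspring are genetic copies of their mother, so a field
sample is not a collection of independent genotypes but a collection of
*clones*. Two complications follow for anyone analysing microsatellite
data from such populations:

1. **Pseudo-replication.** The same multilocus genotype (MLG) sampled
   twenty times in one field is one biological event, not twenty. All
   diversity and differentiation statistics must be computed on a reduced
   dataset, conventionally one representative of each MLG per sample
   (individuals collected on the same host plant, locality and date).
2. **Mutational fuzz.** Long-lived clones accumulate stepwise
   microsatellite mutations and pick up allele-scoring errors, so one
   biological clone appears as a cloud of MLGs differing by a few allele
   steps. The unit of interest is the *multilocus lineage* (MLL): a
   cluster of MLGs separated by small distances, interpreted as one clone
   plus its somatic variants.

`clonepart` implements this workflow end to end and ships the published
worldwide sugarcane-aphid (*Melanaphis sacchari*) reference table of 36
MLGs x 10 loci as a fixture, so the whole pipeline can be exercised
against known results.

## The distance, the threshold, and the lineages

The pairwise distance between MLGs is the **number of allelic
differences**: at each locus the two diploid allele pairs are compared as
multisets and `2 - shared` is accumulated. A genotype `206/210` therefore
differs from `204/206` by one allele, not two. This distance is a metric
(the tests verify identity, symmetry and the triangle inequality by brute
force), is bounded by twice the locus count, and equals zero only for
identical genotypes.

In a clonal dataset the histogram of these distances is multimodal:
within-lineage pairs pile up at 1–4 steps, between-lineage pairs sit much
further out. `detect_threshold()` takes the first local minimum of the
zero-filled histogram — the smallest distance $t \ge 2$ with
$c(t) < c(t-1)$ and $c(t) \le c(t+1)$, ties resolved toward smaller $t$ —
and `assign_mll()` then groups MLGs by single linkage using edges with
$d < t$. Single linkage is the right join here because a lineage is a
chain of mutational neighbours: a 3-step variant connects through the
founder even if it is 6 steps from another variant. On the reference
table this yields a threshold of 5 and exactly the five published
lineages (A: 20 MLGs, B: 4, C: 8, D: 2, E: 2).

```{r}
panel <- load_table1_fixture()
mlgs <- collapse_mlg(panel)
d <- distance_matrix(mlgs)
h <- distance_histogram(d)
detect_threshold(h)
assign_mll(d, detect_threshold(h))
```

## Validating lineages with p\_sex

Grouping MLGs is a hypothesis: *these genotypes derive from one sexual
event followed by clonal propagation*. The alternative — that the
repeated genotype arose several times by independent sexual reproduction
— is quantified by `p_sex`. First `p_gen`, the probability of drawing the
genotype from the population allele frequencies in a single sexual event,
is computed over the *identical loci* of the lineage (loci at which all
member MLGs agree):

$$p_{gen} = \prod_{l}\begin{cases} f_i^2 + f_i(1-f_i)F_{IS} & \text{homozygote}\\
2 f_i f_j (1 - F_{IS}) & \text{heterozygote}\end{cases}$$

with $F_{IS} = 0$ this is the plain Hardy–Weinberg product. Then, for a
genotype observed $n$ times among $N$ analysis units,

$$p_{sex} = \sum_{i=n}^{N} \binom{N}{i}\, p_{gen}^{\,i} (1-p_{gen})^{N-i},$$

the binomial upper tail. Values below 0.01 support common clonal origin;
on the reference lineages every `p_sex` is far below that bound.

Two estimator choices deserve comment, since the field's reference
implementation does not document them unambiguously:

* **Allele frequencies** default to the *round-robin* estimator: the
  frequencies at locus $l$ are counted over one representative of each
  genotype that is distinct on the remaining loci. This prevents a
  heavily replicated clone from inflating the frequency of its own
  alleles. A plain pooled (`"overall"`) variant is also exposed.
* **The $F_{IS}$ correction** uses the standard inbreeding-model genotype
  probabilities above; a negative $F_{IS}$ (heterozygote excess, the
  clonal signature) raises heterozygote probabilities, which is
  conservative for `p_sex`. By default $F_{IS}$ is the multilocus
  Weir–Cockerham estimate from the dataset; passing `f_is = 0` gives the
  uncorrected Hardy–Weinberg variant.

## Clonal richness

Richness is $R = (G-1)/(N-1)$ with $G$ the number of genotypes (MLGs or
MLLs) and $N$ the number of analysis units, reported to 3 decimals. The
formula's $N$ is sometimes verbally described as the number of *samples*,
but the published headline values only reproduce with $N$ equal to the
number of retained representative individuals (here $(36-1)/(98-1) =
0.361$ and $(5-1)/(98-1) = 0.041$); `clonepart` therefore uses retained
analysis units as $N$ and documents the distinction.

## Minimum spanning networks

`build_msn()` grows a spanning tree Kruskal-style in non-decreasing
distance order. Interactive tie resolution in the classic network tools
is replaced by a deterministic rule: before any edge of weight $w$ is
committed, every weight-$w$ edge joining two still-separate components is
recorded; the first in id order becomes a tree edge, the rest become
*alternative* (reticulation) edges. The retained tree always has minimum
weight, and the alternative set equals the tied edges belonging to some
other minimum spanning tree — verified in the tests against exhaustive
spanning-tree enumeration for up to 7 nodes. `expand_step_nodes()`
rewrites every length-$k$ edge as $k$ unit steps through inferred nodes,
the convention used to draw such networks with one node per allele step.
Layout and rendering are out of scope; `export_network()` writes TSV edge
lists, GraphML and DOT with lineage/host annotations so any graph viewer
can reproduce the figure.

## Clone-aware population genetics

All tests run on the one-representative-per-sample dataset (analysing the
raw panel instead is possible but amounts to clonal pseudo-replication).
Estimators are Weir & Cockerham (1984) throughout: per-allele variance
components $a$ (among populations), $b$ (among individuals), $c$ (within
individuals), combined as ratios of sums over alleles and loci, giving
$\theta$ (= $F_{ST}$) and $f$ (= $F_{IS} = 1 - \sum c / \sum(b+c)$).
Monomorphic loci carry no information and are excluded. A population of
fixed heterozygotes gives $f = -1$, the textbook signature of long-term
clonality; complete fixation for different alleles gives $\theta = 1$.

Exact tests are Monte-Carlo permutation tests rather than Markov-chain
approximations, for reproducibility under a seed with the same null:

* **Hardy–Weinberg**: alleles are re-paired at random within the
  population and locus. The two-sided statistic is the conditional
  probability of the genotype table given the allele counts; one-sided
  tests use the heterozygote count (excess / deficit).
* **Genic differentiation**: the alleles x populations table per locus
  gives $G = 2\sum o \ln(o/e)$, summed over loci for the global test;
  individuals (not gene copies) are permuted among populations so the
  diploid structure is preserved.

All permutation p-values use the add-one estimator $(1+k)/(1+n_{perm})$,
so they are never zero and are uniform under the null up to the
discreteness of the statistic — a property the acceptance suite checks
with Kolmogorov–Smirnov tests over 200 null replicates.

## COI barcodes

The companion mitochondrial module collapses aligned 658-bp COI sequences
to haplotypes (exact match), computes uncorrected p-distances with `N`
and gaps excluded pairwise — the standard convention for barcode data,
and consistent with the few-tenths-of-a-percent intraspecific divergences
involved, where model correction is immaterial — and builds the haplotype
network from substitution counts via the same MSN machinery. Divergence
can be averaged over individual pairs (the default, matching how means
are usually reported) or over distinct haplotype pairs.

## The synthetic-data generator

Real per-individual data for the reference study (beyond the printed
36-MLG table) are not distributable, so every stage is validated against
a generator that emulates the inferred process: a few founder clones,
apomictic descent, stepwise mutation, and multi-sample collection.

* **Founders.** Lineage founders differ at `founder_min_distance`
  (default 8) allele slots. The differing alleles are drawn from
  lineage-specific size bands separated by many motif steps, so that
  small mutations can never create allele sharing between lineages;
  between-lineage distances therefore never fall below the founder
  spacing. Founders are heterozygous at about half their loci
  (`het_prob = 0.5`), reproducing the fixed-heterozygosity signature.
* **Mutation.** Per allele, mutation events are
  Binomial(`generations` = 125, `mutation_rate` = 1e-4), each a ±1 motif
  step — about 0.25 expected events per individual across 20 allele
  slots, which at study scale yields the observed handful of 1–4-step
  within-lineage variants. The `preset_study_scale()` configuration caps
  events at 2 per individual, bounding within-lineage pairwise distances
  at 4 — the *separable* regime in which the histogram's first minimum
  provably falls between the within- and between-lineage supports.
* **Scale.** Defaults: 5 lineages with weights (0.40, 0.11, 0.35, 0.12,
  0.02) matching the published lineage sizes, 57 samples over 42
  localities and 2 hosts, 1333 individuals split as evenly as possible.
* **COI.** One founder haplotype per lineage at 0–4 substitutions from a
  random root, at disjoint sites; individuals inherit their lineage's
  haplotype. With the published-scale copy numbers this gives a mean
  pairwise divergence of a few tenths of a percent over 658 bp.
* **Null model.** `simulate_panmictic_panel()` draws alleles
  independently under random mating, providing the calibrated null for
  the Hardy–Weinberg and G-test uniformity checks.

What the generator does *not* emulate: null alleles and allele dropout,
recombination or occasional sexual generations, homoplasy across
lineages, uneven locality effort, and mutation-rate heterogeneity among
loci. Passing recovery tests on this generator therefore shows that the
pipeline is correct in the separable clonal regime it assumes — not that
every real dataset is separable. On real data the histogram should always
be inspected (`distance_histogram()` is returned by the pipeline report)
before accepting an automatic threshold, and `run_full_analysis()`
accepts a manual threshold for exactly this reason.

## Numerical and design choices

* **Determinism.** MLG ids are lexicographic in the genotype, MLL ids are
  ordered by smallest member, tie edges are resolved in id order, and
  every stochastic routine takes an explicit seed — two runs from the
  same inputs are identical.
* **Missing data.** The reference data are complete, so conventions are
  ours: the missing sentinel is a configurable integer code (default 0)
  rendered `0/0`; half-called pairs are rejected; distances skip missing
  loci and rescale by $L/(L-m)$ (rounded), configurable off; individuals
  missing all loci are dropped with a warning.
* **Degenerate inputs.** A monotone distance histogram has no detectable
  threshold and raises an error (the caller must supply one);
  monomorphic loci give a conventional Hardy–Weinberg p of 1 with a
  warning and are excluded from F-statistics; richness is undefined for
  fewer than two units.
* **Problem sizes.** The validation suite runs the full pipeline on the
  36-MLG reference table, twenty 1333-individual simulations for
  recovery, a 500-individual simulation for the clonal signature at
  `n_perm` = 10^4, and 200 null replicates at `n_perm` = 199 for the
  uniformity checks — sizes chosen to match the study's scale where it
  matters (recovery) and to keep Monte-Carlo error well inside the
  asserted bounds elsewhere.

## Known limitations

* The `p_sex` machinery follows the cited clonal-identity method but the
  original tool's exact pooling choices are undocumented; both frequency
  estimators are exposed instead of guessing.
* Between-lineage $F_{ST}$ on the reference table treats MLG rows as
  individuals (the per-individual dataset is not distributable), so those
  values are indicative, not a reproduction of the published per-pair
  table.
* No null-allele screening, no model-based clustering, no
  model-corrected sequence distances, and no tree inference — these are
  deliberate non-goals.
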