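---
title: "Testing phylosymbiosis from OTU count tables: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing phylosymbiosis from OTU count tables: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosym)
```

## The question and the model

Phylosymbiosis is the observation that, across a clade of host species, the
dendrogram of microbial community compositions mirrors the host phylogeny.
It is an eco-evolutionary pattern, not a claim of co-speciation or vertical
transmission: the test is purely topological. `phylosym` operationalizes it
as a three-step procedure:

1. summarize each host species' microbiota as its mean relative-abundance
   vector over individuals (after rarefaction and, for the combined
   analysis, after averaging each individual's intestinal sections);
2. cluster species by UPGMA on Bray–Curtis dissimilarities between those
   profiles;
3. compare the dendrogram's rooted topology to the host phylogeny with two
   metrics, and locate them in a null distribution of topologies.

### Tree metrics

Both trees are compared as **rooted** trees through their cluster sets: the
clades of size 2..n−1. A binary rooted tree on n leaves has exactly n−2 such
clusters, so the Robinson–Foulds count (the symmetric difference of the two
cluster sets) is normalized by its maximum 2(n−2). Rooted comparison is
deliberate: both inputs are rooted (UPGMA is rooted by construction; the
host tree has a defined outgroup), and for n = 4 the rooted normalization
admits the intermediate value 0.5 — one shared clade out of two — which an
unrooted 4-taxon comparison (a single internal bipartition, values 0 or 1)
cannot produce.

The Matching-Cluster distance refines RF by penalizing near-misses less:
the smaller cluster set is padded with empty sets, each possible pairing of
clusters is scored by the symmetric difference of their leaf memberships,
and MC is the minimum-cost perfect matching, computed exactly with a
Hungarian (shortest-augmenting-path) assignment solver. Where RF scores a
clade as simply present or absent, MC counts how many leaves must move.

No closed-form maximum of MC over topologies is available, so nMC uses the
empirical maximum over the null topology ensemble as its denominator. For
the 4-leaf case this maximum is 6, so a dendrogram sharing one clade with
the host (MC = 2) reports nMC = 2/6 = 0.333. Exhaustive enumeration shows
the attainable values at n = 4 are nRF ∈ {0, 0.5, 1}, with MC = 2 when the
dendrogram is a caterpillar sharing one clade and MC = 3 for the balanced
topology sharing one clade — the two metrics genuinely differ in resolution.

### The topology null

Significance is assessed against the uniform distribution over labeled
rooted binary topologies: all (2n−3)!! of them, enumerated exhaustively for
n ≤ 7 (15 topologies at n = 4), or sampled uniformly by random sequential
leaf attachment beyond. The p-value is the probability that a random
topology is **at least as close** to the host tree as the observed
dendrogram (ties count as successes — conservative for a discrete null); in
Monte-Carlo mode the add-one estimator (1 + hits)/(1 + draws) keeps p
positive. Under this null, perfect 4-taxon congruence has p = 1/15 ≈ 0.067:
with only four species no topology test can beat ~0.067, which is why the
per-section congruence table should be read as an effect-size pattern
rather than a chain of independent significance stamps. Other nulls exist
in the literature (e.g. permuting leaf labels of the observed dendrogram
shape, which gives 2/24 ≈ 0.083 for a caterpillar); we use the uniform
topology null as the simplest defensible choice and report its composition
in every result.

## Community statistics

The surrounding statistics are the field's standard toolkit, implemented
against their defining formulas:

- **Bray–Curtis**: Σ|x−y|/Σ(x+y), computed on rarefied counts. At equal
  depths this equals the relative-abundance version; we rarefy first rather
  than normalizing.
- **ANOSIM**: R = (r̄_B − r̄_W)/(M/2) on mean-rank-tied dissimilarity
  ranks, with Monte-Carlo label permutation and Bonferroni-adjusted
  pairwise two-group runs.
- **PERMANOVA (ADONIS)**: Gower-centred inner products G = −½·C·d²·C,
  sequential (Type-I) sums of squares via hat-matrix increments, pseudo-F,
  and permutation of raw sample labels. The default model is
  `species * section * individual` in that order, matching the convention
  of sequential distance-based ANOVA tables. The individual bird enters as
  a **single numeric covariate** (df = 1), not a factor: nested factor
  coding would consume most of the residual degrees of freedom in a design
  where individual nests inside species, and a 1-df regression slope is the
  only coding that leaves the individual term a single row in the table.
- **Indicator genera**: Dufrêne–Legendre IndVal = max over groups of
  100 × specificity × fidelity, permutation-tested per taxon.
- **Alpha diversity**: observed richness; bias-corrected Chao1
  S + F1(F1−1)/(2(F2+1)), which stays defined when no doubletons exist;
  dominance Σp² (the *complement* of Simpson diversity — the convention
  under which a community with one 59 % genus scores ≈ 0.36, consistent
  with the magnitudes this pipeline is meant to reproduce); and
  Buzas–Gibson evenness e^H/S, whose small values (~0.05–0.15) are the
  natural scale for communities with hundreds of OTUs, unlike Pielou's J.
  Rarefaction curves use the exact hypergeometric expectation
  E[S_m] = S − Σ_i C(N−N_i, m)/C(N, m), evaluated with log-binomials;
  extrapolation beyond the sample total is out of scope.
- **Group comparisons**: Kruskal–Wallis (tie-corrected, via base R) with
  Dunn's z post hoc on the pooled tie-corrected rank variance; one-way
  ANOVA with pooled-SD pairwise t tests. Both adjust pairwise p-values by
  Bonferroni over the a(a−1)/2 comparisons.
- **nMDS**: stress majorization (Guttman transform) alternating with
  isotonic regression of configuration distances on the dissimilarity
  order. Ties are handled with the *secondary* treatment (tied
  dissimilarities share one fitted value): under the primary treatment a
  configuration of four equidistant points could be "embedded" in the
  plane at zero stress, which defeats the purpose of stress as a
  diagnostic. Twenty starts by default (first classical-MDS, rest random);
  a numerical guard stops any start whose stress-1 would increase, so the
  reported stress path is non-increasing by construction.

Permutation p-values throughout use (1 + exceedances)/(1 + permutations),
which cannot return 0 and is the standard Monte-Carlo estimator.

## Pre-analysis transforms

Samples are retained iff their depth is **at least** the rarefaction depth
(the smallest retained sample may itself define the depth); rarefaction is
a single without-replacement draw to exactly 20,000 reads by default,
reproducible under a seed — not an average over repeated draws, matching
the subsampling semantics of the mothur toolchain this emulates. Sections
of one individual are merged by the arithmetic mean of their rarefied
rows (1–3 sections, whichever are present), so merged tables are
fractional; all downstream statistics accept non-integer abundances.

## The synthetic-data generator

The generator exists so the full pipeline can be exercised and validated
without any sequencing data. It emulates the post-OTU-calling state of a
four-species waterbird study:

- **Mean profiles.** Named genera carry the published prevalences
  (*Catellicoccus* 58.86 %, *Lactobacillus* 6.45 % and *Clostridium s.s.*
  4.75 % in gulls; *Fusobacterium* 32.43 %, *Clostridium s.s.* 8.69 % and
  *Campylobacter* 8.16 % in cormorants; *Fusobacterium*/*Cetobacterium*
  19.81/10.67 % in egrets and 27.30/13.33 % in night herons; *Helicobacter*
  11.10/7.20 % in herons/egrets). The unclassified *Clostridiaceae* genus
  is published only as a range (8.18–14.06 %); the default takes the
  midpoint, configurable. *Clostridium s.s.* in egrets and night herons is
  published only as lying within 4.75–8.69 %; the default uses 6 %.
  Remaining phylum mass is spread over background genera — 2 shared + 6
  species-specific per phylum — so the published phylum totals (gull
  Firmicutes 90.3 / Proteobacteria 9.2 / Fusobacteria 0.3 %; cormorant
  Fusobacteria 39.4 %; night heron 48.6 %; egret Firmicutes 40.0 %) are
  reproduced exactly while most genera stay species-specific, echoing the
  mostly-unshared OTU sets real Venn analyses show. Phylum totals not
  published (the non-dominant phyla of the three fish-eating species) are
  package defaults chosen to sum to 1 with Fusobacteria > 34 % in all
  non-gull species.
- **Individuals.** Each bird's composition is one Dirichlet draw with
  concentration `c × mean` (default c = 50), after expanding each genus
  into 5 OTUs with geometric (ratio 0.5) within-genus weights — a
  rank-abundance structure that costs no extra parameters. Small
  per-OTU concentrations make individual communities sparse and
  individual-specific, the pattern driving within-species ANOSIM structure.
- **Sections.** Each of the 3 sections is an independent multinomial draw
  from its individual's composition — no section effect is injected,
  because the study design this mirrors found none.
- **Cohorts and depths.** 7 cormorants, 11 egrets, 8 night herons, 5 gulls
  (93 section samples). Library sizes are log-normal around 30,000 reads,
  truncated at 20,000, except a 10 % "shallow" fraction drawn below the
  threshold so the depth filter has real work — roughly the rate at which
  field studies of this kind lose libraries to insufficient depth (here,
  typically 8-12 of 93 samples per run).

What the generator does *not* emulate: sequencing error, chimeras,
taxonomy misclassification, section effects, or any covariance between
taxa beyond the Dirichlet's. Passing recovery tests therefore shows the
pipeline is correct and well-calibrated on ideal compositional data — not
that real waterbird data would reproduce any particular statistic.

## Numerical and design choices

- UPGMA ties are broken toward the pair whose smallest member label sorts
  first, making dendrograms bit-reproducible; merge heights are half the
  average between-cluster distance so two leaves at distance d join at
  height d/2.
- A dataset where all species profiles coincide yields an
  all-(near-)zero distance matrix; the report still emits a tie-broken
  dendrogram but attaches a stability warning.
- Degenerate inputs are flagged rather than hidden: zero within-group
  variance with unequal means reports an infinite F; a PERMANOVA with zero
  residual SS skips permutation and warns.
- All stochastic stages (generation, rarefaction, permutation tests, nMDS
  starts, Monte-Carlo nulls) take explicit seeds; `analyze_dataset()`
  derives per-stage seeds from one master seed and embeds seed and config
  hash in every report file.
- Problem sizes in the validation suite (20 pipeline replicates for
  topology recovery; 200-individual cohorts for profile recovery; 500
  replicates at 199 permutations for test calibration) were chosen as the
  smallest designs whose Monte-Carlo error is well below the tolerances
  being checked.

## Known limitations

- With four host species the congruence test's resolution is capped at
  p = 1/15; the per-section pattern is an effect-size statement.
- The uniform-topology null is one of several defensible nulls; results
  are reported with the null's composition so readers can translate.
- `ape`'s tree representation cannot distinguish a rooted basal polytomy
  from an unrooted tree, so cluster extraction trusts the caller to supply
  rooted trees and treats the displayed root as the root.
- Unifrac-style phylogenetically weighted dissimilarities are out of scope
  (they require an OTU tree), as are coverage-based rarefaction and
  richness extrapolation beyond the observed depth.

## A minimal run

```{r example, eval = FALSE}
ds <- simulate_count_table(generator_config(seed = 42))
counts <- rarefy(filter_min_depth(ds$counts, 20000), 20000, seed = 42)
info <- ds$info[ds$info$sample_id %in% counts$sample_id, ]
phylosymbiosis_report(counts, info, host_phylogeny())
```
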