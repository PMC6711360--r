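Package: phylosym
Title: Phylosymbiosis Testing from Microbial Community Count Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for testing phylosymbiosis - the congruence
    between a host clade's phylogeny and the hierarchical clustering of its
    members' gut microbial community compositions.  Provides rarefaction and
    depth filtering of OTU count tables, intestinal-section merging, alpha
    diversity indices (observed richness, bias-corrected Chao1, dominance,
    Buzas-Gibson evenness) with Kruskal-Wallis/Dunn and ANOVA/Bonferroni group
    comparisons, Bray-Curtis dissimilarities with ANOSIM, PERMANOVA, non-metric
    multidimensional scaling, shared-OTU set analysis and Dufrene-Legendre
    indicator values, UPGMA dendrograms, and rooted-tree congruence via
    normalized Robinson-Foulds and Matching-Cluster distances under a uniform
    topology null.  A synthetic-data module simulates multi-species waterbird
    gut communities with Dirichlet-multinomial individual variation so the
    whole pipeline can be exercised and validated without sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
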