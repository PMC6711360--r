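#' Host phylogeny fixture for the four waterbird species
#'
#' Rooted topology (((egret, night_heron), cormorant), gull) with unit branch
#' lengths: the two herons (family Ardeidae) are sisters, the cormorant joins
#' them at the order level, and the gull (a different order) is the outgroup.
#'
#' @return an [ape::phylo] rooted tree with 4 leaves.
#' @export
host_phylogeny <- function() {
  ape::read.tree(text = "(((egret:1,night_heron:1):1,cormorant:1):1,gull:1);")
}

#' Topology-congruence test between a dendrogram and a host phylogeny
#'
#' Computes the rooted-cluster Robinson-Foulds and Matching-Cluster distances
#' between a microbiota dendrogram and the host tree, and situates them in a
#' null distribution of topologies: exhaustive over all (2n - 3)!! labeled
#' rooted binary topologies when n <= 7, otherwise `n_random` uniform draws.
#' For each metric, p is the probability that a null topology is at least as
#' close to the host tree as the observed dendrogram (ties count as
#' successes). The Matching-Cluster distance is normalized by the maximum MC
#' observed across the null set, so both normalized metrics lie in [0, 1].
#'
#' @param dendrogram,host rooted [ape::phylo] trees on the same leaf set.
#' @param null `"auto"` (exhaustive when n <= 7, else Monte-Carlo),
#'   `"exhaustive"`, or `"sample"`.
#' @param n_random number of sampled null topologies in Monte-Carlo mode.
#' @param seed optional seed for Monte-Carlo sampling.
#' @return an object of class `congruence_test` with elements `rf`, `nrf`,
#'   `p_rf`, `mc`, `nmc`, `p_mc`, `mc_max`, `null_type`, `null_size`, `n_leaves`.
#' @examples
#' host <- host_phylogeny()
#' congruence_test(host, host) # perfect congruence: p = 1/15
#' @export
congruence_test <- function(dendrogram, host, null = c("auto", "exhaustive", "sample"),
                            n_random = 1000, seed = NULL) {
  null <- match.arg(null)
  leaves <- check_same_leaves(dendrogram, host)
  n <- length(leaves)
  if (null == "auto") null <- if (n <= 7) "exhaustive" else "sample"
  if (null == "exhaustive" && n > 7) {
    abort("exhaustive null only supported for n <= 7; use null = \"sample\"")
  }
  if (null == "sample" && n_random < 100) {
    warn("fewer than 100 null topologies gives a coarse p-value")
  }

  obs_rf <- rf_dist(dendrogram, host)
  host_clusters <- tree_clusters(host)
  obs_mc <- mc_from_clusters(tree_clusters(dendrogram), host_clusters, leaves)

  null_trees <- if (null == "exhaustive") {
    enumerate_topologies(leaves)
  } else {
    with_seed(seed, replicate(n_random, sample_topology(leaves), simplify = FALSE))
  }
  host_keys <- cluster_keys(host_clusters)
  null_rf <- vapply(null_trees, function(t) {
    k <- cluster_keys(tree_clusters(t))
    length(setdiff(k, host_keys)) + length(setdiff(host_keys, k))
  }, numeric(1))
  null_mc <- vapply(null_trees, function(t) {
    mc_from_clusters(tree_clusters(t), host_clusters, leaves)
  }, numeric(1))

  mc_max <- max(null_mc)
  if (null == "exhaustive") {
    p_rf <- mean(null_rf <= obs_rf$rf)
    p_mc <- mean(null_mc <= obs_mc)
  } else {
    # add-one Monte-Carlo estimator so p never hits 0
    p_rf <- (1 + sum(null_rf <= obs_rf$rf)) / (1 + length(null_rf))
    p_mc <- (1 + sum(null_mc <= obs_mc)) / (1 + length(null_mc))
  }

  structure(
    list(
      rf = obs_rf$rf,
      nrf = obs_rf$nrf,
      p_rf = p_rf,
      mc = as.integer(obs_mc),
      nmc = if (mc_max > 0) obs_mc / mc_max else 0,
      p_mc = p_mc,
      mc_max = mc_max,
      rf_max = 2 * (n - 2),
      null_type = null,
      null_size = length(null_trees),
      n_leaves = n,
      seed = seed
    ),
    class = "congruence_test"
  )
}

#' @export
print.congruence_test <- function(x, ...) {
  cat("Topology congruence test (", x$n_leaves, " leaves, ",
    x$null_type, " null of ", x$null_size, " topologies)\n",
    sep = ""
  )
  cat(sprintf("  Robinson-Foulds: RF = %d, nRF = %.3f, p = %.4f\n", x$rf, x$nrf, x$p_rf))
  cat(sprintf(
    "  Matching-Cluster: MC = %d, nMC = %.3f (max %d), p = %.4f\n",
    x$mc, x$nmc, as.integer(x$mc_max), x$p_mc
  ))
  invisible(x)
}

# Mean relative-abundance profile per host species from a count table.
species_mean_profiles <- function(counts, species_of) {
  m <- ct_matrix(counts)
  rel <- m / rowSums(m)
  sp <- species_of[rownames(m)]
  if (anyNA(sp)) abort("every sample needs a species assignment")
  prof <- rowsum(rel, sp) / as.vector(table(sp)[sort(unique(sp))])
  prof
}

#' Phylosymbiosis report across intestinal sections
#'
#' The pipeline's headline computation. Starting from a rarefied-depth count
#' table, builds a species-level microbiota dendrogram for (a) all sections
#' combined (section samples averaged per individual first) and (b) each
#' intestinal section separately, then tests each dendrogram's congruence
#' with the host phylogeny via [congruence_test()].
#'
#' Each dataset's species profile is the mean relative-abundance vector over
#' its samples; species are clustered by UPGMA on Bray-Curtis dissimilarities
#' between profiles.
#'
#' @param counts count table (tibble, `sample_id` first column) at a common
#'   depth, e.g. output of [rarefy()].
#' @param info sample metadata with columns `sample_id`, `species`,
#'   `individual`, `section`.
#' @param host rooted host phylogeny whose leaf labels are the species names.
#' @param null,n_random,seed passed to [congruence_test()].
#' @return a tibble of class `phylosym_report` with one row per dataset
#'   (`all_sections`, then each section): nRF and its p, nMC and its p, and
#'   the dendrogram in newick form. Full `congruence_test` objects and trees
#'   are attached as attributes `tests` and `trees`.
#' @export
phylosymbiosis_report <- function(counts, info, host,
                                  null = "auto", n_random = 1000, seed = NULL) {
  stopifnot(is.data.frame(info))
  need <- c("sample_id", "species", "individual", "section")
  if (!all(need %in% names(info))) {
    abort(paste0("`info` must contain columns: ", paste(need, collapse = ", ")))
  }
  species <- sort(unique(as.character(info$species)))
  if (!setequal(species, host$tip.label)) {
    abort("host tree leaves must match the species in `info`")
  }

  datasets <- list()
  # combined: average sections per individual, then species means
  merged <- merge_sections(counts, info)
  ind_species <- setNames(as.character(info$species), as.character(info$individual))
  datasets$all_sections <- list(counts = merged, species_of = ind_species)
  for (sec in c("anterior", "middle", "posterior")) {
    ids <- info$sample_id[info$section == sec & info$sample_id %in% counts$sample_id]
    if (length(ids) == 0) next
    sub <- counts[match(ids, counts$sample_id), , drop = FALSE]
    sp <- setNames(as.character(info$species[match(ids, info$sample_id)]), ids)
    if (!setequal(unique(sp), species)) {
      warn(paste0("section '", sec, "' lacks some species; skipped"))
      next
    }
    datasets[[sec]] <- list(counts = sub, species_of = sp)
  }

  rows <- list()
  tests <- list()
  trees <- list()
  for (nm in names(datasets)) {
    ds <- datasets[[nm]]
    prof <- species_mean_profiles(ds$counts, ds$species_of)
    d <- bray_curtis(ct_tibble(prof))
    if (max(d) < 1e-10) {
      warn(paste0(
        "dataset '", nm, "': species profiles are (near-)identical; ",
        "dendrogram reflects tie-breaking only"
      ))
    }
    dend <- upgma(d)
    ct <- congruence_test(dend, host, null = null, n_random = n_random, seed = seed)
    tests[[nm]] <- ct
    trees[[nm]] <- dend
    rows[[nm]] <- tibble(
      dataset = nm,
      n_samples = nrow(ds$counts),
      rf = ct$rf, nrf = ct$nrf, p_rf = ct$p_rf,
      mc = ct$mc, nmc = ct$nmc, p_mc = ct$p_mc,
      dendrogram = ape::write.tree(dend)
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "tests") <- tests
  attr(out, "trees") <- trees
  attr(out, "host") <- host
  class(out) <- c("phylosym_report", class(out))
  out
}
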