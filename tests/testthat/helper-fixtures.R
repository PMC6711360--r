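# Shared fixture builders and independent oracles.

# count table tibble from a plain matrix (rows samples, cols taxa)
ct <- function(m, samples = NULL, taxa = NULL) {
  if (!is.null(samples)) rownames(m) <- samples
  if (!is.null(taxa)) colnames(m) <- taxa
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("t%02d", seq_len(ncol(m)))
  phylosym:::ct_tibble(m)
}

read_newick <- function(txt) ape::read.tree(text = txt)

# Brute-force matching-cluster distance: try every pairing of the padded
# cluster sets (independent of the Hungarian solver).
mc_brute_force <- function(t1, t2) {
  leaves <- sort(t1$tip.label)
  c1 <- tree_clusters(t1)
  c2 <- tree_clusters(t2)
  k <- max(length(c1), length(c2))
  pad <- function(cl) c(cl, rep(list(character(0)), k - length(cl)))
  c1 <- pad(c1)
  c2 <- pad(c2)
  cost <- function(a, b) length(setdiff(a, b)) + length(setdiff(b, a))
  perms <- combinat_perms(k)
  best <- Inf
  for (p in perms) {
    tot <- sum(vapply(seq_len(k), function(i) cost(c1[[i]], c2[[p[i]]]), numeric(1)))
    best <- min(best, tot)
  }
  best
}

combinat_perms <- function(k) {
  if (k == 1) {
    return(list(1L))
  }
  out <- list()
  for (p in combinat_perms(k - 1)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1]] <- append(p, k, after = pos - 1)
    }
  }
  out
}

# Naive rooted RF by pairwise set comparison (no key hashing).
rf_naive <- function(t1, t2) {
  c1 <- tree_clusters(t1)
  c2 <- tree_clusters(t2)
  in_other <- function(a, cl) any(vapply(cl, function(b) setequal(a, b), logical(1)))
  sum(!vapply(c1, in_other, logical(1), cl = c2)) +
    sum(!vapply(c2, in_other, logical(1), cl = c1))
}

# One-way PERMANOVA within-group sum of squares by the direct pairwise
# formula SS_W = sum_g sum_{i<j in g} d_ij^2 / n_g (independent oracle).
ss_within_direct <- function(d, groups) {
  d <- as.matrix(d)
  ss <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d[idx, idx, drop = FALSE]
    ss <- ss + sum(sub[lower.tri(sub)]^2) / length(idx)
  }
  ss
}

# small standard synthetic dataset used by several integration tests
small_dataset <- function(seed = 101) {
  cfg <- generator_config(
    n_individuals = c(cormorant = 3, egret = 3, night_heron = 3, gull = 3),
    seed = seed
  )
  simulate_count_table(cfg)
}
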