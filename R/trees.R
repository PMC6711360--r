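#' UPGMA dendrogram from a distance matrix
#'
#' Average-linkage agglomerative clustering producing an ultrametric rooted
#' dendrogram. Merge heights are half the average between-cluster distance, so
#' two leaves at distance d sit at height d/2. Ties between candidate merges
#' are broken deterministically in favour of the pair whose smallest member
#' label sorts first (then the second-smallest), making the output
#' bit-reproducible.
#'
#' @param d symmetric distance matrix with row/column labels, or a
#'   [stats::dist] object.
#' @return an [ape::phylo] rooted ultrametric tree.
#' @examples
#' d <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3,
#'   dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
#' )
#' upgma(d)
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) abort("distance matrix must have row labels")
  if (any(is.na(m)) || any(!is.finite(m))) abort("distances must be finite and non-missing")
  if (max(abs(m - t(m))) > 1e-12) abort("distance matrix must be symmetric")
  n <- nrow(m)
  if (n < 2) abort("need at least 2 items to cluster")
  labels <- rownames(m)

  newick <- labels
  height <- rep(0, n)
  size <- rep(1L, n)
  minlab <- labels
  active <- rep(TRUE, n)
  D <- m
  diag(D) <- Inf

  while (sum(active) > 1) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    dmin <- min(sub)
    # candidate pairs at the minimum; deterministic lexicographic tie-break
    hits <- which(sub <= dmin + 1e-12 & upper.tri(sub), arr.ind = TRUE)
    keys <- apply(hits, 1, function(rc) {
      paste(sort(c(minlab[idx[rc[1]]], minlab[idx[rc[2]]])), collapse = "\r")
    })
    pick <- hits[order(keys)[1], ]
    i <- idx[pick[1]]
    j <- idx[pick[2]]
    h <- D[i, j] / 2

    kids <- c(i, j)[order(c(minlab[i], minlab[j]))]
    newick_new <- paste0(
      "(", newick[kids[1]], ":", format(h - height[kids[1]], digits = 15),
      ",", newick[kids[2]], ":", format(h - height[kids[2]], digits = 15), ")"
    )

    # weighted (UPGMA) update: average over all original leaf pairs
    other <- setdiff(idx, c(i, j))
    if (length(other) > 0) {
      dnew <- (size[i] * D[i, other] + size[j] * D[j, other]) / (size[i] + size[j])
      D[i, other] <- dnew
      D[other, i] <- dnew
    }
    newick[i] <- newick_new
    height[i] <- h
    size[i] <- size[i] + size[j]
    minlab[i] <- min(minlab[i], minlab[j])
    active[j] <- FALSE
    D[j, ] <- Inf
    D[, j] <- Inf
  }
  root <- which(active)
  ape::read.tree(text = paste0(newick[root], ";"))
}

#' Nontrivial clades of a rooted tree
#'
#' Returns the cluster-set representation of a rooted tree: every clade (set
#' of leaf labels descending from an internal node) of size between 2 and
#' n - 1. Singletons and the full leaf set are excluded. For a binary rooted
#' tree there are exactly n - 2 such clusters.
#'
#' Trees are interpreted as rooted at their displayed root node. Note that a
#' rooted star (no internal structure, empty cluster set) and an unrooted
#' tree have the same representation in `phylo`; callers are expected to
#' supply rooted trees.
#'
#' @param tree an [ape::phylo] rooted tree with >= 3 leaves.
#' @return a list of sorted character vectors, one per nontrivial clade.
#' @export
tree_clusters <- function(tree) {
  if (!inherits(tree, "phylo")) abort("`tree` must be an ape phylo object")
  n <- length(tree$tip.label)
  if (n < 3) abort("tree must have at least 3 leaves")
  tr <- ape::reorder.phylo(tree, "postorder")
  m <- n + tr$Nnode
  sets <- vector("list", m)
  for (i in seq_len(n)) sets[[i]] <- i
  for (k in seq_len(nrow(tr$edge))) {
    p <- tr$edge[k, 1]
    ch <- tr$edge[k, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  out <- list()
  for (nd in (n + 1):m) {
    sz <- length(sets[[nd]])
    if (sz >= 2 && sz <= n - 1) {
      out[[length(out) + 1]] <- sort(tree$tip.label[sets[[nd]]])
    }
  }
  out
}

cluster_keys <- function(clusters) {
  vapply(clusters, paste, character(1), collapse = "\r")
}

check_same_leaves <- function(t1, t2) {
  l1 <- sort(t1$tip.label)
  l2 <- sort(t2$tip.label)
  if (!identical(l1, l2)) {
    only1 <- setdiff(l1, l2)
    only2 <- setdiff(l2, l1)
    abort(paste0(
      "trees have different leaf sets",
      if (length(only1)) paste0("; only in first: ", paste(only1, collapse = ", ")) else "",
      if (length(only2)) paste0("; only in second: ", paste(only2, collapse = ", ")) else ""
    ))
  }
  l1
}

#' Robinson-Foulds distance between rooted trees
#'
#' Counts the clades present in exactly one of the two trees (symmetric
#' difference of their nontrivial cluster sets) and normalizes by the maximum
#' 2(n - 2) attainable between binary rooted trees on n leaves.
#'
#' @param t1,t2 rooted [ape::phylo] trees on the same leaf set.
#' @return a list with integer `rf` and normalized `nrf`.
#' @export
rf_dist <- function(t1, t2) {
  leaves <- check_same_leaves(t1, t2)
  n <- length(leaves)
  k1 <- cluster_keys(tree_clusters(t1))
  k2 <- cluster_keys(tree_clusters(t2))
  rf <- length(setdiff(k1, k2)) + length(setdiff(k2, k1))
  list(rf = as.integer(rf), nrf = rf / (2 * (n - 2)))
}

#' Matching-Cluster distance between rooted trees
#'
#' Pads the smaller cluster set with empty sets, scores each possible pairing
#' of clusters by the symmetric difference of their leaf memberships, and
#' takes the minimum-total-cost perfect matching (Hungarian algorithm). Unlike
#' Robinson-Foulds, near-identical clades incur a small rather than full
#' penalty.
#'
#' @inheritParams rf_dist
#' @param null_max optional positive normalizer, typically the maximum MC over
#'   a null topology set (see [congruence_test()]); if supplied, `nmc` is
#'   `mc / null_max`.
#' @return a list with integer `mc` and (if `null_max` given) `nmc`.
#' @export
mc_dist <- function(t1, t2, null_max = NULL) {
  leaves <- check_same_leaves(t1, t2)
  c1 <- tree_clusters(t1)
  c2 <- tree_clusters(t2)
  mc <- mc_from_clusters(c1, c2, leaves)
  nmc <- if (!is.null(null_max)) {
    if (null_max <= 0) abort("`null_max` must be positive")
    mc / null_max
  } else {
    NULL
  }
  list(mc = as.integer(mc), nmc = nmc)
}

# Matching-cluster cost from two cluster lists over a common leaf order.
mc_from_clusters <- function(c1, c2, leaves) {
  k <- max(length(c1), length(c2))
  if (k == 0) {
    return(0L)
  }
  memb <- function(cl) {
    m <- matrix(FALSE, k, length(leaves))
    for (i in seq_along(cl)) m[i, match(cl[[i]], leaves)] <- TRUE
    m
  }
  m1 <- memb(c1)
  m2 <- memb(c2)
  cost <- matrix(0, k, k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      cost[i, j] <- sum(xor(m1[i, ], m2[j, ]))
    }
  }
  as.integer(solve_assignment(cost)$cost)
}

#' Minimum-cost perfect matching (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' shortest-augmenting-path formulation with dual potentials, O(n^3).
#'
#' @param cost square numeric matrix of finite costs.
#' @return list with `assignment` (column assigned to each row) and the
#'   minimum total `cost`.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  if (nrow(cost) != ncol(cost)) abort("cost matrix must be square")
  if (any(!is.finite(cost))) abort("costs must be finite")
  n <- nrow(cost)
  if (n == 0) {
    return(list(assignment = integer(0), cost = 0))
  }
  u <- numeric(n)      # row potentials
  v <- numeric(n + 1)  # column potentials, index 1 = virtual column
  p <- integer(n + 1)  # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) {
    if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  }
  list(
    assignment = assignment,
    cost = sum(cost[cbind(seq_len(n), assignment)])
  )
}

# ---- rooted binary topology enumeration / sampling -------------------------

# Trees are built as nested pairs (lists of two subtrees; leaves are labels),
# then serialized to newick.

nested_newick <- function(tr) {
  if (is.list(tr)) {
    paste0("(", nested_newick(tr[[1]]), ",", nested_newick(tr[[2]]), ")")
  } else {
    tr
  }
}

nested_to_phylo <- function(tr) {
  ape::read.tree(text = paste0(nested_newick(tr), ";"))
}

# All trees obtained by attaching leaf `x` to any edge of `tr`, including
# above the root: a tree with k leaves offers 2k - 1 attachment points, which
# yields every labeled rooted binary topology exactly once.
attach_everywhere <- function(tr, x) {
  res <- list(list(tr, x))
  if (is.list(tr)) {
    for (l2 in attach_everywhere(tr[[1]], x)) {
      res[[length(res) + 1]] <- list(l2, tr[[2]])
    }
    for (r2 in attach_everywhere(tr[[2]], x)) {
      res[[length(res) + 1]] <- list(tr[[1]], r2)
    }
  }
  res
}

n_leaves_nested <- function(tr) {
  if (is.list(tr)) n_leaves_nested(tr[[1]]) + n_leaves_nested(tr[[2]]) else 1L
}

attach_at_random <- function(tr, x) {
  k <- n_leaves_nested(tr)
  slot <- sample.int(2L * k - 1L, 1L)
  attach_slot(tr, x, slot)
}

# Deterministically attach at attachment point `slot` in 1..(2k - 1):
# slot 1 = above the root, then left subtree slots, then right subtree slots.
attach_slot <- function(tr, x, slot) {
  if (slot == 1L) {
    return(list(tr, x))
  }
  slot <- slot - 1L
  nl <- 2L * n_leaves_nested(tr[[1]]) - 1L
  if (slot <= nl) {
    list(attach_slot(tr[[1]], x, slot), tr[[2]])
  } else {
    list(tr[[1]], attach_slot(tr[[2]], x, slot - nl))
  }
}

#' Enumerate all labeled rooted binary topologies
#'
#' Generates each of the (2n - 3)!! rooted binary tree shapes on the given
#' leaf labels exactly once, by sequential attachment of leaves to every edge
#' (plus the root edge). Refuses n > 7, where the count exceeds 10,000 and a
#' Monte-Carlo null should be used instead.
#'
#' @param labels character vector of 3 to 7 unique leaf labels.
#' @return list of [ape::phylo] trees.
#' @export
enumerate_topologies <- function(labels) {
  labels <- as.character(labels)
  n <- length(labels)
  if (anyDuplicated(labels)) abort("leaf labels must be unique")
  if (n < 3 || n > 7) {
    abort("exhaustive enumeration supports 3 to 7 leaves; use sample_topology() beyond")
  }
  trees <- list(labels[[1]])
  for (x in labels[-1]) {
    trees <- unlist(lapply(trees, attach_everywhere, x = x), recursive = FALSE)
  }
  lapply(trees, nested_to_phylo)
}

#' Sample a uniform random labeled rooted binary topology
#'
#' Attaches each successive leaf to an edge chosen uniformly among the
#' current 2k - 1 attachment points, which induces the uniform distribution
#' over all (2n - 3)!! labeled rooted binary topologies.
#'
#' @param labels character vector of >= 2 unique leaf labels.
#' @param seed optional integer seed for reproducibility.
#' @return an [ape::phylo] tree.
#' @export
sample_topology <- function(labels, seed = NULL) {
  labels <- as.character(labels)
  if (length(labels) < 2) abort("need at least 2 leaves")
  if (anyDuplicated(labels)) abort("leaf labels must be unique")
  with_seed(seed, {
    tr <- labels[[1]]
    for (x in labels[-1]) tr <- attach_at_random(tr, x)
    nested_to_phylo(tr)
  })
}
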