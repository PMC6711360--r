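# Analysis of similarity (ANOSIM) on dissimilarity ranks.

anosim_r <- function(rank_vec, within) {
  n_pairs <- length(rank_vec)
  (mean(rank_vec[!within]) - mean(rank_vec[within])) / (n_pairs / 2)
}

anosim_core <- function(d, g, n_permutations, seed) {
  labels <- rownames(d)
  lower <- lower.tri(d)
  rank_vec <- rank(d[lower])
  pair_i <- row(d)[lower]
  pair_j <- col(d)[lower]

  gi <- as.integer(g)
  within <- gi[pair_i] == gi[pair_j]
  if (all(within) || !any(within)) abort("need both within- and between-group pairs")
  r_obs <- anosim_r(rank_vec, within)

  perm_r <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) {
      gp <- sample(gi)
      anosim_r(rank_vec, gp[pair_i] == gp[pair_j])
    }, numeric(1))
  })
  p <- (1 + sum(perm_r >= r_obs)) / (1 + n_permutations)
  list(r = r_obs, p = p)
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of whether between-group dissimilarities exceed
#' within-group dissimilarities: `R = (rB - rW) / (M/2)` where rB and rW are
#' the mean ranks (mean-rank ties) of between- and within-group pairs and
#' `M = n(n-1)/2`. R near 1 means groups are strongly separated, 0 means no
#' structure. Significance is by Monte-Carlo permutation of group labels with
#' the add-one estimator `(1 + #{R* >= R}) / (1 + B)`. Pairwise two-group
#' ANOSIMs with Bonferroni adjustment are run for every pair of groups with
#' at least 2 members (singleton groups are excluded with a warning).
#'
#' @param d symmetric dissimilarity matrix with sample labels (or `dist`).
#' @param groups grouping vector, either named by sample or in row order.
#' @param n_permutations number of label permutations.
#' @param seed optional seed.
#' @param pairwise run pairwise comparisons too?
#' @return object of class `anosim_test` with `r`, `p_value`,
#'   `n_permutations` and a `pairwise` tibble.
#' @export
anosim <- function(d, groups, n_permutations = 999, seed = NULL, pairwise = TRUE) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) abort("distance matrix must have sample labels")
  g <- align_groups(groups, rownames(d))
  sizes <- table(g)
  if (sum(sizes >= 2) < 2) abort("need at least 2 groups with >= 2 members")

  global <- anosim_core(d, g, n_permutations, seed)

  pw <- tibble(
    group1 = character(), group2 = character(), r = numeric(),
    p_raw = numeric(), p_adjusted = numeric()
  )
  if (pairwise) {
    ok <- names(sizes)[sizes >= 2]
    dropped <- setdiff(names(sizes), ok)
    if (length(dropped) > 0) {
      warn(paste0(
        "singleton group(s) excluded from pairwise ANOSIM: ",
        paste(dropped, collapse = ", ")
      ))
    }
    prs <- combn(ok, 2)
    n_pairs <- ncol(prs)
    pw <- purrr::map_dfr(seq_len(n_pairs), function(k) {
      sel <- g %in% prs[, k]
      sub <- anosim_core(
        d[sel, sel, drop = FALSE], droplevels(g[sel]),
        n_permutations, seed
      )
      tibble(
        group1 = prs[1, k], group2 = prs[2, k], r = sub$r,
        p_raw = sub$p, p_adjusted = min(1, sub$p * n_pairs)
      )
    })
  }
  structure(
    list(
      r = global$r, p_value = global$p, n_permutations = n_permutations,
      pairwise = pw, seed = seed
    ),
    class = "anosim_test"
  )
}

#' @export
print.anosim_test <- function(x, ...) {
  cat(sprintf(
    "ANOSIM: R = %.3f, p = %.4g (%d permutations)\n",
    x$r, x$p_value, x$n_permutations
  ))
  if (nrow(x$pairwise) > 0) {
    cat("Pairwise (Bonferroni-adjusted):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}
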