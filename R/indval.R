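# Dufrene-Legendre indicator values with a permutation test.

indval_max <- function(mean_ab, occ) {
  a <- sweep(mean_ab, 2, colSums(mean_ab), "/") # specificity
  iv <- 100 * a * occ
  list(iv = iv, max = apply(iv, 2, max), best = apply(iv, 2, which.max))
}

group_summaries <- function(m, g) {
  ng <- as.vector(table(g))
  mean_ab <- rowsum(m, g) / ng
  occ <- rowsum((m > 0) * 1, g) / ng
  list(mean_ab = mean_ab, occ = occ)
}

#' Dufrene-Legendre indicator values
#'
#' For each taxon t and group g, specificity `A_tg` is the mean abundance of
#' t in g divided by the sum of its mean abundances over all groups, and
#' fidelity `B_tg` is the fraction of g's samples containing t. The indicator
#' value of t is `IndVal_t = max_g 100 * A_tg * B_tg` - 100 for a perfect
#' indicator (always present in one group, absent elsewhere). Significance of
#' each taxon's IndVal is assessed by permuting group labels
#' (`p = (1 + #{IndVal* >= IndVal}) / (1 + B)`). Taxa absent from every
#' sample are skipped.
#'
#' @param x count table tibble (counts or averaged abundances).
#' @param groups grouping vector (named by sample or in row order).
#' @param n_permutations number of label permutations.
#' @param seed optional seed.
#' @return tibble of class `indicator_values`: `taxon`, `best_group`, `a`,
#'   `b`, `indval`, `p_value`, sorted by decreasing `indval`.
#' @export
indicator_values <- function(x, groups, n_permutations = 999, seed = NULL) {
  m <- ct_matrix(x)
  g <- align_groups(groups, rownames(m))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  present <- colSums(m) > 0
  if (!all(present)) m <- m[, present, drop = FALSE]
  if (ncol(m) == 0) abort("no taxon is present in any sample")

  gs <- group_summaries(m, g)
  obs <- indval_max(gs$mean_ab, gs$occ)

  exceed <- integer(ncol(m))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      gp <- sample(g)
      ps <- group_summaries(m, gp)
      pm <- indval_max(ps$mean_ab, ps$occ)$max
      exceed <- exceed + (pm >= obs$max - 1e-12)
    }
  })
  p <- (1 + exceed) / (1 + n_permutations)

  levs <- rownames(gs$mean_ab)
  a_mat <- sweep(gs$mean_ab, 2, colSums(gs$mean_ab), "/")
  out <- tibble(
    taxon = colnames(m),
    best_group = levs[obs$best],
    a = unname(a_mat[cbind(obs$best, seq_len(ncol(m)))]),
    b = unname(gs$occ[cbind(obs$best, seq_len(ncol(m)))]),
    indval = unname(obs$max),
    p_value = p
  ) |>
    dplyr::arrange(dplyr::desc(.data$indval))
  class(out) <- c("indicator_values", class(out))
  out
}
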