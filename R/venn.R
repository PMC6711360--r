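# Shared-OTU (Venn) set analysis across 2-4 groups.

#' Shared and unique OTUs across groups
#'
#' For every non-empty subset of groups, counts the OTUs exclusive to that
#' Venn region (present in exactly those groups; presence = summed count > 0
#' within a group) and the OTUs shared by all members of the subset
#' regardless of the others. For each subset the relative abundance of its
#' shared OTU set is reported per group (share of that group's reads carried
#' by those OTUs) and pooled over the subset's groups.
#'
#' @param x count table tibble.
#' @param groups grouping vector (named by sample or in row order); 2 to 4
#'   groups supported.
#' @return tibble with one row per subset: `groups` (labels joined by `+`),
#'   `degree`, `n_exclusive`, `n_shared`, `shared_abundance` (list column of
#'   per-group shares) and `shared_abundance_pooled`.
#' @export
shared_otu_sets <- function(x, groups) {
  m <- ct_matrix(x)
  g <- align_groups(groups, rownames(m))
  levs <- levels(g)
  if (length(levs) < 2 || length(levs) > 4) {
    abort("shared-OTU analysis supports 2 to 4 groups")
  }
  totals <- rowsum(m, g) # group x OTU read totals
  pres <- totals > 0

  subsets <- unlist(
    lapply(seq_along(levs), function(k) combn(levs, k, simplify = FALSE)),
    recursive = FALSE
  )
  rows <- purrr::map(subsets, function(ss) {
    inside <- pres[ss, , drop = FALSE]
    outside <- pres[setdiff(levs, ss), , drop = FALSE]
    in_all <- colSums(inside) == length(ss)
    exclusive <- in_all & colSums(outside) == 0
    shared_reads <- vapply(
      ss, function(gr) sum(totals[gr, in_all]),
      numeric(1)
    )
    group_reads <- vapply(ss, function(gr) sum(totals[gr, ]), numeric(1))
    tibble(
      groups = paste(ss, collapse = "+"),
      degree = length(ss),
      n_exclusive = sum(exclusive),
      n_shared = sum(in_all),
      shared_abundance = list(setNames(shared_reads / group_reads, ss)),
      shared_abundance_pooled = sum(shared_reads) / sum(group_reads)
    )
  })
  dplyr::bind_rows(rows)
}
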