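# Pre-analysis transforms: depth filtering, rarefaction, section merging,
# taxonomic aggregation, relative abundance.

#' Drop samples below a sequencing-depth threshold
#'
#' Retains exactly the samples whose total read count is at least
#' `threshold` (inclusive: the smallest retained sample may define the
#' rarefaction depth itself). Sample order is preserved.
#'
#' @param x count table tibble.
#' @param threshold minimum depth, default the 20,000-read rarefaction depth.
#' @return filtered count table; warns when nothing survives.
#' @export
filter_min_depth <- function(x, threshold = 20000) {
  if (threshold <= 0) abort("`threshold` must be positive")
  m <- ct_matrix(x)
  keep <- rowSums(m) >= threshold
  if (!any(keep)) warn("no samples reach the depth threshold; empty table returned")
  x[keep, , drop = FALSE]
}

#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement down to exactly
#' `depth`, as a single draw (the mothur `sub.sample` semantics), so every
#' row of the result sums to `depth`. Reproducible under `seed`.
#'
#' @param x count table tibble of whole-number counts, every row sum >=
#'   `depth` (run [filter_min_depth()] first).
#' @param depth target depth, default 20,000.
#' @param seed optional integer seed.
#' @return rarefied count table.
#' @export
rarefy <- function(x, depth = 20000, seed = NULL) {
  m <- ct_matrix(x)
  if (any(abs(m - round(m)) > 1e-8)) abort("rarefaction needs integer counts")
  m <- round(m)
  sums <- rowSums(m)
  if (any(sums < depth)) {
    abort(paste0(
      sum(sums < depth), " sample(s) are shallower than depth ", depth,
      "; remove them with filter_min_depth() first"
    ))
  }
  with_seed(seed, {
    out <- m
    k <- ncol(m)
    for (r in seq_len(nrow(m))) {
      if (sums[r] == depth) next
      reads <- rep.int(seq_len(k), m[r, ])
      drawn <- sample(reads, depth)
      out[r, ] <- tabulate(drawn, nbins = k)
    }
    ct_tibble(out)
  })
}

#' Average intestinal-section samples into one row per individual
#'
#' Merges each individual's section samples by arithmetic mean of their
#' (rarefied, equal-depth) count rows. Individuals with 1-3 available
#' sections are averaged over whatever is present; resulting counts may be
#' fractional. Individuals listed in `info` but absent from the table are
#' excluded with a warning.
#'
#' @param x count table tibble, typically rarefied to a common depth.
#' @param info metadata tibble with `sample_id`, `individual` (and usually
#'   `species`, `section`).
#' @return count table tibble with `sample_id` holding individual IDs.
#' @export
merge_sections <- function(x, info) {
  m <- ct_matrix(x)
  idx <- match(rownames(m), info$sample_id)
  if (anyNA(idx)) {
    abort(paste0(
      "samples missing from metadata: ",
      paste(head(rownames(m)[is.na(idx)], 5), collapse = ", ")
    ))
  }
  indiv <- as.character(info$individual[idx])
  absent <- setdiff(unique(as.character(info$individual)), indiv)
  if (length(absent) > 0) {
    warn(paste0(
      length(absent), " individual(s) have no retained sections and are excluded: ",
      paste(head(absent, 5), collapse = ", ")
    ))
  }
  avg <- rowsum(m, indiv) / as.vector(table(indiv)[sort(unique(indiv))])
  ct_tibble(avg)
}

#' Aggregate OTU counts to genus or phylum
#'
#' Sums OTU columns within their taxonomy label at the requested rank;
#' per-sample totals are conserved. Every OTU in the table must be present
#' in the taxonomy.
#'
#' @param x count table tibble.
#' @param taxonomy tibble with `otu_id` and the rank columns.
#' @param rank `"genus"` or `"phylum"`.
#' @return count table tibble whose columns are rank labels (sorted).
#' @export
aggregate_rank <- function(x, taxonomy, rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  m <- ct_matrix(x)
  idx <- match(colnames(m), taxonomy$otu_id)
  if (anyNA(idx)) {
    abort(paste0(
      "OTUs missing from taxonomy: ",
      paste(head(colnames(m)[is.na(idx)], 10), collapse = ", ")
    ))
  }
  labels <- as.character(taxonomy[[rank]][idx])
  agg <- t(rowsum(t(m), labels)) # columns come out sorted by label
  ct_tibble(agg)
}

#' Convert counts to per-sample relative abundances
#'
#' Divides each row by its total. All-zero samples are flagged with a warning
#' and kept as zero rows.
#'
#' @param x count table tibble.
#' @return tibble of fractions, rows summing to 1 (or 0 for empty samples).
#' @export
to_relative <- function(x) {
  m <- ct_matrix(x)
  sums <- rowSums(m)
  if (any(sums == 0)) {
    warn(paste0(
      "empty sample(s): ", paste(head(rownames(m)[sums == 0], 5), collapse = ", ")
    ))
    sums[sums == 0] <- 1
  }
  ct_tibble(m / sums)
}
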