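# Alpha diversity: richness, Chao1, dominance, evenness, rarefaction curves.

alpha_one <- function(v) {
  if (all(v == 0)) abort("cannot compute diversity of an all-zero sample")
  pos <- v[v > 0]
  s <- length(pos)
  f1 <- sum(pos == 1)
  f2 <- sum(pos == 2)
  p <- pos / sum(pos)
  h <- -sum(p * log(p))
  tibble(
    sobs = s,
    chao1 = s + f1 * (f1 - 1) / (2 * (f2 + 1)),
    dominance = sum(p^2),
    evenness = exp(h) / s,
    f1 = f1,
    f2 = f2
  )
}

#' Per-sample alpha-diversity indices
#'
#' Computes, for every sample, the indices used to profile community
#' diversity: observed richness `sobs`; the bias-corrected Chao1 estimate
#' `S + F1(F1 - 1) / (2(F2 + 1))` (defined even when no doubletons exist);
#' dominance `D = sum(p_i^2)` (the complement of Simpson diversity: large
#' when one taxon dominates); and Buzas-Gibson evenness `exp(H) / S` with
#' Shannon entropy `H`. Singleton and doubleton counts are returned too.
#'
#' Dominance and evenness depend only on relative abundances; `sobs`, `f1`,
#' `f2` and Chao1 are depth-sensitive, so tables should be rarefied first.
#'
#' @param x count table tibble (integer counts).
#' @return tibble with one row per sample: `sample_id`, `sobs`, `chao1`,
#'   `dominance`, `evenness`, `f1`, `f2`.
#' @examples
#' tbl <- tibble::tibble(sample_id = "s1", a = 5, b = 2, c = 1, d = 1)
#' alpha_diversity(tbl) # chao1 = 4.5
#' @export
alpha_diversity <- function(x) {
  m <- ct_matrix(x)
  out <- purrr::map(seq_len(nrow(m)), function(r) alpha_one(m[r, ]))
  dplyr::bind_cols(tibble(sample_id = rownames(m)), dplyr::bind_rows(out))
}

#' Expected richness under rarefaction (interpolation)
#'
#' Hurlbert's expectation of the number of taxa observed in a random
#' subsample of size m drawn without replacement:
#' `E[S_m] = S_obs - sum_i C(N - N_i, m) / C(N, m)`, evaluated with
#' log-binomials for numerical stability. Defined for `1 <= m <= N`;
#' extrapolation beyond the sample total is not supported.
#'
#' @param counts integer count vector for one sample.
#' @param m vector of subsample sizes.
#' @return tibble with columns `m` and `expected_richness` (monotone
#'   non-decreasing, equal to `S_obs` at `m = N`).
#' @export
rarefaction_expectation <- function(counts, m) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) abort("sample has no reads")
  if (any(abs(counts - round(counts)) > 1e-8)) abort("counts must be integers")
  n <- sum(counts)
  if (any(m < 1) || any(m > n)) {
    abort(paste0("subsample sizes must be within [1, ", n, "] (no extrapolation)"))
  }
  s <- length(counts)
  es <- vapply(m, function(mm) {
    # lchoose(a, b) is -Inf when b > a, so impossible terms vanish
    s - sum(exp(lchoose(n - counts, mm) - lchoose(n, mm)))
  }, numeric(1))
  tibble(m = m, expected_richness = es)
}
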