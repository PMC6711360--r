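#' Bray-Curtis dissimilarity matrix
#'
#' Computes `d_ij = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` between all
#' sample pairs: 0 for identical rows, 1 for rows sharing no taxa. The
#' measure is invariant to multiplying both rows of a pair by the same
#' constant, so on equal-depth (rarefied) counts it coincides with the
#' relative-abundance version.
#'
#' @param x count table tibble (non-negative values; at most one all-zero
#'   row, since a pair of empty samples has no defined dissimilarity).
#' @return symmetric numeric matrix with zero diagonal and sample labels.
#' @examples
#' tbl <- tibble::tibble(sample_id = c("a", "b"), t1 = c(6, 2), t2 = c(4, 8))
#' bray_curtis(tbl) # 0.4
#' @export
bray_curtis <- function(x) {
  m <- ct_matrix(x)
  rs <- rowSums(m)
  if (sum(rs == 0) > 1) {
    abort("more than one all-zero sample: Bray-Curtis is undefined for such pairs")
  }
  manh <- as.matrix(dist(m, method = "manhattan"))
  tot <- outer(rs, rs, "+")
  d <- manh / tot
  d[tot == 0] <- 0
  diag(d) <- 0
  d
}
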