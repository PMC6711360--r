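# PERMANOVA (the ADONIS test): distance-based multivariate ANOVA with
# sequential (Type-I) sums of squares and permutation p-values.

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' Partitions a dissimilarity matrix according to a model formula, in the
#' style of the ADONIS test. The squared dissimilarities are Gower-centred,
#' `G = -1/2 C d^2 C` with `C = I - 11'/n`; each model term's sum of squares
#' is the increment `tr(H_k G) - tr(H_{k-1} G)` of the sequential
#' hat-matrix projections, so terms are assessed in formula order (Type-I).
#' Pseudo-F per term is `(SS_term / df_term) / (SS_res / df_res)` and
#' `R^2 = SS_term / SS_total`. Significance is by permutation of raw sample
#' labels (rows/columns of G), with the add-one estimator.
#'
#' Numeric covariates (e.g. an individual-bird code entered as a single
#' regression slope, df = 1) and factor-by-factor interactions are both
#' supported; a term adding no rank (aliased) is absorbed with a warning.
#'
#' @param d symmetric dissimilarity matrix with sample labels (or `dist`).
#' @param design data frame of sample-level variables, rows aligned with (or
#'   a `sample_id` column matching) the distance labels.
#' @param formula right-hand-side model formula, e.g.
#'   `~ species * section * individual`.
#' @param n_permutations number of permutations (10,000 in the headline
#'   analysis; reduce for quick runs).
#' @param seed optional seed.
#' @return object of class `permanova` whose `table` is a tibble with one
#'   row per term plus Residual and Total: `term`, `df`, `ss`, `f_model`,
#'   `r_squared`, `p_value`.
#' @export
permanova <- function(d, design, formula, n_permutations = 999, seed = NULL) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (is.null(rownames(d))) abort("distance matrix must have sample labels")
  if ("sample_id" %in% names(design)) {
    idx <- match(rownames(d), design$sample_id)
    if (anyNA(idx)) abort("design must cover every sample in the distance matrix")
    design <- design[idx, , drop = FALSE]
  } else if (nrow(design) != n) {
    abort("design must have one row per sample (or a sample_id column)")
  }

  # Gower-centred inner-product matrix
  d2 <- d^2
  cm <- diag(n) - matrix(1 / n, n, n)
  G <- -0.5 * cm %*% d2 %*% cm

  trms <- stats::terms(formula)
  term_labels <- attr(trms, "term.labels")
  if (length(term_labels) == 0) abort("formula must contain at least one term")

  # sequential hat-matrix increments per term
  hats <- vector("list", length(term_labels))
  dfs <- integer(length(term_labels))
  x_prev <- matrix(1, n, 1)
  q_prev <- qr.Q(qr(x_prev))
  h_prev <- tcrossprod(q_prev)
  rank_prev <- 1L
  for (k in seq_along(term_labels)) {
    xk <- stats::model.matrix(
      stats::reformulate(term_labels[seq_len(k)]), data = design
    )
    qk <- qr(xk)
    if (qk$rank == rank_prev) {
      warn(paste0("term '", term_labels[k], "' adds no rank; df absorbed"))
    }
    qmat <- qr.Q(qk)[, seq_len(qk$rank), drop = FALSE]
    hk <- tcrossprod(qmat)
    hats[[k]] <- hk - h_prev
    dfs[k] <- qk$rank - rank_prev
    h_prev <- hk
    rank_prev <- qk$rank
  }
  df_res <- n - 1L - sum(dfs)
  if (df_res < 0) abort("model has more df than samples allow")

  ss_total <- sum(diag(G))
  ss_terms <- vapply(hats, function(h) sum(h * G), numeric(1))
  ss_res <- ss_total - sum(ss_terms)
  degenerate <- ss_res <= 1e-12 || df_res == 0
  if (degenerate) {
    warn("residual sum of squares is (near) zero; pseudo-F is unstable")
  }
  ms_res <- if (df_res > 0) ss_res / df_res else NA_real_
  f_obs <- ifelse(dfs > 0, (ss_terms / pmax(dfs, 1)) / ms_res, NA_real_)

  p <- rep(NA_real_, length(term_labels))
  if (n_permutations > 0 && !degenerate) {
    exceed <- integer(length(term_labels))
    with_seed(seed, {
      for (b in seq_len(n_permutations)) {
        perm <- sample.int(n)
        gp <- G[perm, perm]
        ssb <- vapply(hats, function(h) sum(h * gp), numeric(1))
        fb <- (ssb / pmax(dfs, 1)) / ((ss_total - sum(ssb)) / df_res)
        exceed <- exceed + (fb >= f_obs - 1e-12)
      }
    })
    p <- ifelse(dfs > 0, (1 + exceed) / (1 + n_permutations), NA_real_)
  }

  tab <- tibble(
    term = c(term_labels, "Residual", "Total"),
    df = c(dfs, df_res, n - 1L),
    ss = c(ss_terms, ss_res, ss_total),
    f_model = c(f_obs, NA_real_, NA_real_),
    r_squared = c(ss_terms / ss_total, ss_res / ss_total, 1),
    p_value = c(p, NA_real_, NA_real_)
  )
  structure(
    list(
      table = tab, n_permutations = n_permutations, seed = seed,
      degenerate = degenerate
    ),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,", x$n_permutations, "permutations)\n")
  print(as.data.frame(x$table), row.names = FALSE, digits = 4)
  invisible(x)
}
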