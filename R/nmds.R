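# Non-metric multidimensional scaling by stress majorization with isotonic
# regression on dissimilarity ranks (Kruskal stress-1).

nmds_stress <- function(dd, dhat) {
  sqrt(sum((dd - dhat)^2) / sum(dd^2))
}

# Monotone fit of configuration distances against the dissimilarity order,
# with secondary tie treatment: tied dissimilarities share one fitted value.
nmds_dhat <- function(dd, ord, tie_group) {
  yf <- isoreg(dd[ord])$yf
  yf <- stats::ave(yf, tie_group)
  dhat <- numeric(length(dd))
  dhat[ord] <- yf
  dhat
}

nmds_one_start <- function(dm, x0, ord, tie_group, max_iter, tol) {
  n <- nrow(dm)
  x <- x0
  pair <- which(lower.tri(dm), arr.ind = TRUE)
  stress_path <- numeric(0)
  best <- NULL
  for (it in seq_len(max_iter)) {
    dd <- as.matrix(dist(x))[lower.tri(dm)]
    dhat <- nmds_dhat(dd, ord, tie_group)
    s <- nmds_stress(dd, dhat)
    if (length(stress_path) > 0 && s > utils::tail(stress_path, 1) - 1e-12) {
      # numerical guard: never report an increase; keep the previous config
      break
    }
    stress_path <- c(stress_path, s)
    best <- list(x = x, stress = s)
    if (s < 1e-8) break
    if (length(stress_path) >= 2 &&
      stress_path[length(stress_path) - 1] - s < tol) {
      break
    }
    # Guttman transform
    ratio <- ifelse(dd > 0, dhat / dd, 0)
    B <- matrix(0, n, n)
    B[cbind(pair[, 1], pair[, 2])] <- -ratio
    B <- B + t(B)
    diag(B) <- -rowSums(B)
    x <- (B %*% x) / n
  }
  converged <- length(stress_path) >= 2 &&
    (abs(diff(utils::tail(stress_path, 2))) < tol || best$stress < 1e-8)
  list(
    x = best$x, stress = best$stress, stress_path = stress_path,
    converged = converged || best$stress < 1e-8
  )
}

#' Non-metric multidimensional scaling (nMDS)
#'
#' Embeds samples in k dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities as closely
#' as possible. Alternates an isotonic (monotone) regression of configuration
#' distances on the dissimilarity order (secondary tie treatment: tied
#' dissimilarities receive a common fitted value) with a Guttman-transform
#' update of the configuration; goodness of fit is Kruskal stress-1,
#' `sqrt(sum((d - dhat)^2) / sum(d^2))`. The first start is the classical
#' (metric) MDS solution, the remaining `n_starts - 1` are random, and the
#' best final stress wins. The per-iteration stress sequence of the winning
#' start is non-increasing.
#'
#' @param d symmetric dissimilarity matrix with sample labels (or `dist`).
#' @param k embedding dimension.
#' @param n_starts number of starts (first one classical-MDS-based).
#' @param max_iter,tol iteration cap and stress-improvement tolerance.
#' @param seed optional seed for the random starts.
#' @return object of class `nmds`: `points` (tibble with `sample_id` and
#'   `NMDS1..k`), `stress`, `converged`, `stress_path`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, max_iter = 200, tol = 1e-6, seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < k + 1) abort("need at least k + 1 samples")
  if (is.null(rownames(dm))) abort("distance matrix must have sample labels")
  dv <- dm[lower.tri(dm)]
  ord <- order(dv)
  tie_group <- cumsum(c(1, diff(dv[ord]) > 1e-12))

  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      x0 <- if (s == 1) {
        x <- cmdscale(dm, k = k)
        if (ncol(x) < k) {
          x <- cbind(x, matrix(rnorm(n * (k - ncol(x)), sd = 1e-4), n))
        }
        x
      } else {
        matrix(rnorm(n * k), n, k)
      }
      fit <- nmds_one_start(dm, x0, ord, tie_group, max_iter, tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- best$x
    colnames(pts) <- paste0("NMDS", seq_len(k))
    structure(
      list(
        points = dplyr::bind_cols(
          tibble(sample_id = rownames(dm)), as_tibble(pts)
        ),
        stress = best$stress,
        converged = best$converged,
        stress_path = best$stress_path,
        n_starts = n_starts,
        seed = seed
      ),
      class = "nmds"
    )
  })
}

#' @export
print.nmds <- function(x, ...) {
  cat(sprintf(
    "nMDS: %d points, stress-1 = %.4f (%sconverged, %d starts)\n",
    nrow(x$points), x$stress, if (x$converged) "" else "not ", x$n_starts
  ))
  invisible(x)
}
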