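# broom-style tidiers for the package's result objects.

#' @rdname phylosym_tidiers
#' @param x a result object.
#' @param ... unused.
#' @method tidy anosim_test
#' @export
tidy.anosim_test <- function(x, ...) x$pairwise

#' @rdname phylosym_tidiers
#' @method glance anosim_test
#' @export
glance.anosim_test <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n_permutations = x$n_permutations)
}

#' @rdname phylosym_tidiers
#' @method tidy permanova
#' @export
tidy.permanova <- function(x, ...) x$table

#' @rdname phylosym_tidiers
#' @method glance permanova
#' @export
glance.permanova <- function(x, ...) {
  model <- x$table[!x$table$term %in% c("Residual", "Total"), , drop = FALSE]
  tibble(
    r_squared_model = sum(model$r_squared),
    df_model = sum(model$df),
    n_permutations = x$n_permutations,
    degenerate = x$degenerate
  )
}

#' Tidiers for phylosym result objects
#'
#' [tidy()] returns the per-comparison (pairwise, per-term, per-point) table
#' of a result; [glance()] returns its one-row summary.
#'
#' @name phylosym_tidiers
#' @method tidy group_test
#' @export
tidy.group_test <- function(x, ...) x$pairwise

#' @rdname phylosym_tidiers
#' @method glance group_test
#' @export
glance.group_test <- function(x, ...) {
  tibble(
    method = x$method, statistic = x$statistic,
    df1 = x$df[1], df2 = if (length(x$df) > 1) x$df[2] else NA_integer_,
    p_value = x$p_value, degenerate = x$degenerate
  )
}

#' @rdname phylosym_tidiers
#' @method tidy nmds
#' @export
tidy.nmds <- function(x, ...) x$points

#' @rdname phylosym_tidiers
#' @method glance nmds
#' @export
glance.nmds <- function(x, ...) {
  tibble(
    stress = x$stress, converged = x$converged,
    n_iterations = length(x$stress_path), n_starts = x$n_starts
  )
}

#' @rdname phylosym_tidiers
#' @method glance congruence_test
#' @export
glance.congruence_test <- function(x, ...) {
  tibble(
    rf = x$rf, nrf = x$nrf, p_rf = x$p_rf,
    mc = x$mc, nmc = x$nmc, p_mc = x$p_mc,
    null_type = x$null_type, null_size = x$null_size
  )
}

#' @rdname phylosym_tidiers
#' @method tidy congruence_test
#' @export
tidy.congruence_test <- function(x, ...) glance.congruence_test(x)
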