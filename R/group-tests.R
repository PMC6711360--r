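# Univariate group comparisons: Kruskal-Wallis + Dunn, one-way ANOVA +
# Bonferroni pairwise t-tests.

new_group_test <- function(method, statistic, df, p_value, pairwise,
                           degenerate = FALSE) {
  structure(
    list(
      method = method, statistic = statistic, df = df, p_value = p_value,
      pairwise = pairwise, degenerate = degenerate
    ),
    class = "group_test"
  )
}

#' @export
print.group_test <- function(x, ...) {
  lab <- if (x$method == "kruskal_dunn") "Kruskal-Wallis H" else "one-way ANOVA F"
  cat(sprintf(
    "%s = %.4g, df = %s, p = %.4g%s\n", lab, x$statistic,
    paste(x$df, collapse = ","), x$p_value,
    if (x$degenerate) " (degenerate)" else ""
  ))
  if (nrow(x$pairwise) > 0) {
    cat("Pairwise comparisons (Bonferroni-adjusted):\n")
    print(as.data.frame(x$pairwise), row.names = FALSE)
  }
  invisible(x)
}

check_groups <- function(values, groups) {
  g <- factor(as.character(groups))
  if (nlevels(g) < 2) abort("need at least 2 groups")
  if (any(table(g) == 0)) abort("every group must be non-empty")
  if (anyNA(values)) abort("values must not contain NA")
  g
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H across the groups (via
#' [stats::kruskal.test()]), followed by Dunn's z test for every group pair
#' using the pooled tie-corrected rank variance, with Bonferroni adjustment
#' over the `a(a-1)/2` comparisons. When every value is identical the test
#' degenerates to H = 0, p = 1.
#'
#' @param data data frame holding the response and grouping columns.
#' @param value,group column names (tidy-eval) of the numeric response and
#'   the grouping factor.
#' @return a `group_test` object; use [tidy()] for the pairwise table and
#'   [glance()] for the global test.
#' @export
kruskal_dunn <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  g <- check_groups(values, dplyr::pull(data, {{ group }}))
  n <- length(values)

  if (length(unique(values)) == 1) {
    h <- 0
    p <- 1
    degenerate <- TRUE
  } else {
    kt <- kruskal.test(values, g)
    h <- unname(kt$statistic)
    p <- kt$p.value
    degenerate <- FALSE
  }

  r <- rank(values)
  rbar <- tapply(r, g, mean)
  ng <- as.vector(table(g))
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  sigma2 <- n * (n + 1) / 12 - tie_term

  pairs <- combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    i <- match(pairs[1, k], levels(g))
    j <- match(pairs[2, k], levels(g))
    se <- sqrt(sigma2 * (1 / ng[i] + 1 / ng[j]))
    z <- if (se > 0) (rbar[[i]] - rbar[[j]]) / se else 0
    praw <- 2 * pnorm(-abs(z))
    tibble(
      group1 = pairs[1, k], group2 = pairs[2, k],
      statistic = z, p_raw = praw,
      p_adjusted = min(1, praw * n_pairs)
    )
  })
  new_group_test("kruskal_dunn", h, nlevels(g) - 1, p, pw, degenerate)
}

#' One-way ANOVA with Bonferroni pairwise t-tests
#'
#' Classical one-way F test with (a - 1, N - a) degrees of freedom, followed
#' by all pairwise t-tests using the pooled within-group standard deviation
#' and Bonferroni adjustment over the pairs. Zero within-group variance with
#' unequal means is flagged degenerate (infinite F, p = 0).
#'
#' @inheritParams kruskal_dunn
#' @return a `group_test` object.
#' @export
anova_bonferroni <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  g <- check_groups(values, dplyr::pull(data, {{ group }}))
  a <- nlevels(g)
  n <- length(values)
  if (n - a < 1) abort("need at least 1 residual degree of freedom")

  means <- tapply(values, g, mean)
  ng <- as.vector(table(g))
  ssb <- sum(ng * (means - mean(values))^2)
  ssw <- sum((values - means[as.integer(g)])^2)
  df1 <- a - 1
  df2 <- n - a

  degenerate <- FALSE
  if (ssw <= 1e-300) {
    if (ssb <= 1e-300) {
      f <- 0
      p <- 1
    } else {
      f <- Inf
      p <- 0
      degenerate <- TRUE
      warn("zero within-group variance with unequal means; F is infinite")
    }
  } else {
    f <- (ssb / df1) / (ssw / df2)
    p <- pf(f, df1, df2, lower.tail = FALSE)
  }

  s_pooled <- sqrt(ssw / df2)
  pairs <- combn(levels(g), 2)
  n_pairs <- ncol(pairs)
  pw <- purrr::map_dfr(seq_len(n_pairs), function(k) {
    i <- match(pairs[1, k], levels(g))
    j <- match(pairs[2, k], levels(g))
    se <- s_pooled * sqrt(1 / ng[i] + 1 / ng[j])
    t <- if (se > 0) (means[[i]] - means[[j]]) / se else 0
    praw <- if (se > 0) 2 * pt(-abs(t), df2) else as.numeric(means[[i]] == means[[j]])
    tibble(
      group1 = pairs[1, k], group2 = pairs[2, k],
      statistic = t, p_raw = praw,
      p_adjusted = min(1, praw * n_pairs)
    )
  })
  new_group_test("anova_bonferroni", f, c(df1, df2), p, pw, degenerate)
}
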