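# Bray-Curtis, ANOSIM, PERMANOVA, nMDS, shared-OTU sets, indicator values.

test_that("Bray-Curtis matches hand arithmetic and its invariances", {
  expect_equal(bray_curtis(ct(matrix(c(6, 2, 4, 8), 2, 2)))[1, 2], 0.4)
  expect_equal(bray_curtis(ct(matrix(c(10, 0, 0, 10), 2, 2)))[1, 2], 1)
  expect_equal(bray_curtis(ct(matrix(c(3, 3, 5, 5), 2, 2)))[1, 2], 0)
  withr::with_seed(20, {
    m <- matrix(rpois(30, 10) + 1, 3, 10)
  })
  d <- bray_curtis(ct(m))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  # joint rescaling of all rows leaves the matrix unchanged
  expect_equal(bray_curtis(ct(m * 7)), d)
  # but unequal per-row scaling changes it (depth sensitivity)
  m2 <- m
  m2[1, ] <- m2[1, ] * 5
  expect_false(isTRUE(all.equal(bray_curtis(ct(m2)), d)))
  expect_error(bray_curtis(ct(matrix(0, 2, 3))), "all-zero")
})

test_that("ANOSIM hits its boundary values", {
  # all between-pair distances exceed all within-pair distances -> R = 1
  m <- rbind(c(0, .1, .9, .9), c(.1, 0, .8, .85), c(.9, .8, 0, .1), c(.9, .85, .1, 0))
  dimnames(m) <- list(letters[1:4], letters[1:4])
  fit <- anosim(m, c("g1", "g1", "g2", "g2"), n_permutations = 99, seed = 1, pairwise = FALSE)
  expect_equal(fit$r, 1)
  # full ties -> R = 0
  m0 <- matrix(0.5, 4, 4, dimnames = dimnames(m))
  diag(m0) <- 0
  fit0 <- anosim(m0, c("g1", "g1", "g2", "g2"), n_permutations = 99, seed = 1, pairwise = FALSE)
  expect_equal(fit0$r, 0)
})

test_that("ANOSIM R and p agree with the exhaustive label-permutation oracle", {
  withr::with_seed(21, {
    m <- matrix(runif(36), 6, 6)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
  })
  g <- c("A", "A", "A", "B", "B", "B")
  # independent oracle: enumerate every assignment of 3 labels
  rv <- rank(m[lower.tri(m)])
  pi_ <- row(m)[lower.tri(m)]
  pj <- col(m)[lower.tri(m)]
  r_of <- function(members) {
    within <- (pi_ %in% members) == (pj %in% members)
    (mean(rv[!within]) - mean(rv[within])) / (length(rv) / 2)
  }
  all_r <- vapply(combn(6, 3, simplify = FALSE), r_of, numeric(1))
  r_obs <- r_of(1:3)
  p_exact <- mean(all_r >= r_obs)

  fit <- anosim(m, g, n_permutations = 1999, seed = 3, pairwise = FALSE)
  expect_equal(fit$r, r_obs)
  # Monte-Carlo p within binomial error of the exact permutation p
  expect_lt(abs(fit$p_value - p_exact), 4 * sqrt(p_exact * (1 - p_exact) / 1999) + 1e-3)
})

test_that("ANOSIM pairwise excludes singleton groups with a warning", {
  withr::with_seed(22, {
    m <- matrix(runif(49), 7, 7)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:7], letters[1:7])
  })
  g <- c("A", "A", "A", "B", "B", "B", "C")
  expect_warning(fit <- anosim(m, g, n_permutations = 99, seed = 1), "singleton")
  expect_equal(nrow(fit$pairwise), 1)
  expect_true(all(fit$pairwise$p_adjusted >= fit$pairwise$p_raw))
})

test_that("PERMANOVA reproduces the hand-worked degenerate one-way partition", {
  x <- c(0, 0, 0, 10, 10, 10)
  d <- as.matrix(dist(x))
  dimnames(d) <- list(letters[1:6], letters[1:6])
  des <- data.frame(g = rep(c("a", "b"), each = 3))
  expect_warning(
    fit <- permanova(d, des, ~g, n_permutations = 0),
    "near.*zero|zero"
  )
  tab <- fit$table
  expect_equal(tab$ss[tab$term == "g"], 150)
  expect_equal(tab$r_squared[tab$term == "g"], 1)
  expect_equal(tab$ss[tab$term == "Residual"], 0, tolerance = 1e-9)
  expect_true(fit$degenerate)
})

test_that("PERMANOVA agrees with the direct within-group sums oracle and vegan", {
  skip_if_not_installed("vegan")
  withr::with_seed(23, {
    for (rep in 1:5) {
      n <- 12
      m <- matrix(rpois(n * 15, 20), n, 15, dimnames = list(sprintf("s%02d", 1:n), NULL))
      g <- sample(rep(c("a", "b", "c"), each = 4))
      d <- bray_curtis(ct(m))
      fit <- permanova(d, data.frame(g = g), ~g, n_permutations = 0)
      ss_tot <- sum(d[lower.tri(d)]^2) / n
      ss_w <- ss_within_direct(d, g)
      expect_equal(fit$table$ss[1], ss_tot - ss_w, tolerance = 1e-9)
      ref <- vegan::adonis2(as.dist(d) ~ g, data = data.frame(g = g),
        permutations = 2, by = "terms"
      )
      expect_equal(fit$table$f_model[1], ref$F[1], tolerance = 1e-9)
      expect_equal(fit$table$r_squared[1], ref$R2[1], tolerance = 1e-9)
    }
  })
})

test_that("PERMANOVA multi-term model matches vegan adonis2 sequential SS", {
  skip_if_not_installed("vegan")
  withr::with_seed(24, {
    n <- 36
    m <- matrix(rpois(n * 20, 15), n, 20, dimnames = list(sprintf("s%02d", 1:n), NULL))
    des <- data.frame(
      sp = rep(c("a", "b", "c"), each = 12),
      sec = rep(c("x", "y", "z"), 12),
      ind = as.numeric(rep(1:6, 6))
    )
    d <- bray_curtis(ct(m))
    fit <- permanova(d, des, ~ sp * sec * ind, n_permutations = 99, seed = 1)
    ref <- vegan::adonis2(as.dist(d) ~ sp * sec * ind, data = des,
      permutations = 2, by = "terms"
    )
    keep <- seq_len(nrow(fit$table) - 2)
    expect_equal(fit$table$ss[keep], ref$SumOfSqs[keep], tolerance = 1e-9)
    expect_equal(fit$table$df[keep], ref$Df[keep])
    expect_equal(fit$table$f_model[keep], ref$F[keep], tolerance = 1e-9)
    # R^2 partition closes
    expect_equal(sum(fit$table$r_squared[seq_len(nrow(fit$table) - 1)]), 1)
    expect_equal(sum(fit$table$df[seq_len(nrow(fit$table) - 1)]), n - 1)
  })
})

test_that("PERMANOVA is invariant to sample reordering", {
  withr::with_seed(25, {
    n <- 10
    m <- matrix(rpois(n * 12, 10), n, 12, dimnames = list(sprintf("s%02d", 1:n), NULL))
  })
  g <- rep(c("a", "b"), each = 5)
  d <- bray_curtis(ct(m))
  des <- data.frame(sample_id = rownames(d), g = g)
  perm <- c(4, 9, 1, 7, 2, 10, 3, 6, 5, 8)
  fit1 <- permanova(d, des, ~g, n_permutations = 0)
  fit2 <- permanova(d[perm, perm], des, ~g, n_permutations = 0)
  expect_equal(fit1$table$f_model[1], fit2$table$f_model[1], tolerance = 1e-12)
})

test_that("null PERMANOVA R^2 averages to df / (n - 1)", {
  withr::with_seed(26, {
    n <- 12
    r2 <- replicate(300, {
      x <- matrix(rnorm(n * 5), n, 5, dimnames = list(sprintf("s%02d", 1:n), NULL))
      d <- as.matrix(dist(x))
      g <- sample(rep(c("a", "b", "c"), each = 4))
      fit <- permanova(d, data.frame(g = g), ~g, n_permutations = 0)
      fit$table$r_squared[1]
    })
  })
  expected <- 2 / 11
  expect_lt(abs(mean(r2) - expected), 3 * sd(r2) / sqrt(length(r2)))
})

test_that("nMDS embeds embeddable configurations at near-zero stress", {
  withr::with_seed(27, {
    pts <- matrix(rnorm(16), 8, 2)
  })
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(letters[1:8], letters[1:8])
  fit <- nmds(d, k = 2, n_starts = 5, seed = 1)
  expect_lt(fit$stress, 0.01)
  expect_true(fit$converged)
  expect_equal(dim(fit$points), c(8L, 3L))
})

test_that("nMDS cannot flatten 4 equidistant points into the plane", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  fit <- nmds(d, k = 2, n_starts = 10, seed = 2)
  expect_gt(fit$stress, 0.01)
})

test_that("nMDS stress decreases monotonically along the winning start", {
  withr::with_seed(28, {
    m <- matrix(rpois(10 * 15, 12), 10, 15, dimnames = list(sprintf("s%02d", 1:10), NULL))
  })
  d <- bray_curtis(ct(m))
  fit <- nmds(d, k = 2, n_starts = 6, seed = 3)
  expect_true(all(diff(fit$stress_path) <= 1e-12))
})

test_that("shared-OTU sets reproduce the toy Venn arithmetic", {
  # 3 OTUs, 2 groups, one shared OTU
  m <- rbind(
    g1a = c(5L, 0L, 3L),
    g1b = c(2L, 0L, 1L),
    g2a = c(0L, 4L, 2L),
    g2b = c(0L, 4L, 0L)
  )
  colnames(m) <- c("otuA", "otuB", "otuC")
  tbl <- phylosym:::ct_tibble(m)
  out <- shared_otu_sets(tbl, c("g1", "g1", "g2", "g2"))
  pairrow <- out[out$groups == "g1+g2", ]
  expect_equal(pairrow$n_shared, 1) # otuC present in both
  expect_equal(pairrow$n_exclusive, 1)
  # shared abundance: otuC reads / total reads
  expect_equal(
    pairrow$shared_abundance_pooled,
    (3 + 1 + 2 + 0) / sum(m)
  )
  expect_equal(
    unname(pairrow$shared_abundance[[1]]["g1"]),
    4 / 11
  )
  # exclusive regions
  expect_equal(out$n_exclusive[out$groups == "g1"], 1) # otuA
  expect_equal(out$n_exclusive[out$groups == "g2"], 1) # otuB

  # disjoint groups share nothing; identical groups share everything
  two <- function(vals) {
    mm <- matrix(vals, 2, 2, byrow = TRUE, dimnames = list(c("a", "b"), c("o1", "o2")))
    phylosym:::ct_tibble(mm)
  }
  dis <- shared_otu_sets(two(c(1L, 0L, 0L, 1L)), c("x", "y"))
  expect_equal(dis$n_shared[dis$groups == "x+y"], 0)
  same <- shared_otu_sets(two(c(1L, 2L, 1L, 2L)), c("x", "y"))
  expect_equal(same$n_shared[same$groups == "x+y"], 2)
  expect_equal(same$n_exclusive[same$groups == "x"], 0)
  five <- matrix(1L, 5, 2, dimnames = list(paste0("s", 1:5), c("o1", "o2")))
  expect_error(
    shared_otu_sets(phylosym:::ct_tibble(five), letters[1:5]), "2 to 4"
  )
})

test_that("indicator values hit the textbook anchor points", {
  # perfect indicator: always present in one group, absent elsewhere
  m <- rbind(
    a1 = c(10L, 1L), a2 = c(8L, 0L), a3 = c(12L, 2L),
    b1 = c(0L, 1L), b2 = c(0L, 3L), b3 = c(0L, 2L)
  )
  colnames(m) <- c("perfect", "even")
  g <- rep(c("A", "B"), each = 3)
  fit <- indicator_values(phylosym:::ct_tibble(m), g, n_permutations = 199, seed = 1)
  perfect <- fit[fit$taxon == "perfect", ]
  expect_equal(perfect$indval, 100)
  expect_equal(perfect$best_group, "A")

  # equal mean abundance and full occurrence everywhere: IndVal = 100 / g
  m2 <- rbind(
    a1 = c(4L), a2 = c(4L), b1 = c(4L), b2 = c(4L), c1 = c(4L), c2 = c(4L)
  )
  colnames(m2) <- "ubiquitous"
  fit2 <- indicator_values(
    phylosym:::ct_tibble(m2), rep(c("A", "B", "C"), each = 2),
    n_permutations = 99, seed = 1
  )
  expect_equal(fit2$indval, 100 / 3, tolerance = 1e-9)
})

test_that("indicator permutation p matches the exhaustive assignment oracle", {
  # perfect indicator with balanced 4 + 4 groups
  m <- cbind(perfect = c(5L, 6L, 7L, 8L, 0L, 0L, 0L, 0L))
  rownames(m) <- sprintf("s%d", 1:8)
  tbl <- phylosym:::ct_tibble(m)
  g <- rep(c("A", "B"), each = 4)

  # oracle: enumerate all C(8,4) assignments of the A labels
  assignments <- combn(8, 4, simplify = FALSE)
  stat <- vapply(assignments, function(idx) {
    gg <- ifelse(seq_len(8) %in% idx, "A", "B")
    means <- tapply(m[, 1], gg, mean)
    occ <- tapply(m[, 1] > 0, gg, mean)
    max(100 * (means / sum(means)) * occ)
  }, numeric(1))
  obs <- stat[[1]] # 1:4 = observed grouping is the first combination
  p_exact <- mean(stat >= obs)
  expect_equal(p_exact, 2 / 70) # only the two aligned splits reach 100

  fit <- indicator_values(tbl, g, n_permutations = 4999, seed = 5)
  expect_lt(
    abs(fit$p_value[1] - p_exact),
    4 * sqrt(p_exact * (1 - p_exact) / 4999) + 1e-3
  )
})

test_that("species separation on default synthetic data yields strong ANOSIM signal", {
  ok <- vapply(1:20, function(i) {
    ds <- simulate_count_table(generator_config(seed = 3000 + i))
    rare <- rarefy(filter_min_depth(ds$counts, 20000), 20000, seed = 4000 + i)
    info <- ds$info[ds$info$sample_id %in% rare$sample_id, ]
    merged <- merge_sections(rare, info)
    sp <- info$species[match(merged$sample_id, info$individual)]
    fit <- anosim(bray_curtis(merged), sp, n_permutations = 199, pairwise = FALSE)
    fit$p_value <= 0.05 && fit$r > 0.3
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})
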