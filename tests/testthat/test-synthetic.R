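# Synthetic community generator: profiles, Dirichlet variation, count tables,
# host tree fixture.

test_that("default profiles carry the literature prevalences and phylum totals", {
  p <- species_profiles()
  get <- function(sp, g) p$mean_fraction[p$species == sp & p$genus == g]
  expect_equal(get("gull", "Catellicoccus"), 0.5886)
  expect_equal(get("gull", "Lactobacillus"), 0.0645)
  expect_equal(get("cormorant", "Fusobacterium"), 0.3243)
  expect_equal(get("cormorant", "Campylobacter"), 0.0816)
  expect_equal(get("night_heron", "Cetobacterium"), 0.1333)
  # unclassified Clostridiaceae defaults to the midpoint of its range
  expect_equal(get("egret", "Clostridiaceae_unclassified"), (0.0818 + 0.1406) / 2)

  # per-species fractions sum to one
  sums <- tapply(p$mean_fraction, p$species, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # phylum aggregates reproduce the configured totals
  phy <- tapply(p$mean_fraction, list(p$species, p$phylum), sum)
  expect_equal(unname(phy["gull", "Firmicutes"]), 0.903)
  expect_equal(unname(phy["gull", "Proteobacteria"]), 0.092)
  expect_equal(unname(phy["gull", "Fusobacteria"]), 0.003)
  expect_equal(unname(phy["cormorant", "Fusobacteria"]), 0.394)
  expect_equal(unname(phy["night_heron", "Fusobacteria"]), 0.486)
  expect_equal(unname(phy["egret", "Firmicutes"]), 0.400)
})

test_that("a single-genus profile concentrates its phylum at 1", {
  p <- species_profiles(
    named_genera = tibble::tibble(
      species = "x", genus = "OnlyGenus", phylum = "OnlyPhylum", mean_fraction = 1
    ),
    phylum_totals = tibble::tibble(
      species = "x", phylum = "OnlyPhylum", total = 1
    )
  )
  expect_equal(sum(p$mean_fraction[p$phylum == "OnlyPhylum"]), 1)
})

test_that("overfull named-genus mass is a configuration error", {
  expect_error(
    species_profiles(
      named_genera = tibble::tibble(
        species = "x", genus = c("g1", "g2"), phylum = "P",
        mean_fraction = c(0.8, 0.5)
      ),
      phylum_totals = tibble::tibble(species = "x", phylum = "P", total = 1)
    ),
    "exceed"
  )
})

test_that("Dirichlet draws are centred on the profile and collapse at high concentration", {
  prof <- species_profiles()
  gull <- prof[prof$species == "gull", ]
  mu <- simulate_individual_composition(gull, Inf)
  expect_equal(sum(mu), 1, tolerance = 1e-9)
  cat_ids <- names(mu)[startsWith(names(mu), "Otu")]
  # infinite concentration returns the mean exactly
  mu2 <- simulate_individual_composition(gull, 1e9, seed = 1)
  expect_equal(mu2, mu, tolerance = 1e-3)

  # Monte-Carlo moment check: mean of many draws within 3 SE of the mean
  withr::with_seed(4, {
    draws <- replicate(
      800, simulate_individual_composition(gull, 50)
    )
  })
  est <- rowMeans(draws)
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  big <- mu > 0.01
  expect_true(all(abs(est[big] - mu[big]) <= 3 * se[big] + 1e-12))

  # determinism under seed
  a <- simulate_individual_composition(gull, 50, seed = 7)
  b <- simulate_individual_composition(gull, 50, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_individual_composition(gull[0, ], 50), "empty")
})

test_that("count tables have the configured shape and exact depth conservation", {
  ds <- simulate_count_table(generator_config(seed = 5))
  expect_equal(nrow(ds$counts), (7 + 11 + 8 + 5) * 3)
  expect_equal(nrow(ds$info), nrow(ds$counts))
  m <- phylosym:::ct_matrix(ds$counts)
  # every OTU mapped to genus and phylum
  expect_setequal(colnames(m), ds$taxonomy$otu_id)
  expect_false(anyNA(ds$taxonomy$genus))
  expect_false(anyNA(ds$taxonomy$phylum))
  # integer depth conservation and section/individual encoding
  expect_true(all(rowSums(m) >= 10000))
  expect_true(all(grepl("^(cormorant|egret|night_heron|gull)_\\d+_(anterior|middle|posterior)$",
    rownames(m)
  )))

  # no shallow samples when the shallow fraction is zero
  ds0 <- simulate_count_table(generator_config(
    depth_shallow_fraction = 0, seed = 6,
    n_individuals = c(cormorant = 2, egret = 2, night_heron = 2, gull = 2)
  ))
  expect_true(all(rowSums(phylosym:::ct_matrix(ds0$counts)) >= 20000))
})

test_that("generation is bit-reproducible under a fixed seed", {
  cfg <- generator_config(
    seed = 77,
    n_individuals = c(cormorant = 2, egret = 2, night_heron = 2, gull = 2)
  )
  a <- simulate_count_table(cfg)
  b <- simulate_count_table(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$info, b$info)
})

test_that("deep gull samples recover Catellicoccus within multinomial noise", {
  cfg <- generator_config(
    n_individuals = c(cormorant = 1, egret = 1, night_heron = 1, gull = 1),
    individual_concentration = 1e7, # isolate the multinomial layer
    depth_shallow_fraction = 0, seed = 8
  )
  ds <- simulate_count_table(cfg)
  gen <- aggregate_rank(ds$counts, ds$taxonomy, "genus")
  rel <- to_relative(gen)
  gull <- rel[grepl("^gull", rel$sample_id), ]
  depth <- rowSums(phylosym:::ct_matrix(ds$counts)[gull$sample_id, ])
  p0 <- 0.5886
  se <- sqrt(p0 * (1 - p0) / depth)
  expect_true(all(abs(gull$Catellicoccus - p0) <= 4 * se))
})

test_that("phylum means of deep samples recover the configured totals", {
  cfg <- generator_config(
    n_individuals = c(cormorant = 12, egret = 12, night_heron = 12, gull = 12),
    depth_shallow_fraction = 0, seed = 9, sections_per_individual = 1
  )
  ds <- simulate_count_table(cfg)
  rel <- to_relative(aggregate_rank(ds$counts, ds$taxonomy, "phylum"))
  sp <- ds$info$species[match(rel$sample_id, ds$info$sample_id)]
  check <- function(species, phylum, target) {
    v <- rel[[phylum]][sp == species]
    se <- sd(v) / sqrt(length(v))
    expect_lte(abs(mean(v) - target), 3 * se + 0.002)
  }
  check("gull", "Firmicutes", 0.903)
  check("cormorant", "Fusobacteria", 0.394)
  check("night_heron", "Fusobacteria", 0.486)
  check("egret", "Firmicutes", 0.400)
})

test_that("same-species pairs are closer than cross-species pairs", {
  ds <- simulate_count_table(generator_config(
    seed = 10, depth_shallow_fraction = 0, sections_per_individual = 1
  ))
  d <- bray_curtis(rarefy(ds$counts, 20000, seed = 10))
  sp <- ds$info$species[match(rownames(d), ds$info$sample_id)]
  same <- outer(sp, sp, "==")[lower.tri(d)]
  dv <- d[lower.tri(d)]
  withr::with_seed(11, {
    hits <- replicate(400, {
      dv[sample(which(same), 1)] < dv[sample(which(!same), 1)]
    })
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the host tree fixture has the expected clades and round-trips", {
  h <- host_phylogeny()
  expect_setequal(h$tip.label, c("egret", "night_heron", "cormorant", "gull"))
  keys <- phylosym:::cluster_keys(tree_clusters(h))
  expect_setequal(keys, c("egret\rnight_heron", "cormorant\regret\rnight_heron"))
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(h, tmp)
  back <- ape::read.tree(tmp)
  expect_equal(rf_dist(h, back)$rf, 0L)
})
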