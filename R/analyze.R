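# End-to-end orchestration: filter -> rarefy -> alpha -> beta -> merge ->
# species-level statistics -> phylosymbiosis report.

stage_log <- function(stage, detail) {
  inform(paste0("[phylosym] ", stage, ": ", detail))
}

#' Run the full phylosymbiosis analysis pipeline
#'
#' Wires the modules into the end-to-end analysis: depth filtering and
#' rarefaction of the count table; per-sample alpha diversity with
#' Kruskal-Wallis/Dunn comparisons across host species; section-level
#' Bray-Curtis statistics (ANOSIM over species; PERMANOVA of
#' species * section * individual, the individual entering as a single
#' numeric covariate so it costs one df); section merging; species-level
#' ANOSIM, nMDS, shared-OTU sets and genus-level indicator values; and the
#' dendrogram-vs-phylogeny congruence report.
#'
#' @param counts count table tibble (or path to a counts TSV).
#' @param info sample metadata tibble (or path).
#' @param taxonomy taxonomy tibble (or path).
#' @param host host phylogeny (`phylo`, or path to a newick file).
#' @param depth rarefaction depth (reads per sample).
#' @param adonis_permutations permutations for the PERMANOVA.
#' @param permutations permutations for the other permutation tests.
#' @param nmds_starts random starts for the nMDS.
#' @param seed integer seed driving every stochastic stage.
#' @param out_dir optional directory; when given, tabular reports are written
#'   there as TSV plus a JSON manifest with the seed and config hash.
#' @return object of class `phylosym_analysis`: a list with `alpha`,
#'   `alpha_tests`, `adonis`, `anosim_sections`, `anosim_species`, `nmds`,
#'   `venn`, `indicators`, `phylosymbiosis`, and bookkeeping in `log`.
#' @export
analyze_dataset <- function(counts, info, taxonomy, host = host_phylogeny(),
                            depth = 20000, adonis_permutations = 10000,
                            permutations = 999, nmds_starts = 20,
                            seed = 1L, out_dir = NULL) {
  if (is.character(counts)) counts <- read_count_table(counts)
  if (is.character(info)) info <- read_metadata(info)
  if (is.character(taxonomy)) taxonomy <- read_taxonomy(taxonomy)
  if (is.character(host)) host <- ape::read.tree(host)
  if (permutations < 100 || adonis_permutations < 100) {
    abort("permutation counts must be >= 100")
  }
  seed <- as.integer(seed)

  n_raw <- nrow(counts)
  retained <- filter_min_depth(counts, depth)
  stage_log("filter", paste0(n_raw, " samples in, ", nrow(retained), " retained at depth >= ", depth))
  rare <- rarefy(retained, depth, seed = seed)
  stage_log("rarefy", paste0(nrow(rare), " samples x ", ncol(rare) - 1, " OTUs at depth ", depth))

  info_kept <- info[info$sample_id %in% rare$sample_id, , drop = FALSE]
  species_of_sample <- setNames(as.character(info_kept$species), info_kept$sample_id)

  # alpha diversity at OTU and genus level, compared across species
  alpha_otu <- alpha_diversity(rare) |>
    dplyr::mutate(level = "otu", species = species_of_sample[.data$sample_id])
  genus_tbl <- aggregate_rank(rare, taxonomy, "genus")
  alpha_genus <- alpha_diversity(genus_tbl) |>
    dplyr::mutate(level = "genus", species = species_of_sample[.data$sample_id])
  alpha <- dplyr::bind_rows(alpha_otu, alpha_genus)
  alpha_tests <- list()
  for (lev in c("otu", "genus")) {
    for (index in c("sobs", "chao1", "dominance", "evenness")) {
      alpha_tests[[paste(lev, index, sep = "_")]] <- kruskal_dunn(
        alpha[alpha$level == lev, , drop = FALSE], !!index, !!"species"
      )
    }
  }
  stage_log("alpha", paste0(nrow(alpha), " index rows, ", length(alpha_tests), " group tests"))

  # section-level beta statistics
  d_sections <- bray_curtis(rare)
  design <- tibble(
    sample_id = info_kept$sample_id,
    species = factor(info_kept$species),
    section = factor(info_kept$section),
    individual = as.numeric(factor(info_kept$individual))
  )
  adonis <- permanova(
    d_sections, design, ~ species * section * individual,
    n_permutations = adonis_permutations, seed = seed + 1L
  )
  anosim_sections <- anosim(
    d_sections, species_of_sample[rownames(d_sections)],
    n_permutations = permutations, seed = seed + 2L
  )
  stage_log("beta_sections", paste0(nrow(d_sections), " samples, ADONIS + ANOSIM done"))

  # merge sections, species-level statistics
  merged <- merge_sections(rare, info_kept)
  indiv_species <- setNames(
    as.character(info_kept$species)[match(merged$sample_id, info_kept$individual)],
    merged$sample_id
  )
  d_indiv <- bray_curtis(merged)
  anosim_species <- anosim(
    d_indiv, indiv_species,
    n_permutations = permutations, seed = seed + 3L
  )
  ord <- nmds(d_indiv, k = 2, n_starts = nmds_starts, seed = seed + 4L)
  venn <- shared_otu_sets(merged, indiv_species)
  genus_merged <- aggregate_rank(merged, taxonomy, "genus")
  indicators <- indicator_values(
    genus_merged, indiv_species,
    n_permutations = permutations, seed = seed + 5L
  )
  stage_log("species_level", paste0(
    nrow(merged), " individuals; ANOSIM R = ", round(anosim_species$r, 3),
    ", nMDS stress = ", round(ord$stress, 3)
  ))

  phylo_report <- phylosymbiosis_report(rare, info_kept, host, seed = seed + 6L)
  stage_log("phylosymbiosis", paste0(nrow(phylo_report), " datasets compared to host tree"))

  result <- structure(
    list(
      alpha = alpha, alpha_tests = alpha_tests,
      adonis = adonis, anosim_sections = anosim_sections,
      anosim_species = anosim_species, nmds = ord, venn = venn,
      indicators = indicators, phylosymbiosis = phylo_report,
      log = list(
        seed = seed, depth = depth, n_raw = n_raw, n_retained = nrow(rare),
        adonis_permutations = adonis_permutations, permutations = permutations
      )
    ),
    class = "phylosym_analysis"
  )
  if (!is.null(out_dir)) write_analysis_reports(result, out_dir)
  result
}

#' @export
print.phylosym_analysis <- function(x, ...) {
  cat("phylosym analysis:", x$log$n_retained, "of", x$log$n_raw,
    "samples at depth", x$log$depth, "\n\n"
  )
  cat("ADONIS:\n")
  print(as.data.frame(x$adonis$table), row.names = FALSE, digits = 4)
  cat(sprintf(
    "\nANOSIM over species (individuals): R = %.3f, p = %.4g\n",
    x$anosim_species$r, x$anosim_species$p_value
  ))
  cat("\nPhylosymbiosis:\n")
  print(as.data.frame(x$phylosymbiosis[, 1:8]), row.names = FALSE, digits = 3)
  invisible(x)
}

write_analysis_reports <- function(result, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  hash <- rlang::hash(result$log)
  provenance <- sprintf("# seed=%d config_hash=%s", result$log$seed, hash)
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    writeLines(provenance, path)
    readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
    path
  }
  emit(result$alpha, "alpha_diversity.tsv")
  emit(result$adonis$table, "adonis.tsv")
  emit(
    dplyr::bind_rows(
      tibble(
        group1 = "(global)", group2 = "", r = result$anosim_species$r,
        p_raw = result$anosim_species$p_value, p_adjusted = NA_real_
      ),
      result$anosim_species$pairwise
    ),
    "anosim_species.tsv"
  )
  emit(result$indicators, "indicator_values.tsv")
  emit(
    dplyr::select(result$venn, -"shared_abundance"),
    "venn_regions.tsv"
  )
  emit(result$nmds$points, "nmds_coordinates.tsv")
  emit(
    tibble::as_tibble(result$phylosymbiosis),
    "phylosymbiosis.tsv"
  )
  jsonlite::write_json(
    c(result$log, list(config_hash = hash)),
    file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(out_dir)
}
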