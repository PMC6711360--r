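# Synthetic community generation: Dirichlet-multinomial draws around the
# per-species mean profiles.

# Global OTU catalogue for a profile set: each genus is split into
# `otus_per_genus` OTUs with geometric within-genus weights (ratio r), giving
# a realistic rank-abundance structure without extra parameters.
otu_catalogue <- function(profiles, otus_per_genus, geometric_ratio) {
  genera <- dplyr::distinct(profiles, .data$genus, .data$phylum) |>
    dplyr::arrange(.data$genus)
  w <- geometric_ratio^(seq_len(otus_per_genus) - 1)
  w <- w / sum(w)
  out <- tidyr::crossing(genera, rank = seq_len(otus_per_genus)) |>
    dplyr::arrange(.data$genus, .data$rank) |>
    dplyr::mutate(weight = w[.data$rank])
  out$otu_id <- sprintf("Otu%04d", seq_len(nrow(out)))
  out[, c("otu_id", "genus", "phylum", "rank", "weight")]
}

# OTU-level mean fractions for one species, over the full catalogue.
otu_means <- function(profiles_one, catalogue) {
  mu <- setNames(rep(0, nrow(catalogue)), catalogue$otu_id)
  idx <- match(catalogue$genus, profiles_one$genus)
  hit <- !is.na(idx)
  mu[hit] <- profiles_one$mean_fraction[idx[hit]] * catalogue$weight[hit]
  mu
}

rdirichlet_one <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(x)
  if (s == 0) {
    # all mass collapsed numerically; fall back to the largest-alpha component
    x[which.max(alpha)] <- 1
    s <- 1
  }
  x / s
}

#' Simulate one individual's gut community composition
#'
#' Draws an OTU-level composition from a Dirichlet distribution centred on
#' the species' mean profile: genus means are expanded into OTUs via the
#' fixed geometric split, then a Dirichlet vector with concentration
#' `concentration * mean` is drawn. As `concentration` grows the draw
#' converges to the mean; small concentrations give sparse, individual
#' communities (each bird hosts its own variant of the species profile).
#'
#' @param profile profile tibble for a single species (columns `genus`,
#'   `phylum`, `mean_fraction`), e.g. one species' rows of
#'   [species_profiles()].
#' @param concentration positive Dirichlet concentration scalar; `Inf`
#'   returns the mean composition exactly.
#' @param otus_per_genus,geometric_ratio genus-to-OTU expansion settings.
#' @param seed optional seed.
#' @return named numeric vector of OTU fractions summing to 1.
#' @export
simulate_individual_composition <- function(profile, concentration,
                                            otus_per_genus = 5,
                                            geometric_ratio = 0.5,
                                            seed = NULL) {
  if (nrow(profile) == 0) abort("empty species profile")
  if (concentration <= 0) abort("`concentration` must be positive")
  catalogue <- otu_catalogue(profile, otus_per_genus, geometric_ratio)
  mu <- otu_means(profile, catalogue)
  if (!is.finite(concentration)) {
    return(mu / sum(mu))
  }
  with_seed(seed, {
    p <- rep(0, length(mu))
    pos <- mu > 0
    p[pos] <- rdirichlet_one(concentration * mu[pos])
    setNames(p, names(mu))
  })
}

#' Simulate a multi-species OTU count table
#'
#' Generates the full synthetic dataset: for every individual of every
#' species a Dirichlet composition is drawn ([simulate_individual_composition()]),
#' and each of its intestinal sections is an independent multinomial sample
#' from that same composition at a simulated library size - sections carry no
#' systematic effect beyond sampling noise, mirroring the finding that
#' intestinal section does not structure the communities. A configured
#' fraction of libraries is drawn shallow (below `depth_min`) so the depth
#' filter has work to do.
#'
#' @param config a [generator_config()].
#' @return list of class `phylosym_dataset` with elements `counts` (wide
#'   tibble, `sample_id` first), `info` (sample metadata), `taxonomy`
#'   (`otu_id`, `genus`, `phylum`), and the `config`.
#' @examples
#' ds <- simulate_count_table(generator_config(seed = 42))
#' dim(ds$counts)
#' @export
simulate_count_table <- function(config) {
  if (!inherits(config, "generator_config")) abort("`config` must be a generator_config")
  catalogue <- otu_catalogue(
    config$profiles, config$otus_per_genus, config$geometric_ratio
  )
  sections <- c("anterior", "middle", "posterior")[seq_len(config$sections_per_individual)]
  if (config$sections_per_individual > 3) {
    sections <- c(sections, paste0("section", 4:config$sections_per_individual))
  }

  with_seed(config$seed, {
    rows <- list()
    info <- list()
    for (sp in sort(names(config$n_individuals))) {
      prof <- config$profiles[config$profiles$species == sp, , drop = FALSE]
      mu <- otu_means(prof, catalogue)
      pos <- mu > 0
      for (i in seq_len(config$n_individuals[[sp]])) {
        comp <- rep(0, length(mu))
        comp[pos] <- rdirichlet_one(config$individual_concentration * mu[pos])
        indiv <- sprintf("%s_%02d", sp, i)
        for (sec in sections) {
          shallow <- config$depth_shallow_fraction > 0 &&
            runif(1) < config$depth_shallow_fraction
          depth <- if (shallow) {
            floor(runif(1, 0.5, 0.99999) * config$depth_min)
          } else {
            max(
              config$depth_min,
              round(rlnorm(1, log(config$depth_mean), config$depth_sdlog))
            )
          }
          id <- paste0(indiv, "_", sec)
          rows[[id]] <- as.integer(rmultinom(1, depth, comp))
          info[[id]] <- tibble(
            sample_id = id, species = sp, individual = indiv, section = sec
          )
        }
      }
    }
    counts <- do.call(rbind, rows)
    colnames(counts) <- catalogue$otu_id
    structure(
      list(
        counts = ct_tibble(counts),
        info = dplyr::bind_rows(info),
        taxonomy = tibble(
          otu_id = catalogue$otu_id,
          genus = catalogue$genus,
          phylum = catalogue$phylum
        ),
        config = config
      ),
      class = "phylosym_dataset"
    )
  })
}

#' @export
print.phylosym_dataset <- function(x, ...) {
  cat(
    "Synthetic community dataset:", nrow(x$counts), "samples x",
    ncol(x$counts) - 1, "OTUs,", length(unique(x$info$species)), "species\n"
  )
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the four pipeline inputs as plain text - counts TSV (first column
#' `sample_id`), taxonomy TSV, metadata TSV, host tree newick - plus a JSON
#' manifest recording the seed and a hash of the full configuration, so runs
#' are auditable and re-readable by [read_count_table()] and friends.
#'
#' @param dataset a `phylosym_dataset` from [simulate_count_table()], or a
#'   [generator_config()] (which is simulated first).
#' @param dir output directory (created if needed).
#' @param host host phylogeny to write alongside, default [host_phylogeny()].
#' @return invisibly, a named character vector of the file paths written.
#' @export
simulate_dataset <- function(dataset, dir, host = host_phylogeny()) {
  if (inherits(dataset, "generator_config")) dataset <- simulate_count_table(dataset)
  if (!inherits(dataset, "phylosym_dataset")) {
    abort("`dataset` must be a phylosym_dataset or generator_config")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    taxonomy = file.path(dir, "taxonomy.tsv"),
    metadata = file.path(dir, "metadata.tsv"),
    host_tree = file.path(dir, "host_tree.nwk"),
    manifest = file.path(dir, "manifest.json")
  )
  write_count_table(dataset$counts, paths[["counts"]])
  readr::write_tsv(dataset$taxonomy, paths[["taxonomy"]])
  readr::write_tsv(dataset$info, paths[["metadata"]])
  ape::write.tree(host, file = paths[["host_tree"]])
  jsonlite::write_json(
    list(
      seed = dataset$config$seed,
      config_hash = rlang::hash(dataset$config),
      n_samples = nrow(dataset$counts),
      n_otus = ncol(dataset$counts) - 1L,
      species = sort(unique(dataset$info$species))
    ),
    paths[["manifest"]],
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(paths)
}
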