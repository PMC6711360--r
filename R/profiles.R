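#' Mean community profiles of the four waterbird species
#'
#' Builds the per-species mean genus composition used by the synthetic-data
#' generator. Named genera carry the prevalences reported for the study
#' populations (e.g. *Catellicoccus* 58.86% in black-headed gulls,
#' *Fusobacterium* 32.43% in great cormorants); the remaining mass of each
#' phylum is spread over unnamed "background" genera - a small set shared by
#' all species plus a larger species-specific set - so that the phylum totals
#' (gull: Firmicutes 90.3%, Proteobacteria 9.2%, Fusobacteria 0.3%; cormorant
#' Fusobacteria 39.4%; night heron Fusobacteria 48.6%; egret Firmicutes
#' 40.0%) are reproduced exactly while most genera stay species-specific.
#'
#' The unclassified *Clostridiaceae* genus is reported only as a range
#' (8.18-14.06%) across species; the default takes the midpoint.
#'
#' @param named_genera optional replacement tibble with columns `species`,
#'   `genus`, `phylum`, `mean_fraction` for the named (literature-valued)
#'   genera.
#' @param phylum_totals optional replacement tibble with columns `species`,
#'   `phylum`, `total` (fractions summing to 1 per species).
#' @param n_background_unique,n_background_shared number of species-specific
#'   and shared background genera per phylum.
#' @return tibble with columns `species`, `genus`, `phylum`, `mean_fraction`;
#'   fractions sum to 1 within each species.
#' @examples
#' p <- species_profiles()
#' subset(p, species == "gull" & genus == "Catellicoccus")
#' @export
species_profiles <- function(named_genera = NULL, phylum_totals = NULL,
                             n_background_unique = 6, n_background_shared = 2) {
  uc <- (0.0818 + 0.1406) / 2 # unclassified Clostridiaceae, range midpoint
  if (is.null(named_genera)) {
    named_genera <- dplyr::tribble(
      ~species, ~genus, ~phylum, ~mean_fraction,
      "cormorant", "Fusobacterium", "Fusobacteria", 0.3243,
      "cormorant", "Clostridium_sensu_stricto", "Firmicutes", 0.0869,
      "cormorant", "Campylobacter", "Proteobacteria", 0.0816,
      "cormorant", "Clostridiaceae_unclassified", "Firmicutes", uc,
      "egret", "Fusobacterium", "Fusobacteria", 0.1981,
      "egret", "Cetobacterium", "Fusobacteria", 0.1067,
      "egret", "Helicobacter", "Proteobacteria", 0.0720,
      "egret", "Clostridium_sensu_stricto", "Firmicutes", 0.0600,
      "egret", "Clostridiaceae_unclassified", "Firmicutes", uc,
      "night_heron", "Fusobacterium", "Fusobacteria", 0.2730,
      "night_heron", "Cetobacterium", "Fusobacteria", 0.1333,
      "night_heron", "Helicobacter", "Proteobacteria", 0.1110,
      "night_heron", "Clostridium_sensu_stricto", "Firmicutes", 0.0600,
      "night_heron", "Clostridiaceae_unclassified", "Firmicutes", uc,
      "gull", "Catellicoccus", "Firmicutes", 0.5886,
      "gull", "Lactobacillus", "Firmicutes", 0.0645,
      "gull", "Clostridium_sensu_stricto", "Firmicutes", 0.0475,
      "gull", "Clostridiaceae_unclassified", "Firmicutes", uc
    )
  }
  if (is.null(phylum_totals)) {
    phylum_totals <- dplyr::tribble(
      ~species, ~phylum, ~total,
      "cormorant", "Fusobacteria", 0.394,
      "cormorant", "Firmicutes", 0.350,
      "cormorant", "Proteobacteria", 0.256,
      "egret", "Firmicutes", 0.400,
      "egret", "Fusobacteria", 0.350,
      "egret", "Proteobacteria", 0.250,
      "night_heron", "Fusobacteria", 0.486,
      "night_heron", "Firmicutes", 0.300,
      "night_heron", "Proteobacteria", 0.214,
      "gull", "Firmicutes", 0.903,
      "gull", "Proteobacteria", 0.092,
      "gull", "Fusobacteria", 0.003,
      "gull", "Bacteroidetes", 0.002
    )
  }

  tot_by_sp <- tapply(phylum_totals$total, phylum_totals$species, sum)
  if (any(abs(tot_by_sp - 1) > 1e-9)) {
    abort("phylum totals must sum to 1 for every species")
  }
  named_by_sp <- tapply(named_genera$mean_fraction, named_genera$species, sum)
  if (any(named_by_sp > 1 + 1e-9)) {
    abort("named-genus mass exceeds 1 for at least one species")
  }

  rows <- list(named_genera)
  for (sp in unique(phylum_totals$species)) {
    for (ph in phylum_totals$phylum[phylum_totals$species == sp]) {
      total <- phylum_totals$total[phylum_totals$species == sp & phylum_totals$phylum == ph]
      named <- named_genera$mean_fraction[named_genera$species == sp & named_genera$phylum == ph]
      bg <- total - sum(named)
      if (bg < -1e-9) {
        abort(paste0(
          "named genera of phylum ", ph, " exceed its configured total for ", sp
        ))
      }
      if (bg <= 1e-12) next
      n_bg <- n_background_shared + n_background_unique
      genera <- c(
        if (n_background_shared > 0) paste0(ph, "_bg_shared_", seq_len(n_background_shared)),
        if (n_background_unique > 0) paste0(ph, "_bg_", sp, "_", seq_len(n_background_unique))
      )
      rows[[length(rows) + 1]] <- tibble(
        species = sp, genus = genera, phylum = ph,
        mean_fraction = bg / n_bg
      )
    }
  }
  out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$species, .data$phylum, .data$genus)
  sums <- tapply(out$mean_fraction, out$species, sum)
  stopifnot(all(abs(sums - 1) < 1e-9))
  out
}

#' Configuration for the synthetic community generator
#'
#' Bundles and validates the simulation parameters: the per-species mean
#' profiles, cohort sizes (7 cormorants, 11 egrets, 8 night herons, 5 gulls,
#' matching the study populations), three intestinal sections per individual,
#' the genus-to-OTU expansion, the Dirichlet concentration controlling
#' between-individual compositional variation, and the library-size model
#' (log-normal around `depth_mean`, truncated at `depth_min`, with a
#' designated fraction of shallow libraries that fall below the rarefaction
#' threshold and exercise the depth filter).
#'
#' @param profiles tibble from [species_profiles()].
#' @param n_individuals named integer vector of individuals per species.
#' @param sections_per_individual number of intestinal sections sampled.
#' @param otus_per_genus OTUs each genus is split into.
#' @param geometric_ratio ratio of the within-genus geometric rank-abundance
#'   split.
#' @param individual_concentration Dirichlet concentration scalar; larger
#'   means individuals track the species mean more closely.
#' @param depth_mean,depth_sdlog,depth_min library-size model: log-normal
#'   mean and sdlog, truncated below at `depth_min` (>= 20,000) unless shallow.
#' @param depth_shallow_fraction fraction of samples drawn shallow
#'   (uniform on 0.5-1x `depth_min`), in [0, 1).
#' @param seed integer seed for the whole generation.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(profiles = species_profiles(),
                             n_individuals = c(
                               cormorant = 7, egret = 11,
                               night_heron = 8, gull = 5
                             ),
                             sections_per_individual = 3,
                             otus_per_genus = 5,
                             geometric_ratio = 0.5,
                             individual_concentration = 50,
                             depth_mean = 30000,
                             depth_sdlog = 0.15,
                             depth_min = 20000,
                             depth_shallow_fraction = 0.1,
                             seed = 1L) {
  if (any(n_individuals <= 0) || sections_per_individual <= 0 || otus_per_genus <= 0) {
    abort("all counts must be positive")
  }
  if (is.null(names(n_individuals)) ||
    !setequal(names(n_individuals), unique(profiles$species))) {
    abort("`n_individuals` must be named by the profile species")
  }
  if (depth_min < 20000) {
    abort("`depth_min` must be >= 20,000 so retained samples survive rarefaction")
  }
  if (depth_shallow_fraction < 0 || depth_shallow_fraction >= 1) {
    abort("`depth_shallow_fraction` must be in [0, 1)")
  }
  if (individual_concentration <= 0) abort("`individual_concentration` must be positive")
  if (geometric_ratio <= 0 || geometric_ratio > 1) abort("`geometric_ratio` must be in (0, 1]")
  structure(
    list(
      profiles = profiles,
      n_individuals = n_individuals,
      sections_per_individual = as.integer(sections_per_individual),
      otus_per_genus = as.integer(otus_per_genus),
      geometric_ratio = geometric_ratio,
      individual_concentration = individual_concentration,
      depth_mean = depth_mean,
      depth_sdlog = depth_sdlog,
      depth_min = depth_min,
      depth_shallow_fraction = depth_shallow_fraction,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}
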