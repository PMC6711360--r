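# Plain-text I/O for count tables, taxonomy and metadata.

#' Read an OTU count table
#'
#' Reads a tab-separated count table into the package's wide-tibble form
#' (first column `sample_id`, one integer column per OTU). Two dialects are
#' supported: plain TSV with a `sample_id` header, and the mothur "shared"
#' dialect whose bookkeeping `label` and `numOtus` columns are dropped and
#' whose `Group` column becomes the sample ID.
#'
#' Parsing is strict: ragged rows, non-integer counts (unless
#' `integer = FALSE`, for re-reading section-averaged tables) and duplicate
#' sample or OTU IDs raise an error naming the offending line.
#'
#' @param path file path.
#' @param dialect `"tsv"` or `"mothur"`.
#' @param integer require counts to be whole numbers (default TRUE).
#' @return a count table tibble.
#' @export
read_count_table <- function(path, dialect = c("tsv", "mothur"), integer = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 1) abort("empty file")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  ncol_head <- length(cells[[1]])
  ragged <- which(lengths(cells) != ncol_head)
  if (length(ragged) > 0) {
    abort(paste0(
      "ragged row: line ", ragged[1], " has ", length(cells[[ragged[1]]]),
      " fields, header has ", ncol_head
    ))
  }
  header <- cells[[1]]
  body <- cells[-1]

  if (dialect == "mothur") {
    drop <- which(tolower(header) %in% c("label", "numotus"))
    grp <- which(tolower(header) == "group")
    if (length(grp) != 1) abort("mothur shared file must have a Group column")
    otu_cols <- setdiff(seq_along(header), c(drop, grp))
    ids <- vapply(body, `[[`, character(1), grp)
    raw <- lapply(body, `[`, otu_cols)
    otu_ids <- header[otu_cols]
  } else {
    ids <- vapply(body, `[[`, character(1), 1L)
    raw <- lapply(body, `[`, -1L)
    otu_ids <- header[-1]
  }
  if (anyDuplicated(otu_ids)) {
    abort(paste0(
      "duplicate OTU IDs in header: ",
      paste(unique(otu_ids[duplicated(otu_ids)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate sample IDs: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- matrix(NA_real_, length(body), length(otu_ids), dimnames = list(ids, otu_ids))
  for (r in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[r]]))
    if (anyNA(v)) {
      abort(paste0("non-numeric count on line ", r + 1L))
    }
    if (integer && any(abs(v - round(v)) > 1e-8)) {
      abort(paste0("non-integer count on line ", r + 1L))
    }
    m[r, ] <- v
  }
  if (any(m < 0)) abort("counts must be non-negative")
  ct_tibble(m)
}

#' Write a count table as TSV
#'
#' Lossless counterpart of [read_count_table()] for the plain dialect:
#' columns are written in their current (deterministic) order.
#'
#' @param x count table tibble.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_count_table <- function(x, path) {
  ct_matrix(x) # validates
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read a taxonomy table (OTU, genus, phylum)
#' @param path TSV file with columns `otu_id`, `genus`, `phylum`.
#' @return tibble.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("otu_id", "genus", "phylum")
  if (!all(need %in% names(out))) {
    abort(paste0("taxonomy file must have columns: ", paste(need, collapse = ", ")))
  }
  out
}

#' Read sample metadata (sample, species, individual, section)
#' @param path TSV file with columns `sample_id`, `species`, `individual`,
#'   `section`.
#' @return tibble; section values must be anterior/middle/posterior.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  out <- readr::read_tsv(path, show_col_types = FALSE)
  need <- c("sample_id", "species", "individual", "section")
  if (!all(need %in% names(out))) {
    abort(paste0("metadata file must have columns: ", paste(need, collapse = ", ")))
  }
  bad <- setdiff(unique(out$section), c("anterior", "middle", "posterior"))
  if (length(bad) > 0) {
    abort(paste0("unknown intestinal section(s): ", paste(bad, collapse = ", ")))
  }
  out
}
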