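# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# A NULL seed leaves the RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Count tables travel as wide tibbles: first column `sample_id`, one numeric
# column per OTU/taxon.  These two helpers convert to/from a plain matrix
# with sample row names.
ct_matrix <- function(x) {
  stopifnot(is.data.frame(x))
  if (!identical(names(x)[1], "sample_id")) {
    abort("a count table must have `sample_id` as its first column")
  }
  ids <- as.character(x[["sample_id"]])
  if (anyDuplicated(ids)) {
    abort(paste0(
      "duplicate sample IDs: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) abort("count columns must be numeric")
  if (anyDuplicated(colnames(m))) {
    abort(paste0(
      "duplicate OTU IDs: ",
      paste(unique(colnames(m)[duplicated(colnames(m))]), collapse = ", ")
    ))
  }
  if (any(m < 0)) abort("counts must be non-negative")
  rownames(m) <- ids
  m
}

ct_tibble <- function(m) {
  out <- as_tibble(m, rownames = NA)
  tibble(sample_id = rownames(m)) |> dplyr::bind_cols(out)
}

# Align a grouping vector with the rows of a distance matrix / count matrix.
align_groups <- function(groups, labels) {
  if (!is.null(names(groups))) {
    missing <- setdiff(labels, names(groups))
    if (length(missing) > 0) {
      abort(paste0("groups missing for: ", paste(head(missing, 5), collapse = ", ")))
    }
    groups <- groups[labels]
  } else if (length(groups) != length(labels)) {
    abort("`groups` must be named by sample or match the number of samples")
  }
  factor(as.character(groups))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
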