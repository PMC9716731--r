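#' Count matrices and sample metadata
#'
#' Throughout the package a count matrix is a wide tibble whose first column is
#' `feature_id` and whose remaining columns are samples (nonnegative integer
#' counts). Sample metadata travels in a separate tibble with a `sample`
#' column plus whatever design columns apply (`condition`, `batch`, `pair_id`,
#' `tumor_type`).
#'
#' @param counts A wide count tibble (`feature_id` + one column per sample).
#' @param meta A sample metadata tibble with a `sample` column.
#' @return `validate_counts()` returns `counts` invisibly after checking the
#'   invariants (unique feature ids, nonnegative integer counts, metadata
#'   coverage when `meta` is supplied).
#' @export
validate_counts <- function(counts, meta = NULL) {
  if (!is.data.frame(counts) || !"feature_id" %in% names(counts)) {
    abort("`counts` must be a data frame with a `feature_id` column.")
  }
  if (anyDuplicated(counts$feature_id)) {
    dup <- unique(counts$feature_id[duplicated(counts$feature_id)])
    abort(paste0("Duplicate feature ids: ", paste(head(dup, 5), collapse = ", ")))
  }
  vals <- count_values(counts)
  if (ncol(vals) == 0) abort("`counts` has no sample columns.")
  bad <- which(!is.finite(vals) | vals < 0 | vals != round(vals), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "Non-integer or negative count at feature '%s', sample '%s'.",
      counts$feature_id[bad[1, 1]], colnames(vals)[bad[1, 2]]
    ))
  }
  if (!is.null(meta)) {
    if (!"sample" %in% names(meta)) abort("`meta` must have a `sample` column.")
    missing <- setdiff(colnames(vals), meta$sample)
    if (length(missing) > 0) {
      abort(paste0("Samples absent from metadata: ", paste(missing, collapse = ", ")))
    }
  }
  invisible(counts)
}

# numeric matrix (features x samples) from the wide tibble
count_values <- function(counts) {
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  storage.mode(m) <- "double"
  rownames(m) <- counts$feature_id
  m
}

# rebuild the wide tibble from a matrix
values_to_counts <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

sample_names <- function(counts) setdiff(names(counts), "feature_id")

# metadata rows aligned to the count columns
aligned_meta <- function(counts, meta) {
  validate_counts(counts, meta)
  meta[match(sample_names(counts), meta$sample), , drop = FALSE]
}

#' Read / write a count matrix with its sample metadata
#'
#' Plain tab-delimited interchange: the count table has a header of sample ids
#' and a first column of feature ids; the metadata table has one row per
#' sample. Non-integer cells and samples missing from the metadata are
#' rejected.
#'
#' @param path Path to the tab-delimited count table.
#' @param meta_path Optional path to the tab-delimited sample metadata.
#' @return A list with elements `counts` (wide tibble) and `meta` (tibble or
#'   `NULL`).
#' @export
load_count_matrix <- function(path, meta_path = NULL) {
  counts <- readr::read_tsv(path, show_col_types = FALSE)
  names(counts)[1] <- "feature_id"
  meta <- if (!is.null(meta_path)) {
    readr::read_tsv(meta_path, show_col_types = FALSE)
  }
  validate_counts(counts, meta)
  list(counts = counts, meta = meta)
}

#' @rdname load_count_matrix
#' @param counts,meta Tables as produced by the simulators or
#'   `load_count_matrix()`.
#' @export
write_count_matrix <- function(counts, path, meta = NULL, meta_path = NULL) {
  validate_counts(counts, meta)
  readr::write_tsv(counts, path)
  if (!is.null(meta) && !is.null(meta_path)) readr::write_tsv(meta, meta_path)
  invisible(path)
}
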