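#' Read and write connectivity matrices and cohort tables
#'
#' Connectivity matrices travel as whitespace-delimited text with a header
#' row of node labels; cohort tables as CSV with the documented column
#' schema (see [cohort_columns()]); a manifest CSV maps `subject_id` to
#' matrix filename.
#'
#' @param path File path.
#' @name connectome-io
NULL

#' @rdname connectome-io
#' @param m Connectivity matrix.
#' @export
write_connectivity <- function(m, path) {
  validate_connectivity(m)
  df <- as.data.frame(m)
  names(df) <- connectivity_node_ids(m)
  utils::write.table(df, path, sep = " ", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname connectome-io
#' @export
read_connectivity <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- list(colnames(df), colnames(df))
  validate_connectivity(m)
}

#' @rdname connectome-io
#' @export
read_time_series <- function(path) {
  df <- utils::read.table(path, header = TRUE, check.names = FALSE)
  m <- t(as.matrix(df)) # stored time x node; we work node x time
  rownames(m) <- colnames(df)
  m
}

#' @rdname connectome-io
#' @param ts Node x time matrix with node labels as row names.
#' @export
write_time_series <- function(ts, path) {
  df <- as.data.frame(t(ts))
  names(df) <- connectivity_node_ids(ts)
  utils::write.table(df, path, sep = " ", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' @rdname connectome-io
#' @export
read_motion_params <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  if (ncol(m) != 6) {
    stop("motion parameter file must have 6 columns (3 translations mm, ",
         "3 rotations rad), got ", ncol(m), call. = FALSE)
  }
  unname(m)
}

#' Canonical cohort-table column names
#'
#' The cohort CSV schema: one row per subject with demographics, the
#' verbal-intelligence proxy score, five cognitive subtests, structural
#' brain measures and mean framewise displacement. `sex` is coded
#' 0 = male, 1 = female (any two-level coding yields identical residuals).
#'
#' @return Character vector of required column names.
#' @export
cohort_columns <- function() {
  c("subject_id", "age", "sex", "education", "proxy_score",
    cr_subtests(),
    "gm_volume", "hippocampal_volume", "cortical_thickness", "mean_fwd")
}

#' @rdname cohort_columns
#' @export
cr_subtests <- function() {
  c("verbal_fluency", "processing_speed", "executive_function",
    "immediate_memory", "delayed_memory")
}

#' @rdname connectome-io
#' @param cohort Cohort tibble with the [cohort_columns()] schema.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

#' @rdname connectome-io
#' @export
read_cohort <- function(path) {
  cohort <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(cohort_columns(), names(cohort))
  if (length(missing)) {
    stop("cohort table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cohort
}

#' Write a cohort of connectivity matrices with a manifest
#'
#' @param matrices Named list of connectivity matrices (names are subject
#'   ids).
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV (columns `subject_id`, `filename`),
#'   invisibly.
#' @export
write_matrix_set <- function(matrices, dir) {
  stopifnot(length(matrices) >= 1, !is.null(names(matrices)))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- paste0("connectivity_", names(matrices), ".txt")
  for (s in seq_along(matrices)) {
    write_connectivity(matrices[[s]], file.path(dir, files[s]))
  }
  manifest <- tibble::tibble(subject_id = names(matrices), filename = files)
  path <- file.path(dir, "manifest.csv")
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_matrix_set
#' @param manifest_path Path to a manifest CSV.
#' @export
read_matrix_set <- function(manifest_path) {
  manifest <- readr::read_csv(manifest_path, show_col_types = FALSE)
  stopifnot(all(c("subject_id", "filename") %in% names(manifest)))
  dir <- dirname(manifest_path)
  out <- lapply(manifest$filename, function(f) read_connectivity(file.path(dir, f)))
  names(out) <- manifest$subject_id
  out
}
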