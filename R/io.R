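#' Read a region-by-time matrix from CSV/TSV
#'
#' Parses a numeric delimited file into a regions-by-timepoints matrix. The
#' default dialect is rows = regions; set `transpose = TRUE` for files with
#' columns = regions. Missing or non-numeric cells are rejected with the
#' offending position named.
#'
#' @param path file path; delimiter inferred from the extension (`.tsv` =
#'   tab, otherwise comma) unless `delim` is given.
#' @param transpose if `TRUE`, the file holds timepoints in rows.
#' @param header whether the file has a header row.
#' @param delim optional explicit delimiter.
#' @return numeric matrix (regions x timepoints).
#' @export
read_timeseries <- function(path, transpose = FALSE, header = FALSE,
                            delim = NULL) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, sep = delim, header = header,
                          colClasses = "numeric",
                          stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1L, ]
    abort(sprintf("missing/non-numeric cell at row %d, column %d",
                  bad[1L], bad[2L]))
  }
  if (transpose) m <- t(m)
  dimnames(m) <- NULL
  m
}

#' Read a subject metadata table
#'
#' Validates a CSV with columns `subject_id`, `condition`, and optionally
#' `dose` (serum concentration; may be missing for awake rows, which are in
#' any case excluded from dose analyses).
#'
#' @param path CSV path.
#' @param conditions optional allowed condition labels, in order; unknown
#'   labels are rejected.
#' @return tibble with `subject_id`, `condition` (ordered as given), `dose`.
#' @export
read_metadata <- function(path, conditions = NULL) {
  md <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("subject_id", "condition")
  if (!all(req %in% names(md))) {
    abort("metadata must have subject_id and condition columns")
  }
  if (anyDuplicated(md[req])) abort("duplicate (subject_id, condition) rows")
  if (!is.null(conditions)) {
    unknown <- setdiff(unique(md$condition), conditions)
    if (length(unknown)) {
      abort(paste("unknown condition label(s):", paste(unknown, collapse = ", ")))
    }
    md <- md[order(match(md$condition, conditions), md$subject_id), ]
  }
  if (!"dose" %in% names(md)) md$dose <- NA_real_
  tibble::as_tibble(md)
}

#' Write profiles to a tidy results CSV
#'
#' One row per (subject, condition, metric), with a parameters column and a
#' flag column; round-trips losslessly through [read_results()].
#'
#' @param profiles tibble from [cohort_profiles()].
#' @param path output CSV path.
#' @param parameters optional named list recorded (as `key=value;...`) in
#'   every row.
#' @return invisibly, the tidy tibble written.
#' @export
write_results <- function(profiles, path, parameters = list()) {
  par_str <- paste(names(parameters), unlist(parameters),
                   sep = "=", collapse = ";")
  tidy_tab <- tidyr::pivot_longer(
    profiles[c("subject_id", "condition",
               intersect(metric_names, names(profiles)))],
    cols = dplyr::all_of(intersect(metric_names, names(profiles))),
    names_to = "metric", values_to = "value"
  )
  tidy_tab$parameters <- par_str
  tidy_tab$flag <- ifelse(is.finite(tidy_tab$value), "", "nonfinite")
  readr::write_csv(tidy_tab, path)
  invisible(tidy_tab)
}

#' Read back a tidy results CSV into wide profiles
#'
#' @param path CSV written by [write_results()].
#' @return wide tibble with one row per (subject, condition).
#' @export
read_results <- function(path) {
  tidy_tab <- readr::read_csv(path, show_col_types = FALSE)
  tidyr::pivot_wider(tidy_tab[c("subject_id", "condition", "metric", "value")],
                     names_from = "metric", values_from = "value")
}
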