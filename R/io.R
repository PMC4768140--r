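#' Read and write lineage-tracing count tables
#'
#' The interchange format is a delimited text (CSV) table with one row per
#' gland per sampling time and columns `gland_id`, `site`, `time_days`,
#' `n_labelled_lgr5pos`, `n_labelled_lgr5neg`, `n_total_lgr5pos` (the last
#' two may be empty). Glands with zero labelled cells are kept: they carry
#' the clone-extinction signal.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble in the schema above.
#' @export
read_lineage_table <- function(path) {
  required <- c("gland_id", "site", "time_days", "n_labelled_lgr5pos")
  optional <- c("n_labelled_lgr5neg", "n_total_lgr5pos")
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(required, names(d))
  if (length(missing) > 0) {
    stop("lineage table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (col in setdiff(optional, names(d))) d[[col]] <- NA_integer_
  d <- d[c(required, optional)]
  for (col in c("n_labelled_lgr5pos", optional)) {
    d[[col]] <- as.integer(d[[col]])
  }
  count_cols <- c("time_days", "n_labelled_lgr5pos", optional)
  for (col in count_cols) {
    bad <- which(!is.na(d[[col]]) & d[[col]] < 0)
    if (length(bad) > 0) {
      stop("negative values in `", col, "` at data line(s) ",
           paste(utils::head(bad + 1L, 5), collapse = ", "),
           " of ", path, call. = FALSE)
    }
  }
  if (anyNA(d$time_days) || anyNA(d$n_labelled_lgr5pos)) {
    bad <- which(is.na(d$time_days) | is.na(d$n_labelled_lgr5pos))
    stop("missing time or labelled-cell count at data line(s) ",
         paste(utils::head(bad + 1L, 5), collapse = ", "), call. = FALSE)
  }
  d
}

#' @rdname read_lineage_table
#' @param data A lineage table (tibble).
#' @export
write_lineage_table <- function(data, path) {
  stopifnot(all(c("gland_id", "site", "time_days", "n_labelled_lgr5pos")
                %in% names(data)))
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}
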