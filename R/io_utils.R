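ensure_parent_dir <- function(path) {
  d <- dirname(path)
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  invisible(d)
}

#' Write a result table as TSV
#'
#' Tab-separated with a header row; floating-point columns are written with
#' 15 significant digits so a re-read reproduces values within 1e-9. Parent
#' directories are created as needed.
#'
#' @param table A `data.frame` (or matrix coercible to one).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  ensure_parent_dir(path)
  df <- as.data.frame(table, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 15, format = "g")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read back a TSV written by [write_results()]
#' @param path File path.
#' @return A `data.frame`.
#' @export
read_results <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}
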