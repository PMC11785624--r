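#' Construct a spectral-count table
#'
#' A `CountTable` holds integer spectral counts (SpC) per protein per MS run,
#' together with the protein lengths (amino acids) needed for NSAF
#' normalization and the unique-peptide support used for identification-level
#' filtering.
#'
#' @param protein_ids Character vector of unique, nonempty protein
#'   identifiers.
#' @param lengths Integer vector of protein lengths in amino acids
#'   (all >= 1).
#' @param unique_peptides Integer vector of unique-peptide counts (>= 0).
#' @param counts Nonnegative integer matrix, proteins x runs.
#' @param run_ids Character vector of unique run labels (one per counts
#'   column).
#' @param provenance Optional named list recording upstream processing
#'   (e.g. search-engine FDR, count type supplied).
#'
#' @return An object of class `CountTable`.
#' @export
count_table <- function(protein_ids, lengths, unique_peptides, counts,
                        run_ids, provenance = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  obj <- structure(
    list(
      protein_ids = as.character(protein_ids),
      lengths = as.numeric(lengths),
      unique_peptides = as.numeric(unique_peptides),
      counts = counts,
      run_ids = as.character(run_ids),
      provenance = provenance
    ),
    class = "CountTable"
  )
  dimnames(obj$counts) <- list(obj$protein_ids, obj$run_ids)
  validate_count_table(obj)
  obj
}

#' Validate a CountTable's invariants
#'
#' @param x A `CountTable`.
#' @return `x`, invisibly, if valid; otherwise an error is signalled.
#' @export
validate_count_table <- function(x) {
  stopifnot(inherits(x, "CountTable"))
  if (length(x$protein_ids) == 0 && nrow(x$counts) == 0) {
    # empty table is legal (e.g. after an aggressive identification filter)
    return(invisible(x))
  }
  if (anyNA(x$protein_ids) || any(!nzchar(x$protein_ids)))
    stop("CountTable: protein identifiers must be nonempty", call. = FALSE)
  dup <- x$protein_ids[duplicated(x$protein_ids)]
  if (length(dup))
    stop("CountTable format error: duplicated protein ID(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (anyNA(x$lengths) || any(x$lengths < 1) ||
      any(x$lengths != round(x$lengths)))
    stop("CountTable value error: protein length must be an integer >= 1",
         call. = FALSE)
  if (anyNA(x$unique_peptides) || any(x$unique_peptides < 0))
    stop("CountTable value error: unique_peptides must be >= 0",
         call. = FALSE)
  if (nrow(x$counts) != length(x$protein_ids) ||
      ncol(x$counts) != length(x$run_ids))
    stop("CountTable: counts must be proteins x runs", call. = FALSE)
  if (anyDuplicated(x$run_ids))
    stop("CountTable format error: duplicated run IDs", call. = FALSE)
  bad <- which(is.na(x$counts) | x$counts < 0 | x$counts != round(x$counts),
               arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf(
      "CountTable value error: non-integer or negative count at protein '%s', run '%s'",
      x$protein_ids[bad[1, 1]], x$run_ids[bad[1, 2]]), call. = FALSE)
  }
  invisible(x)
}

#' @export
print.CountTable <- function(x, ...) {
  cat(sprintf("CountTable: %d proteins x %d runs\n",
              length(x$protein_ids), length(x$run_ids)))
  invisible(x)
}

#' @export
dim.CountTable <- function(x) dim(x$counts)

#' Read a spectral-count table from TSV
#'
#' The expected header is `protein_id`, `length_aa`, `unique_peptides`,
#' followed by one column per MS run. Blank count cells are read as 0
#' (spectral counting has no distinct missing code: 0 means "not quantified
#' in this run").
#'
#' @param path Path to a tab-separated file.
#' @param sep Field separator (default tab).
#' @return A validated [count_table()].
#' @export
read_count_table <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  mandatory <- c("protein_id", "length_aa", "unique_peptides")
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("count-table format error: missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  run_cols <- setdiff(names(df), mandatory)
  if (length(run_cols) == 0)
    stop("count-table format error: no run columns found", call. = FALSE)
  counts <- as.matrix(df[, run_cols, drop = FALSE])
  suppressWarnings(storage.mode(counts) <- "double")
  counts[is.na(counts)] <- 0
  count_table(
    protein_ids = df$protein_id,
    lengths = df$length_aa,
    unique_peptides = df$unique_peptides,
    counts = counts,
    run_ids = run_cols
  )
}

#' Write a spectral-count table as TSV
#'
#' Inverse of [read_count_table()]; the integer payload round-trips exactly.
#'
#' @param table A `CountTable`.
#' @param path Output path; parent directories are created as needed.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "CountTable"))
  df <- data.frame(
    protein_id = table$protein_ids,
    length_aa = as.integer(table$lengths),
    unique_peptides = as.integer(table$unique_peptides),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  cnt <- table$counts
  storage.mode(cnt) <- "integer"
  df <- cbind(df, as.data.frame(cnt, check.names = FALSE))
  write_results(df, path)
}

#' Identification-level row filter
#'
#' Retains proteins supported by at least `min_unique_peptides` unique
#' peptides. The upstream search-engine protein FDR is applied before this
#' artifact and is recorded only as provenance.
#'
#' @param table A `CountTable`.
#' @param min_unique_peptides Minimum unique-peptide support (default 2).
#' @return A `CountTable` with the retained rows; run columns unchanged.
#' @export
apply_identification_filter <- function(table, min_unique_peptides = 2) {
  stopifnot(inherits(table, "CountTable"))
  if (min_unique_peptides < 0)
    stop("min_unique_peptides must be >= 0", call. = FALSE)
  keep <- table$unique_peptides >= min_unique_peptides
  if (!any(keep))
    warning("identification filter removed all proteins", call. = FALSE)
  out <- table
  out$protein_ids <- table$protein_ids[keep]
  out$lengths <- table$lengths[keep]
  out$unique_peptides <- table$unique_peptides[keep]
  out$counts <- table$counts[keep, , drop = FALSE]
  out
}
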