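#' Construct a sample sheet
#'
#' Maps each MS run to a biological sample, a statistical group, and a
#' technical-replicate index. The statistical group vocabulary is fixed to
#' `control`, `IIM` (idiopathic inflammatory myopathy, pooling subtypes such
#' as sIBM/DM/PM/OM) and `MM` (mitochondrial myopathy); subtype labels may be
#' carried in a free-text `subtype` column but play no statistical role.
#'
#' @param run_id Character vector of unique run labels.
#' @param sample_id Character vector of sample labels.
#' @param group Character vector, each one of `"control"`, `"IIM"`, `"MM"`.
#' @param replicate_index Positive integer replicate index within sample.
#' @param subtype Optional free-text annotation per run.
#' @return A `data.frame` of class `SampleSheet`.
#' @export
sample_sheet <- function(run_id, sample_id, group, replicate_index,
                         subtype = NULL) {
  df <- data.frame(
    run_id = as.character(run_id),
    sample_id = as.character(sample_id),
    group = as.character(group),
    replicate_index = as.integer(replicate_index),
    stringsAsFactors = FALSE
  )
  if (!is.null(subtype)) df$subtype <- as.character(subtype)
  class(df) <- c("SampleSheet", "data.frame")
  validate_sample_sheet(df)
  df
}

#' Validate a SampleSheet's invariants
#' @param x A `SampleSheet`.
#' @return `x`, invisibly.
#' @export
validate_sample_sheet <- function(x) {
  stopifnot(inherits(x, "SampleSheet"))
  allowed <- c("control", "IIM", "MM")
  bad <- setdiff(unique(x$group), allowed)
  if (length(bad))
    stop("sample-sheet value error: unknown group label(s) ",
         paste(sQuote(bad), collapse = ", "),
         "; map disease subtypes (e.g. DM, PM, sIBM, OM) onto 'IIM' and use",
         " the 'subtype' column for the original label", call. = FALSE)
  dup <- x$run_id[duplicated(x$run_id)]
  if (length(dup))
    stop("sample-sheet format error: run listed twice: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  key <- paste(x$sample_id, x$replicate_index)
  if (anyDuplicated(key))
    stop("sample-sheet format error: duplicated (sample_id, replicate_index)",
         call. = FALSE)
  if (any(x$replicate_index < 1))
    stop("sample-sheet value error: replicate_index must be >= 1",
         call. = FALSE)
  grp_per_sample <- tapply(x$group, x$sample_id,
                           function(g) length(unique(g)))
  if (any(grp_per_sample > 1))
    stop("sample-sheet format error: a sample maps to more than one group",
         call. = FALSE)
  invisible(x)
}

#' Read a sample sheet from TSV
#'
#' Expected columns: `run_id`, `sample_id`, `group`, `replicate_index`
#' (plus optional `subtype`).
#'
#' @param path Path to a tab-separated file.
#' @return A validated `SampleSheet`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (file.size(path) == 0)
    stop("sample-sheet format error: empty file", call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  needed <- c("run_id", "sample_id", "group", "replicate_index")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("sample-sheet format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sample_sheet(df$run_id, df$sample_id, df$group, df$replicate_index,
               subtype = if ("subtype" %in% names(df)) df$subtype else NULL)
}

# sample_id -> group lookup (one row per sample)
sheet_samples <- function(sheet) {
  unique(data.frame(sample_id = sheet$sample_id, group = sheet$group,
                    stringsAsFactors = FALSE))
}
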