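#' Construct an NSAF matrix
#'
#' Normalized spectral abundance factors: for protein i in one run,
#' \deqn{NSAF_i = (SpC_i / L_i) / \sum_j (SpC_j / L_j)}
#' where SpC is the spectral count and L the protein length. Each run column
#' over the quantified proteome sums to 1; a value of 0 encodes "not
#' quantified".
#'
#' @param values Nonnegative numeric matrix, proteins x columns.
#' @param protein_ids Row identifiers.
#' @param column_ids Run or sample labels.
#' @param level `"run"` or `"sample"`.
#' @return An object of class `NSAFMatrix`.
#' @export
nsaf_matrix <- function(values, protein_ids, column_ids,
                        level = c("run", "sample")) {
  level <- match.arg(level)
  values <- as.matrix(values)
  if (any(values < 0)) stop("NSAF values must be >= 0", call. = FALSE)
  dimnames(values) <- list(protein_ids, column_ids)
  structure(list(values = values,
                 protein_ids = as.character(protein_ids),
                 column_ids = as.character(column_ids),
                 level = level),
            class = "NSAFMatrix")
}

#' @export
print.NSAFMatrix <- function(x, ...) {
  cat(sprintf("NSAFMatrix (%s level): %d proteins x %d columns\n",
              x$level, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.NSAFMatrix <- function(x) dim(x$values)

#' Compute per-run NSAF values from spectral counts
#'
#' Counts are length-normalized (SpC/L) and each run column is divided by
#' its total, so columns with at least one nonzero count sum to exactly 1.
#' Proteins with zero counts keep NSAF 0. A run with no counts at all yields
#' an all-zero column and is flagged in the `empty_runs` attribute (with a
#' warning).
#'
#' @param table A `CountTable` (normally after
#'   [apply_identification_filter()]).
#' @return An `NSAFMatrix` at run level.
#' @export
compute_nsaf <- function(table) {
  stopifnot(inherits(table, "CountTable"))
  sab <- table$counts / table$lengths       # length-normalized counts
  tot <- colSums(sab)
  empty <- tot == 0
  tot[empty] <- 1                            # leave empty runs all-zero
  values <- sweep(sab, 2, tot, "/")
  out <- nsaf_matrix(values, table$protein_ids, table$run_ids, level = "run")
  attr(out, "empty_runs") <- table$run_ids[empty]
  if (any(empty))
    warning("run(s) with all-zero counts: ",
            paste(table$run_ids[empty], collapse = ", "), call. = FALSE)
  out
}

#' Technical-replicate reproducibility QC
#'
#' For every sample with exactly two replicate runs: the Pearson correlation
#' between the two NSAF columns is computed over proteins quantified
#' (nonzero) in at least one of the two runs, with zeros retained; the
#' per-protein relative standard deviation, RSD = 100 * sd / mean (sample,
#' n-1 standard deviation), is computed only over proteins quantified in
#' both runs. `median_rsd` is the median of the RSDs pooled over all pairs.
#'
#' @param nsaf A run-level `NSAFMatrix`.
#' @param sheet The `SampleSheet`.
#' @return An object of class `ReplicateQC` with fields
#'   `pair_correlations` (named numeric, NA with a flag when fewer than 3
#'   proteins are quantified in both runs), `protein_rsd` (long data.frame:
#'   sample_id, protein_id, rsd), `median_rsd`, and `skipped_samples`.
#' @export
replicate_qc <- function(nsaf, sheet) {
  stopifnot(inherits(nsaf, "NSAFMatrix"), inherits(sheet, "SampleSheet"))
  if (nsaf$level != "run")
    stop("replicate_qc requires a run-level NSAF matrix", call. = FALSE)
  reps <- split(sheet$run_id, sheet$sample_id)
  dup_samples <- names(reps)[lengths(reps) == 2]
  multi <- names(reps)[lengths(reps) > 1 & lengths(reps) != 2]
  if (length(multi))
    warning("sample(s) without exactly 2 replicates skipped in QC: ",
            paste(multi, collapse = ", "), call. = FALSE)
  if (length(dup_samples) == 0)
    stop("replicate_qc: no sample has exactly 2 replicate runs",
         call. = FALSE)

  cors <- stats::setNames(rep(NA_real_, length(dup_samples)), dup_samples)
  undefined <- character(0)
  rsd_rows <- list()
  for (s in dup_samples) {
    runs <- reps[[s]]
    x <- nsaf$values[, runs[1]]
    y <- nsaf$values[, runs[2]]
    either <- x > 0 | y > 0
    both <- x > 0 & y > 0
    if (sum(both) < 3) {
      undefined <- c(undefined, s)
    } else {
      cors[s] <- stats::cor(x[either], y[either], method = "pearson")
    }
    if (any(both)) {
      m <- (x[both] + y[both]) / 2
      sdv <- abs(x[both] - y[both]) / sqrt(2)  # n-1 sd of a pair
      rsd_rows[[s]] <- data.frame(
        sample_id = s,
        protein_id = nsaf$protein_ids[both],
        rsd = 100 * sdv / m,
        stringsAsFactors = FALSE
      )
    }
  }
  protein_rsd <- if (length(rsd_rows)) do.call(rbind, rsd_rows) else
    data.frame(sample_id = character(0), protein_id = character(0),
               rsd = numeric(0))
  rownames(protein_rsd) <- NULL
  structure(list(
    pair_correlations = cors,
    undefined_pairs = undefined,
    protein_rsd = protein_rsd,
    median_rsd = stats::median(protein_rsd$rsd[is.finite(protein_rsd$rsd)]),
    skipped_samples = multi
  ), class = "ReplicateQC")
}

#' @export
print.ReplicateQC <- function(x, ...) {
  cat("ReplicateQC\n")
  cat("  pair Pearson r:",
      paste(sprintf("%s=%.3f", names(x$pair_correlations),
                    x$pair_correlations), collapse = ", "), "\n")
  cat(sprintf("  median RSD: %.1f%% (%d protein-pair values)\n",
              x$median_rsd, nrow(x$protein_rsd)))
  invisible(x)
}

#' Collapse technical replicates to per-sample NSAF values
#'
#' Replicate run columns of each sample are replaced by their arithmetic
#' mean. Zeros participate in the mean: a protein seen in one of two
#' replicates gets half its value (`na_zero = FALSE` switches to
#' complete-case averaging over nonzero replicates instead). Single-run
#' samples pass through unchanged.
#'
#' @param nsaf A run-level `NSAFMatrix`.
#' @param sheet The `SampleSheet`.
#' @param na_zero Logical; `TRUE` (default) averages including zeros.
#' @return A sample-level `NSAFMatrix`, columns ordered as the samples first
#'   appear in the sheet.
#' @export
average_replicates <- function(nsaf, sheet, na_zero = TRUE) {
  stopifnot(inherits(nsaf, "NSAFMatrix"), inherits(sheet, "SampleSheet"))
  if (nsaf$level != "run")
    stop("average_replicates requires a run-level NSAF matrix",
         call. = FALSE)
  unknown <- setdiff(nsaf$column_ids, sheet$run_id)
  if (length(unknown))
    stop("mapping error: run(s) absent from sample sheet: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  samples <- unique(sheet$sample_id)
  values <- vapply(samples, function(s) {
    runs <- intersect(sheet$run_id[sheet$sample_id == s], nsaf$column_ids)
    sub <- nsaf$values[, runs, drop = FALSE]
    if (na_zero) {
      rowMeans(sub)
    } else {
      out <- apply(sub, 1, function(v) {
        nz <- v[v > 0]
        if (length(nz)) mean(nz) else 0
      })
      as.numeric(out)
    }
  }, numeric(nrow(nsaf$values)))
  nsaf_matrix(values, nsaf$protein_ids, samples, level = "sample")
}
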