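#' PCA of samples on NSAF values
#'
#' Samples are observations and proteins features. Features are
#' mean-centered; no variance scaling by default (spectral-count data keep
#' their natural abundance weighting). Component signs are fixed by forcing
#' each component's largest-magnitude loading positive, so score files are
#' reproducible.
#'
#' @param nsaf Sample-level `NSAFMatrix`.
#' @param n_components Number of components to keep.
#' @param scale. Logical; scale features to unit variance (default FALSE).
#' @return An object of class `EmbeddingResult`: `sample_ids`, `scores`
#'   (samples x components), `loadings` (proteins x components),
#'   `explained_fraction`.
#' @export
pca_samples <- function(nsaf, n_components = 2, scale. = FALSE) {
  stopifnot(inherits(nsaf, "NSAFMatrix"))
  if (n_components < 1) stop("n_components must be >= 1", call. = FALSE)
  x <- t(nsaf$values)                       # samples x proteins
  if (nrow(x) < 2) stop("PCA needs >= 2 samples", call. = FALSE)
  max_comp <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_comp)
    stop("n_components must be <= min(samples - 1, proteins)",
         call. = FALSE)
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale.)
  k <- n_components
  scores <- pc$x[, seq_len(k), drop = FALSE]
  loadings <- pc$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {                   # deterministic sign convention
    i_max <- which.max(abs(loadings[, j]))
    if (loadings[i_max, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  structure(list(sample_ids = nsaf$column_ids, scores = scores,
                 loadings = loadings, explained_fraction = expl),
            class = "EmbeddingResult")
}

#' @export
print.EmbeddingResult <- function(x, ...) {
  cat(sprintf("EmbeddingResult: %d samples, %d components (%s explained)\n",
              length(x$sample_ids), ncol(x$scores),
              paste(sprintf("%.1f%%", 100 * x$explained_fraction),
                    collapse = ", ")))
  invisible(x)
}

# z-score rows; constant rows become all-zero and are flagged
zscore_rows <- function(m) {
  mu <- rowMeans(m)
  sdv <- apply(m, 1, stats::sd)
  constant <- sdv == 0
  z <- (m - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  list(z = z, constant = constant)
}

#' Unsupervised clustering of selected proteins for heatmap rendering
#'
#' Rows are the selected proteins, z-scored across samples (mean 0, sample
#' sd 1 per row); distances are Euclidean; linkage is average (UPGMA). Rows
#' and columns are both clustered. Constant rows are flagged and excluded
#' from the distance computations. The numeric artifact (orders, merge
#' trees, z-scored matrix) is returned; rendering is left to plotting
#' layers such as pheatmap.
#'
#' @param nsaf Imputed sample-level `NSAFMatrix`.
#' @param selection Character vector of selected protein IDs (e.g. strict
#'   hits), nonempty.
#' @return An object of class `ClusteringResult`: `zscored_matrix`,
#'   `row_order`, `column_order`, `row_linkage`, `column_linkage` (hclust
#'   objects or NULL when trivial), `constant_rows`.
#' @export
cluster_heatmap <- function(nsaf, selection) {
  stopifnot(inherits(nsaf, "NSAFMatrix"))
  if (length(selection) == 0)
    stop("cluster_heatmap: empty selection", call. = FALSE)
  missing_ids <- setdiff(selection, nsaf$protein_ids)
  if (length(missing_ids))
    stop("selection contains unknown protein IDs: ",
         paste(utils::head(missing_ids, 5), collapse = ", "),
         call. = FALSE)
  m <- nsaf$values[match(selection, nsaf$protein_ids), , drop = FALSE]
  zs <- zscore_rows(m)
  z <- zs$z
  usable <- !zs$constant
  zu <- z[usable, , drop = FALSE]

  row_linkage <- NULL
  row_order <- seq_len(nrow(z))
  if (sum(usable) >= 2) {
    row_linkage <- stats::hclust(stats::dist(zu, method = "euclidean"),
                                 method = "average")
    row_order <- which(usable)[row_linkage$order]
    row_order <- c(row_order, which(!usable))
  }
  column_linkage <- NULL
  column_order <- seq_len(ncol(z))
  if (ncol(z) >= 2 && sum(usable) >= 1) {
    column_linkage <- stats::hclust(stats::dist(t(zu), method = "euclidean"),
                                    method = "average")
    column_order <- column_linkage$order
  }
  structure(list(zscored_matrix = z,
                 row_order = row_order, column_order = column_order,
                 row_linkage = row_linkage, column_linkage = column_linkage,
                 constant_rows = rownames(z)[zs$constant]),
            class = "ClusteringResult")
}

#' @export
print.ClusteringResult <- function(x, ...) {
  cat(sprintf("ClusteringResult: %d proteins x %d samples (%d constant rows)\n",
              nrow(x$zscored_matrix), ncol(x$zscored_matrix),
              length(x$constant_rows)))
  invisible(x)
}

#' Top split of a column dendrogram
#'
#' Cuts the column tree into two clusters — the first question a heatmap
#' answers is whether that split separates disease from control.
#'
#' @param clustering A `ClusteringResult` with a non-NULL column linkage.
#' @return Integer vector of cluster memberships (1/2) named by column.
#' @export
top_column_split <- function(clustering) {
  stopifnot(inherits(clustering, "ClusteringResult"))
  if (is.null(clustering$column_linkage))
    stop("no column linkage available", call. = FALSE)
  stats::cutree(clustering$column_linkage, k = 2)
}
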