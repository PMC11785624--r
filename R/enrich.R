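#' Benjamini-Hochberg step-up adjustment
#'
#' Thin validated wrapper around the standard step-up procedure; output has
#' the same length and order as the input and never falls below it.
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted q-values.
#' @export
adjust_bh <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p_values, method = "BH")
}

#' Hypergeometric over-representation test
#'
#' For each gene set with effective size (after intersection with the
#' universe) of at least `min_set_size`, tests whether the query set
#' overlaps it more than expected by chance: with N the universe size, K
#' the set size, n the query size and k the overlap,
#' p = P(X >= k) under Hypergeometric(N, K, n). Benjamini-Hochberg
#' q-values are computed over all tested sets; rows are sorted by p
#' ascending with ties broken by set name.
#'
#' @param query Character vector of protein IDs (must be a subset of the
#'   universe).
#' @param library A `GeneSetLibrary`.
#' @param universe Character vector of protein IDs (the background, e.g.
#'   the presence-filtered quantified proteome).
#' @param min_set_size Minimum effective set size to test (default 3).
#' @return A `data.frame` of class `EnrichmentTable` with columns set,
#'   description, k, K, n, N, p_value, q_value, overlap_ids.
#' @export
overrepresentation_test <- function(query, library, universe,
                                    min_set_size = 3) {
  stopifnot(inherits(library, "GeneSetLibrary"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query IDs outside the universe: ",
         paste(utils::head(outside, 10), collapse = ", "), call. = FALSE)
  empty <- data.frame(set = character(0), description = character(0),
                      k = integer(0), K = integer(0), n = integer(0),
                      N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), overlap_ids = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("EnrichmentTable", "data.frame")
  if (length(query) == 0) return(empty)
  N <- length(universe)
  n <- length(query)
  rows <- list()
  for (nm in names(library$sets)) {
    members <- intersect(library$sets[[nm]]$members, universe)
    K <- length(members)
    if (K < min_set_size) next
    overlap <- intersect(query, members)
    k <- length(overlap)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    rows[[nm]] <- data.frame(
      set = nm, description = library$sets[[nm]]$description,
      k = k, K = K, n = n, N = N, p_value = p, q_value = NA_real_,
      overlap_ids = paste(sort(overlap), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out$q_value <- adjust_bh(out$p_value)
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentTable", "data.frame")
  out
}

#' Directional over-representation analysis
#'
#' Over- and underexpressed proteins are analysed separately: two
#' independent enrichment tables, each BH-adjusted within itself.
#'
#' @param over Character vector of overexpressed protein IDs.
#' @param under Character vector of underexpressed protein IDs (disjoint
#'   from `over`).
#' @param library A `GeneSetLibrary`.
#' @param universe Background protein IDs.
#' @param min_set_size Passed to [overrepresentation_test()].
#' @return A list with `over` and `under` `EnrichmentTable`s.
#' @export
directional_enrichment <- function(over, under, library, universe,
                                   min_set_size = 3) {
  if (length(intersect(over, under)))
    stop("over and under sets must be disjoint", call. = FALSE)
  list(
    over = overrepresentation_test(over, library, universe, min_set_size),
    under = overrepresentation_test(under, library, universe, min_set_size)
  )
}

#' Category abundance summaries (proteomap-style)
#'
#' Sums NSAF mass per functional category and sample, then averages over
#' the samples of each group (control, IIM, MM). Proteins annotated to more
#' than one category are assigned to the first-listed category (logged via
#' a warning); unannotated mass goes to the remainder, so per group the
#' category sums plus remainder total 1 when the input columns sum to 1.
#'
#' @param nsaf Sample-level `NSAFMatrix`.
#' @param categories A `GeneSetLibrary` of (near-)partition categories.
#' @param sheet The `SampleSheet`.
#' @return A `data.frame` of class `CategoryAbundance`: one row per
#'   category (plus `"_remainder"`), one column per group present.
#' @export
category_abundance <- function(nsaf, categories, sheet) {
  stopifnot(inherits(nsaf, "NSAFMatrix"),
            inherits(categories, "GeneSetLibrary"),
            inherits(sheet, "SampleSheet"))
  assign_cat <- stats::setNames(rep(NA_character_, nrow(nsaf$values)),
                                nsaf$protein_ids)
  overlapping <- character(0)
  for (nm in names(categories$sets)) {
    members <- intersect(categories$sets[[nm]]$members, nsaf$protein_ids)
    already <- members[!is.na(assign_cat[members])]
    overlapping <- c(overlapping, already)
    fresh <- members[is.na(assign_cat[members])]
    assign_cat[fresh] <- nm
  }
  if (length(overlapping))
    warning(length(unique(overlapping)),
            " protein(s) in multiple categories; first-listed kept",
            call. = FALSE)
  smp <- sheet_samples(sheet)
  groups <- intersect(c("control", "IIM", "MM"), unique(smp$group))
  cat_names <- names(categories$sets)
  res <- matrix(0, nrow = length(cat_names) + 1, ncol = length(groups),
                dimnames = list(c(cat_names, "_remainder"), groups))
  for (g in groups) {
    cols <- intersect(nsaf$column_ids, smp$sample_id[smp$group == g])
    if (length(cols) == 0) next
    sub <- nsaf$values[, cols, drop = FALSE]
    per_sample <- vapply(cat_names, function(nm) {
      colSums(sub[which(assign_cat == nm), , drop = FALSE])
    }, numeric(length(cols)))
    if (length(cols) == 1) per_sample <- matrix(per_sample, nrow = 1)
    cat_means <- colMeans(per_sample)
    res[cat_names, g] <- cat_means
    res["_remainder", g] <- 1 - sum(cat_means)
  }
  out <- data.frame(category = rownames(res), res, check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("CategoryAbundance", "data.frame")
  out
}
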