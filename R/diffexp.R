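#' Analysis profiles for differential calling
#'
#' Two built-in selection profiles:
#' \describe{
#'   \item{strict}{Disease = IIM plus MM versus control; a protein is a hit
#'     when the two-tailed t-test p-value is below 0.05 (one star; 0.01 two
#'     stars) and the absolute signed fold change is at least 3. Directions
#'     pooled.}
#'   \item{exploratory}{Disease = IIM only (the mitochondrial-myopathy
#'     sample omitted); no p-value filter; proteins called over- or
#'     underexpressed at |signed fold change| >= 2.83 (= 2^1.5, i.e. 1.5 on
#'     the log2 scale), directions kept separate.}
#' }
#'
#' @param name `"strict"` or `"exploratory"`, or `"custom"` with explicit
#'   arguments.
#' @param disease_groups Subset of `c("IIM", "MM")`.
#' @param p_threshold P-value threshold, or `NULL` for no p filter.
#' @param p_star2 Second star level (strict profile only).
#' @param fc_threshold Fold-change threshold (> 1).
#' @param directions_separate Logical.
#' @return An object of class `AnalysisProfile`.
#' @export
analysis_profile <- function(name = c("strict", "exploratory", "custom"),
                             disease_groups = NULL, p_threshold = NULL,
                             p_star2 = 0.01, fc_threshold = NULL,
                             directions_separate = NULL) {
  name <- match.arg(name)
  if (name == "strict") {
    disease_groups <- disease_groups %||% c("IIM", "MM")
    p_threshold <- p_threshold %||% 0.05
    fc_threshold <- fc_threshold %||% 3
    directions_separate <- directions_separate %||% FALSE
  } else if (name == "exploratory") {
    disease_groups <- disease_groups %||% "IIM"
    fc_threshold <- fc_threshold %||% 2^1.5
    directions_separate <- directions_separate %||% TRUE
  } else {
    if (is.null(disease_groups) || is.null(fc_threshold) ||
        is.null(directions_separate))
      stop("custom profile needs disease_groups, fc_threshold and ",
           "directions_separate", call. = FALSE)
  }
  if (fc_threshold <= 1) stop("fc_threshold must be > 1", call. = FALSE)
  if (!is.null(p_threshold) && (p_threshold <= 0 || p_threshold >= 1))
    stop("p_threshold must be in (0, 1)", call. = FALSE)
  if (!all(disease_groups %in% c("IIM", "MM")))
    stop("disease_groups must be a subset of {IIM, MM}", call. = FALSE)
  structure(list(name = name, disease_groups = disease_groups,
                 p_threshold = p_threshold, p_star2 = p_star2,
                 fc_threshold = fc_threshold,
                 directions_separate = directions_separate),
            class = "AnalysisProfile")
}

#' Presence filter on a sample-level NSAF matrix
#'
#' Retains proteins quantified (nonzero) in at least
#' `ceiling(disease_fraction * n_disease)` disease samples OR at least
#' `ceiling(control_fraction * n_control)` control samples. Disease pools
#' IIM and MM. All sample columns are kept.
#'
#' @param nsaf Sample-level `NSAFMatrix`.
#' @param sheet The `SampleSheet`.
#' @param disease_fraction Fraction of disease samples required (default
#'   1/2).
#' @param control_fraction Fraction of control samples required (default
#'   2/3).
#' @return A filtered sample-level `NSAFMatrix`.
#' @export
presence_filter <- function(nsaf, sheet, disease_fraction = 1 / 2,
                            control_fraction = 2 / 3) {
  stopifnot(inherits(nsaf, "NSAFMatrix"), inherits(sheet, "SampleSheet"))
  if (nsaf$level != "sample")
    stop("presence_filter requires a sample-level NSAF matrix",
         call. = FALSE)
  for (f in c(disease_fraction, control_fraction))
    if (f <= 0 || f > 1)
      stop("presence fraction must be in (0, 1]", call. = FALSE)
  smp <- sheet_samples(sheet)
  disease <- intersect(nsaf$column_ids,
                       smp$sample_id[smp$group %in% c("IIM", "MM")])
  control <- intersect(nsaf$column_ids,
                       smp$sample_id[smp$group == "control"])
  if (length(disease) == 0 || length(control) == 0)
    stop("presence_filter: both groups must be nonempty", call. = FALSE)
  need_d <- ceiling(disease_fraction * length(disease))
  need_c <- ceiling(control_fraction * length(control))
  n_d <- rowSums(nsaf$values[, disease, drop = FALSE] > 0)
  n_c <- rowSums(nsaf$values[, control, drop = FALSE] > 0)
  keep <- n_d >= need_d | n_c >= need_c
  nsaf_matrix(nsaf$values[keep, , drop = FALSE],
              nsaf$protein_ids[keep], nsaf$column_ids, level = "sample")
}

#' Minimum imputation of missing NSAF values
#'
#' Each zero cell is replaced by the minimum nonzero NSAF of its own sample
#' column (not a global minimum); nonzero cells are untouched. Output is
#' strictly positive.
#'
#' @param nsaf Sample-level `NSAFMatrix` (after [presence_filter()]).
#' @return An imputed `NSAFMatrix`.
#' @export
impute_missing <- function(nsaf) {
  stopifnot(inherits(nsaf, "NSAFMatrix"))
  values <- nsaf$values
  for (j in seq_len(ncol(values))) {
    col <- values[, j]
    nz <- col[col > 0]
    if (length(nz) == 0)
      stop("degenerate sample with no quantified proteins: ",
           nsaf$column_ids[j], call. = FALSE)
    col[col == 0] <- min(nz)
    values[, j] <- col
  }
  out <- nsaf
  out$values <- values
  out
}

#' Signed fold change
#'
#' For the disease/control ratio r = median_disease / mean_control, returns
#' +r when r >= 1 and -1/r otherwise, so over- and underexpression are
#' symmetric around +1 / -1 (e.g. a 26-fold loss prints as -26.17, not
#' 0.038).
#'
#' @param median_disease Positive numeric (vectorized).
#' @param mean_control Positive numeric (vectorized).
#' @return Signed fold change(s) with |value| >= 1.
#' @export
signed_fold_change <- function(median_disease, mean_control) {
  if (any(median_disease <= 0) || any(mean_control <= 0))
    stop("signed_fold_change: inputs must be > 0 (impute first)",
         call. = FALSE)
  r <- median_disease / mean_control
  ifelse(r >= 1, r, -1 / r)
}

#' Differential expression test
#'
#' Per protein: the median NSAF over disease samples (groups per the
#' profile), the mean over control samples, their ratio and signed fold
#' change, and a two-tailed two-sample t-test p-value comparing disease
#' versus control NSAF values (Welch by default; Student pooled-variance
#' optional). Star levels at 0.05 / 0.01. `strict_hit` requires both the
#' p threshold and the fold-change threshold of the profile;
#' `exploratory_direction` applies the fold-change threshold alone.
#' Benjamini-Hochberg q-values are reported as an advisory column only (the
#' strict profile applies no across-protein FDR).
#'
#' @param nsaf Imputed sample-level `NSAFMatrix`.
#' @param sheet The `SampleSheet`.
#' @param profile An [analysis_profile()].
#' @param var_equal `FALSE` (default) for Welch; `TRUE` for Student.
#' @return A `data.frame` of class `DifferentialTable` with columns
#'   protein_id, median_disease, mean_control, ratio, signed_fc, p_value,
#'   q_value_advisory, stars, strict_hit, exploratory_direction, flags.
#' @export
differential_test <- function(nsaf, sheet, profile = analysis_profile("strict"),
                              var_equal = FALSE) {
  stopifnot(inherits(nsaf, "NSAFMatrix"), inherits(sheet, "SampleSheet"),
            inherits(profile, "AnalysisProfile"))
  smp <- sheet_samples(sheet)
  disease <- intersect(nsaf$column_ids,
                       smp$sample_id[smp$group %in% profile$disease_groups])
  control <- intersect(nsaf$column_ids,
                       smp$sample_id[smp$group == "control"])
  if (length(disease) < 2 || length(control) < 2)
    stop("design error: need >= 2 samples per compared group",
         call. = FALSE)
  dmat <- nsaf$values[, disease, drop = FALSE]
  cmat <- nsaf$values[, control, drop = FALSE]
  med_d <- apply(dmat, 1, stats::median)
  mean_c <- rowMeans(cmat)
  sfc <- signed_fold_change(med_d, mean_c)

  n <- nrow(dmat)
  p <- numeric(n)
  flags <- character(n)
  for (i in seq_len(n)) {
    x <- dmat[i, ]
    y <- cmat[i, ]
    if (stats::var(x) == 0 && stats::var(y) == 0) {
      p[i] <- if (mean(x) == mean(y)) 1 else 0
      flags[i] <- "degenerate_variance"
    } else {
      p[i] <- stats::t.test(x, y, var.equal = var_equal)$p.value
    }
  }
  stars <- ifelse(p < profile$p_star2 %||% 0.01, "**",
                  ifelse(p < 0.05, "*", ""))
  strict_hit <- if (is.null(profile$p_threshold)) {
    abs(sfc) >= profile$fc_threshold
  } else {
    p < profile$p_threshold & abs(sfc) >= profile$fc_threshold
  }
  expl_dir <- ifelse(sfc >= profile$fc_threshold, "over",
                     ifelse(sfc <= -profile$fc_threshold, "under", "none"))
  out <- data.frame(
    protein_id = nsaf$protein_ids,
    median_disease = med_d,
    mean_control = mean_c,
    ratio = med_d / mean_c,
    signed_fc = sfc,
    p_value = p,
    q_value_advisory = stats::p.adjust(p, method = "BH"),
    stars = stars,
    strict_hit = strict_hit,
    exploratory_direction = expl_dir,
    flags = flags,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("DifferentialTable", "data.frame")
  attr(out, "profile") <- profile
  out
}

#' Select dysregulated proteins under a profile
#'
#' Strict profile: a single pooled set of strict hits (passed both the p
#' and fold-change thresholds), also split by sign for convenience.
#' Exploratory profile: over = signed_fc >= threshold, under = signed_fc <=
#' -threshold, no p filter. The over and under sets are disjoint by
#' construction.
#'
#' @param table A `DifferentialTable` computed under `profile`.
#' @param profile The same [analysis_profile()].
#' @return A list with `over`, `under` and `pooled` character vectors of
#'   protein IDs.
#' @export
select_dysregulated <- function(table, profile) {
  stopifnot(inherits(table, "DifferentialTable"),
            inherits(profile, "AnalysisProfile"))
  if (profile$directions_separate) {
    over <- table$protein_id[table$signed_fc >= profile$fc_threshold]
    under <- table$protein_id[table$signed_fc <= -profile$fc_threshold]
  } else {
    hits <- table$strict_hit
    over <- table$protein_id[hits & table$signed_fc > 0]
    under <- table$protein_id[hits & table$signed_fc < 0]
  }
  list(over = over, under = under, pooled = c(over, under))
}
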