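#' Pipeline configuration
#'
#' Exactly one of (`counts_path` + `sheet_path`) or `simulate = TRUE` must
#' be active.
#'
#' @param counts_path Path to a spectral-count TSV, or NULL.
#' @param sheet_path Path to a sample-sheet TSV, or NULL.
#' @param gmt_paths Character vector of GMT library paths (may be empty;
#'   a simulated run generates its own libraries).
#' @param simulate Logical; generate inputs with [simulate_counts()].
#' @param sim_config A [simulation_config()] when `simulate` is TRUE.
#' @param output_dir Directory for all written artifacts.
#' @param min_unique_peptides Identification filter threshold (default 2).
#' @param disease_fraction,control_fraction Presence-filter fractions.
#' @param n_components PCA components to keep (default 2).
#' @param min_set_size,fdr_threshold Enrichment options.
#' @param seed Integer seed (governs simulation).
#' @return An object of class `PipelineConfig`.
#' @export
pipeline_config <- function(counts_path = NULL, sheet_path = NULL,
                            gmt_paths = character(0), simulate = FALSE,
                            sim_config = NULL, output_dir = tempfile("run"),
                            min_unique_peptides = 2,
                            disease_fraction = 1 / 2,
                            control_fraction = 2 / 3,
                            n_components = 2, min_set_size = 3,
                            fdr_threshold = 0.05, seed = 17) {
  has_paths <- !is.null(counts_path) || !is.null(sheet_path)
  if (simulate && has_paths)
    stop("config error: choose either input paths or simulate, not both",
         call. = FALSE)
  if (!simulate && (is.null(counts_path) || is.null(sheet_path)))
    stop("config error: counts_path and sheet_path are both required when ",
         "not simulating", call. = FALSE)
  if (simulate && is.null(sim_config))
    sim_config <- simulation_config(seed = seed)
  structure(list(counts_path = counts_path, sheet_path = sheet_path,
                 gmt_paths = gmt_paths, simulate = simulate,
                 sim_config = sim_config, output_dir = output_dir,
                 min_unique_peptides = min_unique_peptides,
                 disease_fraction = disease_fraction,
                 control_fraction = control_fraction,
                 n_components = n_components,
                 min_set_size = min_set_size,
                 fdr_threshold = fdr_threshold, seed = seed),
            class = "PipelineConfig")
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(unclass(config)[!(names(config) %in%
                                                  "output_dir")],
                              auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

#' Run the full membrane-organelle spectral-counting analysis
#'
#' Sequences: identification filter, per-run NSAF, technical-replicate QC,
#' replicate averaging, presence filter, minimum imputation, strict
#' differential analysis (disease = IIM plus MM, p < 0.05 and |FC| >= 3),
#' exploratory differential analysis (IIM only, |FC| >= 2.83, no p filter),
#' PCA and unsupervised clustering of the strict hits, directional gene-set
#' over-representation of the exploratory sets, and category abundance
#' summaries. All intermediates are written as TSV into
#' `config$output_dir`.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `RunReport` (also written to
#'   `report.txt` / `report.tsv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$output_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- "load"
  report <- list(version = as.character(utils::packageVersion("organoproteo")),
                 config_hash = config_hash(config), manifest = character(0))
  emit <- function(df, name) {
    path <- file.path(out, name)
    write_results(df, path)
    report$manifest <<- c(report$manifest, name)
  }
  tryCatch({
    # -- inputs --------------------------------------------------------
    libraries <- lapply(config$gmt_paths, read_gmt)
    organelle_lib <- NULL
    truth <- NULL
    if (config$simulate) {
      sim <- simulate_counts(config$sim_config)
      counts <- sim$counts
      sheet <- sim$sheet
      truth <- sim$truth
      gs <- simulate_gene_sets(truth, seed = config$sim_config$seed + 3L)
      libraries <- c(libraries, list(gs$pathways))
      organelle_lib <- gs$organelles
      emit(truth, "ground_truth.tsv")
    } else {
      counts <- read_count_table(config$counts_path)
      sheet <- read_sample_sheet(config$sheet_path)
    }
    report$n_loaded <- length(counts$protein_ids)

    stage <- "identification_filter"
    counts <- apply_identification_filter(counts,
                                          config$min_unique_peptides)
    report$n_identified <- length(counts$protein_ids)

    stage <- "nsaf"
    nsaf_run <- compute_nsaf(counts)
    emit(cbind(protein_id = nsaf_run$protein_ids,
               as.data.frame(nsaf_run$values)), "nsaf_run.tsv")

    stage <- "replicate_qc"
    has_dups <- any(table(sheet$sample_id) == 2)
    qc <- NULL
    if (has_dups) {
      qc <- replicate_qc(nsaf_run, sheet)
      report$pair_correlations <- qc$pair_correlations
      report$median_rsd <- qc$median_rsd
      emit(data.frame(sample_id = names(qc$pair_correlations),
                      pearson_r = qc$pair_correlations), "replicate_qc.tsv")
    }

    stage <- "average_replicates"
    nsaf_sample <- average_replicates(nsaf_run, sheet)
    report$n_samples <- length(nsaf_sample$column_ids)

    stage <- "presence_filter"
    nsaf_filt <- presence_filter(nsaf_sample, sheet,
                                 config$disease_fraction,
                                 config$control_fraction)
    report$n_present <- nrow(nsaf_filt$values)
    emit(cbind(protein_id = nsaf_filt$protein_ids,
               as.data.frame(nsaf_filt$values)), "nsaf_filtered.tsv")

    stage <- "imputation"
    nsaf_imp <- impute_missing(nsaf_filt)

    stage <- "strict_differential"
    strict <- analysis_profile("strict")
    tab_strict <- differential_test(nsaf_imp, sheet, strict)
    emit(tab_strict, "differential_strict.tsv")
    sel_strict <- select_dysregulated(tab_strict, strict)
    report$n_strict <- length(sel_strict$pooled)

    stage <- "exploratory_differential"
    expl <- analysis_profile("exploratory")
    tab_expl <- differential_test(nsaf_imp, sheet, expl)
    emit(tab_expl, "differential_exploratory.tsv")
    sel_expl <- select_dysregulated(tab_expl, expl)
    report$n_over <- length(sel_expl$over)
    report$n_under <- length(sel_expl$under)

    stage <- "pca"
    emb <- pca_samples(nsaf_filt, n_components = config$n_components)
    emit(data.frame(sample_id = emb$sample_ids, emb$scores),
         "pca_scores.tsv")
    report$pca_explained <- emb$explained_fraction

    stage <- "clustering"
    clust <- NULL
    if (length(sel_strict$pooled) >= 2) {
      clust <- cluster_heatmap(nsaf_imp, sel_strict$pooled)
      emit(cbind(protein_id = rownames(clust$zscored_matrix),
                 as.data.frame(clust$zscored_matrix)),
           "heatmap_zscores.tsv")
    }

    stage <- "enrichment"
    universe <- nsaf_filt$protein_ids
    enr <- NULL
    if (length(libraries)) {
      lib <- libraries[[1]]
      if (length(libraries) > 1) {
        merged <- do.call(c, lapply(libraries, function(l) l$sets))
        lib <- gene_set_library(merged)
      }
      enr <- directional_enrichment(
        intersect(sel_expl$over, universe),
        intersect(sel_expl$under, universe),
        lib, universe, config$min_set_size)
      emit(enr$over, "enrichment_over.tsv")
      emit(enr$under, "enrichment_under.tsv")
      report$top_over <- utils::head(enr$over$set[
        enr$over$q_value <= config$fdr_threshold], 5)
      report$top_under <- utils::head(enr$under$set[
        enr$under$q_value <= config$fdr_threshold], 5)
    }

    stage <- "category_abundance"
    cat_ab <- NULL
    if (!is.null(organelle_lib)) {
      cat_ab <- category_abundance(nsaf_sample, organelle_lib, sheet)
      emit(cat_ab, "category_abundance.tsv")
    }

    report$strict_fc_threshold <- strict$fc_threshold
    report$exploratory_fc_threshold <- expl$fc_threshold
    report <- structure(report, class = "RunReport")
    stage_counts <- c(report$n_loaded, report$n_identified,
                      report$n_present)
    if (any(diff(stage_counts) > 0))
      stop("internal error: stage counts increased", call. = FALSE)

    txt <- summarize_report(report)
    writeLines(txt, file.path(out, "report.txt"))
    write_results(data.frame(
      key = c("n_loaded", "n_identified", "n_present", "n_strict",
              "n_over", "n_under", "median_rsd", "config_hash"),
      value = c(report$n_loaded, report$n_identified, report$n_present,
                report$n_strict, report$n_over, report$n_under,
                if (is.null(report$median_rsd)) NA else report$median_rsd,
                report$config_hash)),
      file.path(out, "report.tsv"))
    report$results <- list(qc = qc, strict = tab_strict,
                           exploratory = tab_expl,
                           selection_strict = sel_strict,
                           selection_exploratory = sel_expl,
                           pca = emb, clustering = clust,
                           enrichment = enr,
                           category_abundance = cat_ab, truth = truth)
    report
  }, error = function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(out, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' One-page plain-text run summary
#'
#' @param report A `RunReport` from [run_pipeline()].
#' @return Character vector of summary lines.
#' @export
summarize_report <- function(report) {
  stopifnot(inherits(report, "RunReport"))
  lines <- c(
    "== membrane-organelle spectral-counting analysis ==",
    sprintf("proteins loaded: %d", report$n_loaded),
    sprintf("after identification filter (>= 2 unique peptides): %d",
            report$n_identified),
    sprintf("after presence filter: %d", report$n_present))
  if (!is.null(report$median_rsd)) {
    lines <- c(lines,
      sprintf("replicate QC: median RSD %.1f%%; pair Pearson r: %s",
              report$median_rsd,
              paste(sprintf("%s=%.2f", names(report$pair_correlations),
                            report$pair_correlations), collapse = ", ")))
  }
  n_strict <- report$n_strict
  lines <- c(lines,
    if (n_strict == 0)
      sprintf("strict profile (p < 0.05, |FC| >= %g): no significant proteins",
              report$strict_fc_threshold)
    else
      sprintf("strict profile (p < 0.05, |FC| >= %g): %d significant proteins",
              report$strict_fc_threshold, n_strict),
    sprintf("exploratory profile (|FC| >= %.2f, IIM only): %d over / %d under (%d total)",
            report$exploratory_fc_threshold, report$n_over, report$n_under,
            report$n_over + report$n_under))
  if (!is.null(report$top_over) && length(report$top_over))
    lines <- c(lines, paste("top over-enriched sets:",
                            paste(report$top_over, collapse = ", ")))
  if (!is.null(report$top_under) && length(report$top_under))
    lines <- c(lines, paste("top under-enriched sets:",
                            paste(report$top_under, collapse = ", ")))
  lines <- c(lines, sprintf("config hash: %s", report$config_hash))
  lines
}

#' @export
print.RunReport <- function(x, ...) {
  writeLines(summarize_report(x))
  invisible(x)
}
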