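test_that("compute_nsaf normalizes length-weighted counts per run", {
  # single protein: whole column mass
  one <- count_table("P1", 100, 2, cbind(r1 = 10), "r1")
  expect_equal(compute_nsaf(one)$values[1, 1], 1.0)

  # equal SpC/L shares split evenly
  two <- count_table(c("P1", "P2"), c(100, 200), c(2, 2),
                     cbind(r1 = c(10, 20)), "r1")
  expect_equal(unname(compute_nsaf(two)$values[, 1]), c(0.5, 0.5))

  # hand arithmetic: SpC/L = (0.02, 0.02, 0.10) -> (1/7, 1/7, 5/7)
  nsaf <- compute_nsaf(tiny_count_table())
  expect_equal(unname(nsaf$values[, "run1"]), c(1 / 7, 1 / 7, 5 / 7))
  expect_equal(colSums(nsaf$values), c(run1 = 1, run2 = 1),
               tolerance = 1e-12)

  # zero-count protein keeps NSAF 0
  with_zero <- count_table(c("P1", "P2"), c(100, 100), c(2, 2),
                           cbind(r1 = c(0, 5)), "r1")
  expect_equal(unname(compute_nsaf(with_zero)$values[, 1]), c(0, 1))

  # all-zero run flagged, column stays zero
  empty_run <- count_table(c("P1", "P2"), c(100, 100), c(2, 2),
                           cbind(r1 = c(1, 2), r2 = c(0, 0)),
                           c("r1", "r2"))
  expect_warning(res <- compute_nsaf(empty_run), "all-zero")
  expect_equal(attr(res, "empty_runs"), "r2")
  expect_equal(unname(res$values[, "r2"]), c(0, 0))
})

test_that("NSAF is scale-invariant per run and row-permutation equivariant", {
  set.seed(11)
  counts <- matrix(rpois(60, 20), 20, 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  tab <- count_table(sprintf("P%d", 1:20), sample(100:900, 20),
                     rep(2, 20), counts, c("a", "b", "c"))
  n1 <- compute_nsaf(tab)
  scaled <- tab
  scaled$counts[, "b"] <- scaled$counts[, "b"] * 7L
  expect_equal(compute_nsaf(scaled)$values, n1$values, tolerance = 1e-12)

  perm <- sample(20)
  tab_p <- count_table(tab$protein_ids[perm], tab$lengths[perm],
                       tab$unique_peptides[perm],
                       tab$counts[perm, ], tab$run_ids)
  expect_equal(compute_nsaf(tab_p)$values,
               n1$values[perm, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("replicate_qc computes pair correlations and paired RSD", {
  sheet <- sample_sheet(run_id = c("s1_r1", "s1_r2"),
                        sample_id = c("s1", "s1"),
                        group = c("control", "control"),
                        replicate_index = 1:2)
  # perfectly linear replicates -> r = 1
  vals <- cbind(s1_r1 = c(1, 2, 3) / 6, s1_r2 = c(2, 4, 6) / 12)
  nsaf <- nsaf_matrix(vals, c("P1", "P2", "P3"), colnames(vals), "run")
  qc <- replicate_qc(nsaf, sheet)
  expect_equal(unname(qc$pair_correlations["s1"]), 1.0)

  # two-point sample-sd formula: values in ratio (1, 2) -> RSD = 47.14%
  nsaf2 <- nsaf_matrix(cbind(s1_r1 = c(1, 5, 4), s1_r2 = c(2, 5, 3)) / 10,
                       c("P1", "P2", "P3"), c("s1_r1", "s1_r2"), "run")
  qc2 <- replicate_qc(nsaf2, sheet)
  p1 <- qc2$protein_rsd[qc2$protein_rsd$protein_id == "P1", "rsd"]
  expect_equal(p1, 100 * (abs(1 - 2) / sqrt(2)) / 1.5, tolerance = 1e-12)
  expect_equal(p1, 47.14045, tolerance = 1e-6)

  # identical replicates: all RSD 0, r = 1
  vals3 <- cbind(s1_r1 = c(0.2, 0.3, 0.5), s1_r2 = c(0.2, 0.3, 0.5))
  qc3 <- replicate_qc(nsaf_matrix(vals3, paste0("P", 1:3),
                                  colnames(vals3), "run"), sheet)
  expect_equal(qc3$median_rsd, 0)
  expect_equal(unname(qc3$pair_correlations["s1"]), 1.0)
})

test_that("replicate_qc skips non-duplicate samples and flags sparse pairs", {
  sheet <- sample_sheet(
    run_id = c("a_r1", "a_r2", "b_r1", "b_r2", "b_r3"),
    sample_id = c("a", "a", "b", "b", "b"),
    group = rep("control", 5), replicate_index = c(1, 2, 1, 2, 3))
  vals <- matrix(c(1, 2, 3, 2, 4, 6, 1, 1, 1, 1, 1, 1, 1, 1, 1) / 6,
                 nrow = 3, dimnames = list(paste0("P", 1:3), sheet$run_id))
  expect_warning(qc <- replicate_qc(
    nsaf_matrix(vals, paste0("P", 1:3), sheet$run_id, "run"), sheet),
    "skipped")
  expect_equal(names(qc$pair_correlations), "a")

  # fewer than 3 jointly quantified proteins -> undefined correlation
  sheet2 <- sample_sheet(c("c_r1", "c_r2"), c("c", "c"),
                         c("control", "control"), 1:2)
  vals2 <- cbind(c_r1 = c(0.6, 0.4, 0), c_r2 = c(0.5, 0, 0.5))
  qc2 <- replicate_qc(nsaf_matrix(vals2, paste0("P", 1:3),
                                  colnames(vals2), "run"), sheet2)
  expect_true(is.na(qc2$pair_correlations["c"]))
  expect_equal(qc2$undefined_pairs, "c")
})

test_that("average_replicates collapses runs to samples", {
  sheet <- design_sheet()
  set.seed(3)
  counts <- matrix(rpois(20 * 17, 15), nrow = 20,
                   dimnames = list(NULL, sheet$run_id))
  tab <- count_table(sprintf("P%d", 1:20), sample(100:500, 20),
                     rep(3, 20), counts, sheet$run_id)
  nsaf <- compute_nsaf(tab)
  avg <- average_replicates(nsaf, sheet)
  expect_equal(avg$level, "sample")
  expect_equal(ncol(avg$values), 14)  # 3 CT + 10 IIM + 1 MM
  expect_equal(unname(avg$values[, "CT1"]),
               unname(rowMeans(nsaf$values[, c("CT1_r1", "CT1_r2")])))
  # single-run samples pass through unchanged
  expect_equal(avg$values[, "MM1"], nsaf$values[, "MM1_r1"],
               ignore_attr = TRUE)

  # zeros participate in the mean by default; alternative drops them
  vals <- cbind(CT1_r1 = c(0, 0.5, 0.5), CT1_r2 = c(0.4, 0.3, 0.3))
  small_sheet <- sample_sheet(c("CT1_r1", "CT1_r2"), c("CT1", "CT1"),
                              c("control", "control"), 1:2)
  m <- nsaf_matrix(vals, paste0("P", 1:3), colnames(vals), "run")
  expect_equal(average_replicates(m, small_sheet)$values["P1", "CT1"], 0.2)
  expect_equal(
    average_replicates(m, small_sheet, na_zero = FALSE)$values["P1", "CT1"],
    0.4)

  # run missing from the sheet is a mapping error
  rogue <- nsaf_matrix(cbind(x_r1 = c(1, 0), CT1_r1 = c(0, 1)),
                       c("P1", "P2"), c("x_r1", "CT1_r1"), "run")
  expect_error(average_replicates(rogue, small_sheet), "absent")
})

test_that("default synthetic dataset meets the replicate QC envelope", {
  sim <- simulate_counts(simulation_config())
  filtered <- apply_identification_filter(sim$counts)
  qc <- replicate_qc(compute_nsaf(filtered), sim$sheet)
  expect_gte(qc$median_rsd, 20)
  expect_lte(qc$median_rsd, 36)
  expect_true(all(qc$pair_correlations >= 0.85))
})
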