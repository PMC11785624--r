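make_design_nsaf <- function(values) {
  # sample-level matrix over the 14-sample design
  sheet <- design_sheet()
  samples <- unique(sheet$sample_id)
  make_sample_nsaf(values, sample_ids = samples)
}

test_that("presence filter applies ceiling OR-semantics over groups", {
  sheet <- design_sheet()  # 11 disease, 3 control -> need 6 or 2
  v <- matrix(0, nrow = 3, ncol = 14)
  v[1, 4:8] <- 1e-3   # 5 disease, 1 control (col 1..3 are CT)
  v[1, 1] <- 1e-3
  v[2, 2:3] <- 1e-3   # 0 disease, 2 of 3 controls
  v[3, 1:14] <- 1e-3  # everywhere
  nsaf <- make_design_nsaf(v)
  kept <- presence_filter(nsaf, sheet)$protein_ids
  expect_false("P1" %in% kept)  # 5 < 6 and 1 < 2
  expect_true("P2" %in% kept)   # control arm alone suffices (OR)
  expect_true("P3" %in% kept)

  # fractions of 1 with full presence still retained (boundary)
  kept_all <- presence_filter(nsaf, sheet, 1, 1)$protein_ids
  expect_equal(kept_all, "P3")
  expect_error(presence_filter(nsaf, sheet, 0, 0.5), "fraction")
})

test_that("presence filter is monotone in both fractions", {
  sheet <- design_sheet()
  set.seed(21)
  v <- matrix(rbinom(40 * 14, 1, 0.5) * runif(40 * 14), nrow = 40)
  nsaf <- make_design_nsaf(v)
  fracs <- c(0.2, 0.4, 0.6, 0.8, 1)
  n_kept <- vapply(fracs, function(f)
    nrow(presence_filter(nsaf, sheet, f, f)$values), integer(1))
  expect_true(all(diff(n_kept) <= 0))
})

test_that("minimum imputation is per-column, positive and idempotent", {
  v <- cbind(S1 = c(0, 1e-4, 9e-4), S2 = c(2e-4, 0, 8e-4))
  nsaf <- make_sample_nsaf(v)
  imp <- impute_missing(nsaf)
  expect_equal(unname(imp$values[, "S1"]), c(1e-4, 1e-4, 9e-4))
  # each zero takes its own column's minimum, not a global one
  expect_equal(imp$values["P2", "S2"], 2e-4)
  expect_true(all(imp$values > 0))
  expect_equal(impute_missing(imp)$values, imp$values)  # idempotent

  # column with no zeros is untouched
  nz <- make_sample_nsaf(cbind(S1 = c(0.4, 0.6)))
  expect_equal(impute_missing(nz)$values, nz$values)

  # all-zero column is a degenerate sample
  bad <- make_sample_nsaf(cbind(S1 = c(0.5, 0.5), S2 = c(0, 0)))
  expect_error(impute_missing(bad), "S2")
})

test_that("signed fold change follows the +r / -1/r convention", {
  expect_equal(signed_fold_change(1e-4, 1e-4), 1)
  expect_equal(signed_fold_change(4e-4, 1e-4), 4)
  expect_equal(signed_fold_change(1e-4, 4e-4), -4)
  # the printed two-decimal style for a deep loss
  expect_equal(round(signed_fold_change(3.821e-5, 1e-3), 2), -26.17)
  expect_error(signed_fold_change(0, 1), "> 0")
})

test_that("signed fold change is antisymmetric", {
  set.seed(9)
  a <- rlnorm(200, -8, 1)
  b <- rlnorm(200, -8, 1)
  expect_equal(signed_fold_change(a, b), -signed_fold_change(b, a),
               tolerance = 1e-12)
  expect_true(all(abs(signed_fold_change(a, b)) >= 1))
})

test_that("differential_test matches the t reference on the toy vectors", {
  sheet <- sample_sheet(
    run_id = c("c1_r1", "c2_r1", "c3_r1", "d1_r1", "d2_r1", "d3_r1"),
    sample_id = c("c1", "c2", "c3", "d1", "d2", "d3"),
    group = c(rep("control", 3), rep("IIM", 3)),
    replicate_index = rep(1L, 6))
  v <- matrix(c(1, 2, 3, 4, 5, 6) * 1e-4, nrow = 1,
              dimnames = list("P1", c("c1", "c2", "c3", "d1", "d2", "d3")))
  nsaf <- nsaf_matrix(v, "P1", colnames(v), "sample")
  prof <- analysis_profile("strict", disease_groups = "IIM")
  res <- differential_test(nsaf, sheet, prof)

  # oracle: hand t statistic + reference t distribution (equal variances,
  # so Welch df = 4 here)
  se <- sqrt(1 / 3 + 1 / 3)       # unit variance in both groups (x 1e-4)
  t_stat <- 3 / se
  p_oracle <- 2 * pt(-t_stat, df = 4)
  expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  expect_equal(round(t_stat, 4), 3.6742)
  expect_equal(round(res$p_value, 4), 0.0213)
  expect_equal(res$stars, "*")

  # Student option agrees here since group variances are equal
  expect_equal(differential_test(nsaf, sheet, prof,
                                 var_equal = TRUE)$p_value,
               p_oracle, tolerance = 1e-9)
})

test_that("differential_test null, degenerate and threshold behavior", {
  sheet <- design_sheet()
  samples <- unique(sheet$sample_id)
  # disease identical to control values -> fc +1, p = 1 via degeneracy
  v <- matrix(1e-3, nrow = 2, ncol = 14,
              dimnames = list(c("P1", "P2"), samples))
  v[2, 4:14] <- 5e-3  # constant but different in disease
  nsaf <- nsaf_matrix(v, c("P1", "P2"), samples, "sample")
  res <- differential_test(nsaf, sheet, analysis_profile("strict"))
  expect_equal(res$signed_fc[1], 1)
  expect_equal(res$p_value[1], 1)
  expect_equal(res$flags[1], "degenerate_variance")
  expect_equal(res$p_value[2], 0)  # zero variance, unequal means
  expect_false(res$strict_hit[1])

  # strict hit with two stars
  set.seed(2)
  ctrl <- c(1.0, 1.1, 0.9) * 1e-4
  dis <- c(3.4, 3.6, 3.5, 3.3, 3.7, 3.5, 3.6, 3.4, 3.5, 3.6, 3.5) * 1e-4
  v2 <- matrix(c(ctrl, dis), nrow = 1, dimnames = list("P1", samples))
  res2 <- differential_test(nsaf_matrix(v2, "P1", samples, "sample"),
                            sheet, analysis_profile("strict"))
  expect_true(res2$strict_hit[1])
  expect_true(res2$p_value[1] < 0.01)
  expect_equal(res2$stars[1], "**")
  expect_gte(abs(res2$signed_fc[1]), 3)

  # fewer than two samples in a group is a design error
  small_sheet <- sample_sheet(c("c1_r1", "d1_r1", "d2_r1"),
                              c("c1", "d1", "d2"),
                              c("control", "IIM", "IIM"), rep(1L, 3))
  v3 <- matrix(1e-3, 1, 3, dimnames = list("P1", c("c1", "d1", "d2")))
  expect_error(differential_test(
    nsaf_matrix(v3, "P1", colnames(v3), "sample"), small_sheet,
    analysis_profile("strict")), "design error")
})

test_that("select_dysregulated applies profile semantics", {
  tab <- data.frame(
    protein_id = c("A", "B", "C"),
    median_disease = 1, mean_control = 1,
    ratio = 1, signed_fc = c(3.0, -2.9, -4.1),
    p_value = c(0.2, 0.01, 0.6), q_value_advisory = 1,
    stars = "", strict_hit = FALSE,
    exploratory_direction = c("over", "none", "under"), flags = "",
    stringsAsFactors = FALSE)
  class(tab) <- c("DifferentialTable", "data.frame")
  expl <- analysis_profile("exploratory")
  sel <- select_dysregulated(tab, expl)
  expect_equal(sel$over, "A")            # +3.0 >= 2.83
  expect_equal(sel$under, c("B", "C"))   # both <= -2.83
  expect_length(intersect(sel$over, sel$under), 0)

  empty <- tab[0, ]
  class(empty) <- c("DifferentialTable", "data.frame")
  sel0 <- select_dysregulated(empty, expl)
  expect_length(sel0$over, 0)
  expect_length(sel0$under, 0)
})
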