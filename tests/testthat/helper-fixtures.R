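# Small in-code fixtures and independent oracles shared across tests.

# 3 proteins x 2 runs, hand-checkable counts
tiny_count_table <- function() {
  count_table(
    protein_ids = c("P1", "P2", "P3"),
    lengths = c(200, 300, 100),
    unique_peptides = c(2, 5, 3),
    counts = cbind(run1 = c(4, 6, 10), run2 = c(8, 12, 20)),
    run_ids = c("run1", "run2")
  )
}

# study-design sheet: 3 controls x 2 technical replicates + 10 IIM + 1 MM
design_sheet <- function() {
  sample_sheet(
    run_id = c(paste0(rep(c("CT1", "CT2", "CT3"), each = 2), "_r",
                      rep(1:2, 3)),
               paste0("IIM", sprintf("%02d", 1:10), "_r1"), "MM1_r1"),
    sample_id = c(rep(c("CT1", "CT2", "CT3"), each = 2),
                  paste0("IIM", sprintf("%02d", 1:10)), "MM1"),
    group = c(rep("control", 6), rep("IIM", 10), "MM"),
    replicate_index = c(rep(1:2, 3), rep(1L, 11))
  )
}

# sample-level NSAF matrix built directly from a value matrix
make_sample_nsaf <- function(values, protein_ids = NULL,
                             sample_ids = NULL) {
  protein_ids <- protein_ids %||% sprintf("P%d", seq_len(nrow(values)))
  sample_ids <- sample_ids %||% sprintf("S%d", seq_len(ncol(values)))
  nsaf_matrix(values, protein_ids, sample_ids, level = "sample")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force hypergeometric upper tail: enumerate all C(N, n) draws
hyper_upper_tail_bruteforce <- function(N, K, n, k) {
  universe <- seq_len(N)
  in_set <- universe <= K
  draws <- utils::combn(N, n)
  overlaps <- colSums(matrix(in_set[draws], nrow = n))
  mean(overlaps >= k)
}

# hand step-up BH
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[o[i]] * m / i)
    q[o[i]] <- prev
  }
  q
}

# three z-scored rows (mean 0, sd 1) with exact pairwise euclidean
# distances 1 (A-B), 4 (A-C), 4 (B-C) over 9 samples; built from an
# orthonormal mean-zero basis so that d^2 = 2*(n-1)*(1 - r)
toy_ultrametric_rows <- function() {
  S <- 8  # n - 1
  base <- stats::contr.helmert(9)          # 9 x 8, columns orthogonal, mean 0
  e <- apply(base[, 1:3], 2, function(v) v / sqrt(sum(v^2) / S))
  r_ab <- 1 - 1 / (2 * S)                  # gives d(A,B) = 1
  zA <- e[, 1]
  zB <- r_ab * e[, 1] + sqrt(1 - r_ab^2) * e[, 2]
  zC <- e[, 3]                             # orthogonal: d = sqrt(2*S) = 4
  m <- rbind(A = zA, B = zB, C = zC)
  colnames(m) <- sprintf("S%d", 1:9)
  m
}
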