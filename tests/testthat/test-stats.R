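test_that("one-sample t series matches the textbook formula", {
  X <- matrix(c(1.2, 0.8, 1.1, 0.9,
                2.0, 1.5, 2.5, 1.0,
                0.0, 0.1, -0.1, 0.0), nrow = 4)
  res <- one_sample_t_series(X, mu = 0.5)
  for (s in 1:3) {
    m <- mean(X[, s]); sd_ <- sd(X[, s])
    expect_equal(res$t[s], (m - 0.5) / (sd_ / 2), tolerance = 1e-12)
    expect_equal(res$p[s], 2 * pt(-abs(res$t[s]), df = 3), tolerance = 1e-12)
  }
})

test_that("degenerate t inputs follow the documented conventions", {
  # all participants exactly at mu: no evidence against mu
  X <- matrix(0.02, nrow = 5, ncol = 3)
  res <- one_sample_t_series(X, mu = 0.02)
  expect_equal(res$t, rep(0, 3))
  expect_equal(res$p, rep(1, 3))
  # zero variance away from mu: missing marker
  res2 <- one_sample_t_series(X, mu = 0)
  expect_true(all(is.na(res2$t)))
  # a strong constant offset with tiny jitter is overwhelming at n=31
  set.seed(2)
  X3 <- matrix(0.02 + 0.5 + rnorm(31 * 2, sd = 1e-3), nrow = 31)
  res3 <- one_sample_t_series(X3, mu = 0.02)
  expect_true(all(res3$p < 1e-6))
})

test_that("chance level is the median of the across-condition average", {
  expect_equal(chance_level(c(0.01, 0.02, 0.03)), 0.02)
  expect_equal(chance_level(rep(0.37, 10)), 0.37)
  set.seed(3)
  ga <- matrix(rnorm(400, mean = 0.02, sd = 0.01), 100, 4)
  expect_equal(chance_level(ga), sort(rowMeans(ga))[c(50, 51)] |> mean())
})

test_that("Benjamini-Yekutieli matches the hand step-up oracle", {
  expect_equal(benjamini_yekutieli(0.03), 0.03)
  expect_equal(benjamini_yekutieli(c(0.01, 0.04)), c(0.03, 0.06))
  expect_equal(benjamini_yekutieli(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "0, 1")
  set.seed(4)
  for (rep in 1:20) {
    p <- runif(sample(3:40, 1))
    adj <- benjamini_yekutieli(p)
    expect_equal(adj, by_oracle(p), tolerance = 1e-12)
    # BY >= BH >= raw, elementwise
    expect_true(all(adj >= p.adjust(p, "BH") - 1e-12))
    expect_true(all(p.adjust(p, "BH") >= p - 1e-12))
  }
})

test_that("window detection merges runs into the spanning envelope", {
  times <- seq(-800, -1)
  p <- rep(0.5, 800)
  sig_runs <- c(-730, -687, -658, -579, -560, -511)
  p[times >= -730 & times <= -687] <- 0.01
  p[times >= -658 & times <= -579] <- 0.01
  p[times >= -560 & times <= -511] <- 0.01
  det <- detect_windows(p, times, alpha = 0.05)
  expect_identical(nrow(det$windows), 3L)
  expect_equal(det$windows$start_ms, c(-730, -658, -560))
  expect_equal(det$windows$end_ms, c(-687, -579, -511))
  expect_equal(det$envelope, c(-730, -511))
  # nothing significant -> empty; single sample -> one-sample window
  expect_null(detect_windows(rep(0.9, 10), 1:10)$envelope)
  one <- detect_windows(c(1, 1, 0.01, 1), times = c(10, 20, 30, 40))
  expect_equal(one$envelope, c(30, 30))
  expect_identical(one$windows$n_samples, 1L)
})

test_that("identical conditions produce no clusters", {
  set.seed(5)
  A <- matrix(rnorm(20 * 50), 20)
  ct <- cluster_permutation_test(A, A, times = 1:50, n_perm = 200, seed = 1)
  expect_identical(nrow(ct$clusters), 0L)
})

test_that("a planted offset is detected as one covering cluster", {
  set.seed(6)
  n <- 20; S <- 120
  A <- matrix(rnorm(n * S), n)
  B <- matrix(rnorm(n * S), n)
  window <- 41:90
  # 5 within-participant SDs of the paired difference (sd = sqrt(2))
  A[, window] <- A[, window] + 5 * sqrt(2)
  ct <- cluster_permutation_test(A, B, times = seq_len(S), n_perm = 1000,
                                 seed = 2)
  top <- ct$clusters[1, ]
  expect_lt(top$p, 0.01)
  covered <- sum(window >= top$start_idx & window <= top$end_idx)
  expect_gte(covered / length(window), 0.9)
})

test_that("permutation p-values are invariant to participant relabeling", {
  set.seed(7)
  A <- matrix(rnorm(12 * 40, mean = 0.3), 12)
  B <- matrix(rnorm(12 * 40), 12)
  ct1 <- cluster_permutation_test(A, B, 1:40, n_perm = 500, seed = 9)
  perm <- sample(12)
  ct2 <- cluster_permutation_test(A[perm, ], B[perm, ], 1:40, n_perm = 500,
                                  seed = 9)
  # the observed statistic is exactly invariant; the Monte-Carlo null is
  # invariant in distribution, so p-values agree to permutation error
  expect_equal(ct1$t_series, ct2$t_series)
  expect_equal(ct1$clusters$mass, ct2$clusters$mass)
  expect_lt(max(abs(ct1$clusters$p - ct2$clusters$p)), 0.06)
  # two-sided mode: swapping A and B flips t but keeps the same p-values
  ct3 <- cluster_permutation_test(A, B, 1:40, n_perm = 500, seed = 9,
                                  direction = "two_sided")
  ct4 <- cluster_permutation_test(B, A, 1:40, n_perm = 500, seed = 9,
                                  direction = "two_sided")
  expect_equal(ct3$t_series, -ct4$t_series)
  expect_equal(sort(ct3$clusters$p), sort(ct4$clusters$p))
})

test_that("stochastic outputs are bit-reproducible under a fixed seed", {
  set.seed(8)
  A <- matrix(rnorm(10 * 30, mean = 0.4), 10)
  B <- matrix(rnorm(10 * 30), 10)
  ct1 <- cluster_permutation_test(A, B, 1:30, n_perm = 300, seed = 77)
  ct2 <- cluster_permutation_test(A, B, 1:30, n_perm = 300, seed = 77)
  expect_identical(ct1$null_max, ct2$null_max)
  expect_identical(ct1$clusters, ct2$clusters)
})

test_that("permutation test rejects invalid configurations", {
  A <- matrix(rnorm(10 * 5), 10)
  expect_error(cluster_permutation_test(A, A, 1:5, n_perm = 50, seed = 1),
               "floor")
  expect_error(cluster_permutation_test(A, A, 1:5, n_perm = 100), "seed")
})

test_that("max-t latency picks the peak of the largest cluster", {
  # craft a t-series with two clusters; the larger one has a known argmax
  tt <- rep(0, 30)
  tt[5:8] <- c(2.5, 3.0, 2.6, 2.2)          # small cluster, mass 10.3
  tt[15:22] <- c(2.5, 3.2, 4.8, 3.9, 3.0, 2.7, 2.5, 2.2)  # mass 24.8
  fake <- structure(list(clusters = NULL, t_series = tt), class = "cluster_test")
  clusters <- rrsa:::find_clusters_1d(tt, 2.04)
  clusters$start_ms <- (1:30)[clusters$start_idx]
  clusters$end_ms <- (1:30)[clusters$end_idx]
  clusters$max_t_ms <- (1:30)[clusters$max_idx]
  clusters$significant <- TRUE
  fake$clusters <- clusters
  expect_equal(max_t_latency(fake), 17)
  # monotone-rising t within a single cluster peaks at the last member
  tt2 <- c(0, 2.1, 2.5, 3.0, 3.5, 0)
  cl2 <- rrsa:::find_clusters_1d(tt2, 2.04)
  expect_identical(cl2$max_idx, 5L)
  # single-sample cluster is its own latency; exact ties break earlier
  tt3 <- c(0, 3, 0, 2.5, 2.5, 0)
  cl3 <- rrsa:::find_clusters_1d(tt3, 2.04)
  expect_identical(cl3$max_idx[1], 2L)
  expect_identical(cl3$max_idx[2], 4L)
})

test_that("jack-knife latency recovers a deterministic planted shift", {
  S <- 100
  n <- 12
  base <- matrix(0, n, S)
  bump <- function(center) {
    prof <- exp(-((1:S) - center)^2 / 18)
    matrix(rep(prof, each = n), n) + matrix(rnorm(n * S, sd = 1e-3), n)
  }
  set.seed(10)
  A <- bump(40)
  B <- A[, c((S - 19):S, 1:(S - 20)), drop = FALSE]  # shifted by 20 samples
  times <- seq(0, by = 2, length.out = S)            # 2 ms per sample
  jk <- jackknife_latency_comparison(A, B, base, times, n_perm = 1000,
                                     seed = 11, check_significance = FALSE)
  expect_equal(jk$delta_ms, -40, tolerance = 1e-9)   # 20 samples at 2 ms
  expect_lt(jk$p_perm, 0.05)
  expect_identical(jk$n_unstable, 0L)
})

test_that("identical conditions give zero latency difference and p near 1", {
  S <- 60; n <- 10
  set.seed(12)
  prof <- exp(-((1:S) - 30)^2 / 20)
  A <- matrix(rep(prof, each = n), n) + matrix(rnorm(n * S, sd = 1e-3), n)
  base <- matrix(0, n, S)
  jk <- jackknife_latency_comparison(A, A, base, 1:S, n_perm = 500,
                                     seed = 13, check_significance = FALSE)
  expect_equal(jk$delta_ms, 0)
  expect_gt(jk$p_perm, 0.9)
})

test_that("latency comparison refuses a non-significant gating effect", {
  set.seed(14)
  A <- matrix(rnorm(10 * 40), 10)
  B <- matrix(rnorm(10 * 40), 10)
  base <- matrix(0, 10, 40)
  expect_error(
    jackknife_latency_comparison(A, B, base, 1:40, n_perm = 200, seed = 15),
    "not significant")
})

test_that("4-connectivity labeling separates diagonal touches", {
  mask <- matrix(FALSE, 5, 5)
  mask[1:2, 1:2] <- TRUE       # block
  mask[3, 3] <- TRUE           # touches the block only diagonally
  mask[5, 1] <- TRUE           # isolated
  lab <- rrsa:::label_4conn(mask)
  expect_identical(max(lab), 3L)
  expect_true(all(lab[1:2, 1:2] == lab[1, 1]))
  expect_false(lab[3, 3] == lab[1, 1])
  # an L-shaped component stays one component
  mask2 <- matrix(FALSE, 4, 4)
  mask2[1, 1:3] <- TRUE; mask2[2:3, 3] <- TRUE
  expect_identical(max(rrsa:::label_4conn(mask2)), 1L)
})

test_that("2-D cluster test flags a planted diagonal block and nothing else", {
  set.seed(16)
  n <- 12; S <- 24
  arr <- array(rnorm(n * S * S, sd = 0.1), dim = c(n, S, S))
  block <- 9:14
  arr[, block, block] <- arr[, block, block] + 0.4
  res <- cts_cluster_test(arr, times = seq_len(S), n_perm = 300, seed = 17)
  expect_gte(nrow(res$clusters), 1L)
  top <- res$clusters[1, ]
  expect_true(top$significant)
  expect_true(top$max_t_row_ms %in% block && top$max_t_col_ms %in% block)
  # zero matrices: no clusters at all
  res0 <- cts_cluster_test(array(0, dim = c(5, 8, 8)), 1:8, n_perm = 100,
                           seed = 18)
  expect_identical(nrow(res0$clusters), 0L)
})

test_that("2-D null data rarely produce significant clusters", {
  set.seed(19)
  hits <- 0L
  for (rep in 1:60) {
    arr <- array(rnorm(10 * 16 * 16), dim = c(10, 16, 16))
    res <- cts_cluster_test(arr, 1:16, n_perm = 150, seed = rep,
                            n_tests = 1L)
    if (any(res$clusters$significant)) hits <- hits + 1L
  }
  expect_lte(hits / 60, 0.15)
})

test_that("Bonferroni scaling caps corrected p-values at 1", {
  set.seed(20)
  arr <- array(rnorm(8 * 10 * 10, mean = 0.05), dim = c(8, 10, 10))
  res <- cts_cluster_test(arr, 1:10, n_perm = 100, seed = 3, n_tests = 4L)
  if (nrow(res$clusters)) {
    expect_true(all(res$clusters$p_bonferroni <= 1))
    expect_true(all(res$clusters$p_bonferroni >= res$clusters$p))
  }
})
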