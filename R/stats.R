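#' Per-sample one-sample t-test series
#'
#' At every time sample, a one-sample t-test of the participants' values
#' against `mu`, with a two-tailed p-value. Samples with zero variance (or
#' fewer than two finite values) are returned as missing, except the
#' degenerate case of every value sitting exactly at `mu`, which reports
#' t = 0, p = 1.
#'
#' @param signals Participants x samples numeric matrix.
#' @param mu Null value (e.g. the chance level).
#' @return A list with `t`, `p`, `df`, `n` and `mean` per sample.
#' @export
one_sample_t_series <- function(signals, mu = 0) {
  signals <- as.matrix(signals)
  if (nrow(signals) < 3L) stop("need at least three participants")
  fin <- is.finite(signals)
  n <- colSums(fin)
  m <- colMeans(signals, na.rm = TRUE)
  s <- apply(signals, 2L, stats::sd, na.rm = TRUE)
  t <- (m - mu) / (s / sqrt(n))
  t[!is.finite(t)] <- NA_real_
  t[(n < 2L) | (!is.na(s) & s == 0)] <- NA_real_
  # a sample sitting exactly at mu with zero spread carries no evidence
  # against mu: report t = 0 rather than a zero-variance missing marker
  at_mu <- (n >= 2L) & !is.na(s) & s == 0 & !is.na(m) & m == mu
  t[at_mu] <- 0
  p <- 2 * stats::pt(-abs(t), df = n - 1L)
  list(t = unname(t), p = unname(p), df = unname(n - 1L), n = unname(n),
       mean = unname(m))
}

#' Chance level of a similarity analysis
#'
#' The median over time of the across-condition average of the grand-average
#' condition signals — the empirical "no structure" similarity level against
#' which the time series are tested (0.02 in the motivating dataset).
#'
#' @param grand_avg A [grand_average()] matrix (samples x conditions) or a
#'   numeric vector already averaged across conditions.
#' @return A single number.
#' @export
chance_level <- function(grand_avg) {
  x <- if (is.matrix(grand_avg)) rowMeans(unclass(grand_avg), na.rm = TRUE) else as.numeric(grand_avg)
  if (!length(x)) stop("empty series")
  stats::median(x, na.rm = TRUE)
}

#' Benjamini-Yekutieli adjusted p-values
#'
#' Step-up false-discovery-rate control valid under arbitrary dependence,
#' with the harmonic-number penalty \eqn{c(m) = \sum_{i=1}^m 1/i}.
#'
#' @param pvals Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values (elementwise at least the raw values, capped
#'   at 1).
#' @export
benjamini_yekutieli <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (any(!is.na(pvals) & (pvals < 0 | pvals > 1))) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BY")
}

#' Detect windows of consecutive significant samples
#'
#' Maximal runs of samples with adjusted p below `alpha`, plus the merged
#' envelope spanning from the earliest onset to the latest offset — the rule
#' used to turn the against-chance test into an analysis window.
#'
#' @param p_adj Adjusted p-value series.
#' @param times Time axis in ms, same length.
#' @param alpha Significance level (default 0.05).
#' @return A list with `windows` (data.frame `start_ms`, `end_ms`,
#'   `n_samples`) and `envelope` (length-2 vector, or `NULL` when nothing is
#'   significant).
#' @export
detect_windows <- function(p_adj, times, alpha = 0.05) {
  stopifnot(length(p_adj) == length(times))
  sig <- is.finite(p_adj) & p_adj < alpha
  runs <- rle(sig)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  windows <- data.frame(start_ms = times[starts[keep]],
                        end_ms = times[ends[keep]],
                        n_samples = runs$lengths[keep])
  envelope <- if (nrow(windows)) c(min(windows$start_ms), max(windows$end_ms)) else NULL
  list(windows = windows, envelope = envelope)
}

# ---- cluster machinery ----------------------------------------------------

# contiguous suprathreshold runs of a t-series; ties in the max broken
# toward the earlier sample (which.max returns the first maximum)
find_clusters_1d <- function(t_series, threshold,
                             direction = c("positive", "two_sided")) {
  direction <- match.arg(direction)
  out <- list()
  for (sgn in if (direction == "positive") 1 else c(1, -1)) {
    mask <- is.finite(t_series) & (sgn * t_series > threshold)
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (k in which(runs$values)) {
      seg <- starts[k]:ends[k]
      tt <- t_series[seg]
      peak <- which.max(sgn * tt)
      out[[length(out) + 1L]] <- data.frame(
        start_idx = starts[k], end_idx = ends[k], sign = sgn,
        mass = sum(tt), max_t = tt[peak], max_idx = seg[peak],
        n_samples = length(seg))
    }
  }
  if (!length(out)) {
    return(data.frame(start_idx = integer(0), end_idx = integer(0),
                      sign = numeric(0), mass = numeric(0), max_t = numeric(0),
                      max_idx = integer(0), n_samples = integer(0)))
  }
  do.call(rbind, out)
}

# paired-difference t-values under sign-flip permutations, computed from the
# sufficient statistics: flipping signs leaves each participant's squared
# value unchanged, so only the column sums move.
perm_t_matrix <- function(D, signs) {
  n_obs <- colSums(is.finite(D))
  Dz <- D; Dz[!is.finite(Dz)] <- 0
  sums <- signs %*% Dz                                  # perms x samples
  means <- sweep(sums, 2L, n_obs, `/`)
  sumsq <- colSums(Dz^2)
  vars <- sweep(-(means^2), 2L, sumsq / n_obs, `+`)     # (sumsq/n - mean^2)
  vars <- sweep(vars, 2L, n_obs / (n_obs - 1L), `*`)
  vars[vars < 0] <- 0
  t <- means / sqrt(sweep(vars, 2L, n_obs, `/`))
  t[!is.finite(t)] <- NA_real_
  t
}

# fast largest |cluster mass| of one t-series (no bookkeeping)
max_mass_1d <- function(tt, threshold, direction) {
  best <- 0
  for (sgn in if (direction == "positive") 1 else c(1, -1)) {
    mask <- is.finite(tt) & (sgn * tt > threshold)
    if (!any(mask)) next
    runs <- rle(mask)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    cs <- cumsum(ifelse(mask, tt, 0))
    for (k in which(runs$values)) {
      mass <- abs(cs[ends[k]] - (if (starts[k] > 1L) cs[starts[k] - 1L] else 0))
      if (mass > best) best <- mass
    }
  }
  best
}

max_cluster_mass_rows <- function(T_mat, threshold, direction) {
  apply(T_mat, 1L, max_mass_1d, threshold = threshold, direction = direction)
}

#' Cluster-mass permutation test on paired condition signals
#'
#' Computes the paired t-series of `condA - condB` across participants,
#' forms clusters by summing adjacent t-values beyond the cluster-forming
#' threshold (default 2.04, the two-tailed 5% critical t at 30 degrees of
#' freedom), and compares each observed cluster mass against the null
#' distribution of the maximum cluster mass obtained by randomly swapping
#' the condition labels within participants (equivalently, sign-flipping the
#' paired differences). P-values use the +1 correction and so never reach 0.
#'
#' @param condA,condB Participants x samples matrices (paired rows).
#' @param times Time axis in ms.
#' @param threshold_t Cluster-forming threshold (> 0).
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed (mandatory).
#' @param alpha Cluster significance level.
#' @param direction `"positive"` tests only clusters where A exceeds B (the
#'   default, matching directional hypotheses of similarity above baseline);
#'   `"two_sided"` also forms negative clusters.
#' @return An object of class `cluster_test` with a `clusters` data.frame
#'   (`start_ms`, `end_ms`, `mass`, `max_t`, `max_t_ms`, `p`,
#'   `significant`), the observed `t_series`, and the test configuration.
#' @export
cluster_permutation_test <- function(condA, condB, times, threshold_t = 2.04,
                                     n_perm = 1000L, seed, alpha = 0.05,
                                     direction = c("positive", "two_sided")) {
  direction <- match.arg(direction)
  condA <- as.matrix(condA); condB <- as.matrix(condB)
  stopifnot(all(dim(condA) == dim(condB)), ncol(condA) == length(times),
            threshold_t > 0)
  if (n_perm < 100L) stop("n_perm below the floor of 100")
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  D <- condA - condB
  n <- nrow(D)
  if (n < 3L) stop("need at least three paired participants")

  t_obs <- as.vector(perm_t_matrix(D, matrix(1, 1L, n)))
  clusters <- find_clusters_1d(t_obs, threshold_t, direction)

  null_max <- with_seed(seed, {
    signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), n_perm, n)
    T_perm <- perm_t_matrix(D, signs)
    max_cluster_mass_rows(T_perm, threshold_t, direction)
  })

  if (nrow(clusters)) {
    clusters$start_ms <- times[clusters$start_idx]
    clusters$end_ms <- times[clusters$end_idx]
    clusters$max_t_ms <- times[clusters$max_idx]
    # ties between null and observed masses are genuine under sign-flipping
    # (e.g. the identity pattern); count them with a tolerance so that
    # floating-point rounding cannot flip a tie
    clusters$p <- vapply(abs(clusters$mass), function(m) {
      (1 + sum(null_max >= m - 1e-9)) / (1 + n_perm)
    }, numeric(1))
    clusters$significant <- clusters$p <= alpha
    clusters <- clusters[order(-abs(clusters$mass)), , drop = FALSE]
    rownames(clusters) <- NULL
  } else {
    clusters$start_ms <- clusters$end_ms <- clusters$max_t_ms <-
      clusters$p <- numeric(0)
    clusters$significant <- logical(0)
  }
  structure(list(clusters = clusters, t_series = t_obs, times = times,
                 threshold = threshold_t, n_perm = n_perm, seed = seed,
                 alpha = alpha, direction = direction, null_max = null_max),
            class = "cluster_test")
}

#' @export
print.cluster_test <- function(x, ...) {
  cat(sprintf("<cluster_test> threshold t=%.2f, %d permutations, seed %s\n",
              x$threshold, x$n_perm, format(x$seed)))
  if (!nrow(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    df <- x$clusters[c("start_ms", "end_ms", "mass", "max_t", "max_t_ms",
                       "p", "significant")]
    print(df, digits = 4)
  }
  invisible(x)
}

#' Latency of the maximum t within the largest cluster
#'
#' The largest-mass cluster of a [cluster_permutation_test()] is used as a
#' mask, and the time of its maximum t-value is returned; ties break toward
#' the earlier sample.
#'
#' @param test A `cluster_test` object.
#' @param significant_only If `TRUE`, only significant clusters qualify.
#' @return Latency in ms, or `NA` if no qualifying cluster exists.
#' @export
max_t_latency <- function(test, significant_only = FALSE) {
  stopifnot(inherits(test, "cluster_test"))
  cl <- test$clusters
  if (significant_only) cl <- cl[cl$significant, , drop = FALSE]
  if (!nrow(cl)) return(NA_real_)
  cl <- cl[order(-abs(cl$mass), cl$start_idx), , drop = FALSE]
  cl$max_t_ms[1L]
}

# largest-cluster max-t latency of a plain t-series (no permutations), used
# inside the jack-knife loop
largest_cluster_latency <- function(t_series, times, threshold,
                                    direction = "positive") {
  cl <- find_clusters_1d(t_series, threshold, direction)
  if (!nrow(cl)) return(NA_real_)
  cl <- cl[order(-abs(cl$mass), cl$start_idx), , drop = FALSE]
  times[cl$max_idx[1L]]
}

#' Jack-knife latency comparison between two effects
#'
#' For each leave-one-participant-out subsample, the paired t-series of each
#' condition against the baseline is recomputed, the largest suprathreshold
#' cluster is used as a mask, and the latency of its maximum t extracted.
#' The two resulting latency sets are compared with a sign-flip permutation
#' test on their paired differences. Comparisons are only meaningful when
#' both effects are significant in the full-sample cluster test, which is
#' verified first.
#'
#' Two test statistics on the leave-one-out values are reported: a naive
#' paired t (treating the n jack-knife values as independent observations,
#' as is sometimes done in practice) and the jack-knife-corrected statistic
#' whose standard error carries the (n-1) inflation factor required for
#' leave-one-out values. The corrected one is the appropriate default; the
#' naive one is retained for comparability with uncorrected analyses.
#'
#' @param condA,condB,baseline Participants x samples matrices (paired).
#' @param times Time axis in ms.
#' @param threshold_t Cluster-forming threshold.
#' @param n_perm Permutations for both the gating cluster tests and the
#'   latency permutation test.
#' @param seed RNG seed (mandatory).
#' @param alpha Significance level for the gating tests.
#' @param check_significance Set `FALSE` to skip the gating requirement
#'   (e.g. in simulations).
#' @return An object of class `jackknife_latency`: jack-knife mean latencies
#'   (ms) per condition, their difference `delta_ms` (A minus B), the
#'   permutation p-value, both jack-knife t statistics with their p-values,
#'   the raw leave-one-out latencies, and the number of unstable iterations
#'   (subsamples where an effect vanished; these are dropped pairwise).
#' @export
jackknife_latency_comparison <- function(condA, condB, baseline, times,
                                         threshold_t = 2.04, n_perm = 1000L,
                                         seed, alpha = 0.05,
                                         check_significance = TRUE) {
  condA <- as.matrix(condA); condB <- as.matrix(condB)
  baseline <- as.matrix(baseline)
  stopifnot(all(dim(condA) == dim(baseline)), all(dim(condB) == dim(baseline)))
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  n <- nrow(condA)
  if (n < 5L) stop("need at least five participants for jack-knife latencies")

  if (check_significance) {
    for (nm in c("A", "B")) {
      cond <- if (nm == "A") condA else condB
      full <- cluster_permutation_test(cond, baseline, times, threshold_t,
                                       n_perm, seed = seed, alpha = alpha)
      if (!any(full$clusters$significant)) {
        stop("effect ", nm, " is not significant in the full-sample cluster ",
             "test; latency comparison not performed")
      }
    }
  }

  loo_latency <- function(cond) {
    D <- cond - baseline
    vapply(seq_len(n), function(i) {
      tt <- as.vector(perm_t_matrix(D[-i, , drop = FALSE],
                                    matrix(1, 1L, n - 1L)))
      largest_cluster_latency(tt, times, threshold_t)
    }, numeric(1))
  }
  lat_a <- loo_latency(condA)
  lat_b <- loo_latency(condB)
  ok <- is.finite(lat_a) & is.finite(lat_b)
  n_unstable <- sum(!ok)
  if (sum(ok) < 3L) stop("too many unstable jack-knife iterations")
  d <- lat_a[ok] - lat_b[ok]
  m <- length(d)
  obs <- mean(d)

  p_perm <- with_seed(seed + 1L, {
    signs <- matrix(sample(c(-1, 1), n_perm * m, replace = TRUE), n_perm, m)
    null_means <- as.vector(signs %*% d) / m
    (1 + sum(abs(null_means) >= abs(obs) - 1e-9)) / (1 + n_perm)
  })

  sd_d <- stats::sd(d)
  t_naive <- if (sd_d == 0) ifelse(obs == 0, 0, Inf * sign(obs)) else obs / (sd_d / sqrt(m))
  se_jack <- sqrt((m - 1) / m * sum((d - obs)^2))
  t_jack <- if (se_jack == 0) ifelse(obs == 0, 0, Inf * sign(obs)) else obs / se_jack
  p_naive <- 2 * stats::pt(-abs(t_naive), df = m - 1L)
  p_jack <- 2 * stats::pt(-abs(t_jack), df = m - 1L)

  structure(list(latency_a = mean(lat_a[ok]), latency_b = mean(lat_b[ok]),
                 delta_ms = obs, p_perm = p_perm,
                 t_jackknife = t_jack, p_jackknife = p_jack,
                 t_naive = t_naive, p_naive = p_naive,
                 latencies_a = lat_a, latencies_b = lat_b,
                 n_unstable = n_unstable, n = n, seed = seed,
                 n_perm = n_perm, threshold = threshold_t),
            class = "jackknife_latency")
}

#' @export
print.jackknife_latency <- function(x, ...) {
  cat(sprintf("<jackknife_latency> A: %.1f ms, B: %.1f ms, delta %.1f ms\n",
              x$latency_a, x$latency_b, x$delta_ms))
  cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$p_perm, x$n_perm))
  cat(sprintf("  jack-knife-corrected t = %.3f (p = %.3g); naive t = %.3f (p = %.3g)\n",
              x$t_jackknife, x$p_jackknife, x$t_naive, x$p_naive))
  if (x$n_unstable) cat("  unstable iterations dropped:", x$n_unstable, "\n")
  invisible(x)
}

# ---- 2-D clusters (cross-temporal matrices) -------------------------------

# connected-component labels of a logical matrix under 4-connectivity,
# by iterative label propagation (vectorized min over the four neighbors)
label_4conn <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(Inf, nr, nc)
  lab[mask] <- seq_len(sum(mask))
  if (!any(mask)) return(matrix(0L, nr, nc))
  repeat {
    up <- rbind(Inf, lab[-nr, , drop = FALSE])
    down <- rbind(lab[-1L, , drop = FALSE], Inf)
    left <- cbind(Inf, lab[, -nc, drop = FALSE])
    right <- cbind(lab[, -1L, drop = FALSE], Inf)
    new <- pmin(lab, up, down, left, right)
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, nr, nc)
  out[mask] <- as.integer(factor(lab[mask]))
  out
}

max_cluster_mass_2d <- function(t_cells, nr, threshold) {
  mask <- is.finite(t_cells) & (t_cells > threshold)
  if (!any(mask)) return(0)
  mm <- matrix(mask, nrow = nr)
  lab <- label_4conn(mm)
  max(rowsum(t_cells[mask], lab[mm]))
}

#' Cluster permutation test on cross-temporal matrices
#'
#' One-sample cluster test of participants' condition CTS matrices against
#' `mu`, with clusters formed from suprathreshold cells under
#' 4-connectivity, a max-cluster null from sign-flip permutations, and a
#' Bonferroni correction over the number of condition tests performed.
#'
#' @param matrices Participants x samples x samples array (or list of square
#'   matrices, one per participant).
#' @param times Time axis in ms (rows and columns of the matrices).
#' @param threshold_t Cluster-forming threshold.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed (mandatory).
#' @param alpha Significance level applied to the corrected p.
#' @param n_tests Bonferroni factor (default 4, one test per condition).
#' @param mu Null value (default 0).
#' @param block_size Permutations processed per block (memory control).
#' @return An object of class `cts_cluster_test` with a `clusters`
#'   data.frame (`mass`, `n_cells`, `max_t`, `max_t_row_ms`, `max_t_col_ms`,
#'   `p`, `p_bonferroni`, `significant`), the observed `t_matrix` and
#'   `labels`, and the configuration.
#' @export
cts_cluster_test <- function(matrices, times, threshold_t = 2.04,
                             n_perm = 1000L, seed, alpha = 0.05, n_tests = 4L,
                             mu = 0, block_size = 250L) {
  if (is.list(matrices)) {
    # list of one square matrix per participant -> participants x S x S
    matrices <- aperm(simplify2array(matrices), c(3L, 1L, 2L))
  }
  np <- dim(matrices)[1L]
  S <- dim(matrices)[2L]
  stopifnot(dim(matrices)[3L] == S, length(times) == S)
  if (n_perm < 100L) stop("n_perm below the floor of 100")
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (np < 3L) stop("need at least three participants")

  D <- matrix(matrices, nrow = np) - mu      # participants x cells
  t_obs <- as.vector(perm_t_matrix(D, matrix(1, 1L, np)))
  t_mat <- matrix(t_obs, S, S)
  mask <- is.finite(t_mat) & (t_mat > threshold_t)
  labels <- label_4conn(mask)

  null_max <- with_seed(seed, {
    out <- numeric(n_perm)
    done <- 0L
    while (done < n_perm) {
      nb <- min(block_size, n_perm - done)
      signs <- matrix(sample(c(-1, 1), nb * np, replace = TRUE), nb, np)
      T_perm <- perm_t_matrix(D, signs)
      out[done + seq_len(nb)] <- apply(T_perm, 1L, max_cluster_mass_2d,
                                       nr = S, threshold = threshold_t)
      done <- done + nb
    }
    out
  })

  k <- max(labels)
  if (k > 0L) {
    rows <- lapply(seq_len(k), function(l) {
      cells <- which(labels == l, arr.ind = TRUE)
      tt <- t_mat[labels == l]
      # earliest tie-break: order cells by row then column
      ord <- order(cells[, 1L], cells[, 2L])
      cells <- cells[ord, , drop = FALSE]
      tt <- tt[ord]
      peak <- which.max(tt)
      mass <- sum(tt)
      p <- (1 + sum(null_max >= mass - 1e-9)) / (1 + n_perm)
      data.frame(mass = mass, n_cells = length(tt), max_t = tt[peak],
                 max_t_row_ms = times[cells[peak, 1L]],
                 max_t_col_ms = times[cells[peak, 2L]],
                 p = p, p_bonferroni = min(1, p * n_tests))
    })
    clusters <- do.call(rbind, rows)
    clusters$significant <- clusters$p_bonferroni <= alpha
    clusters <- clusters[order(-clusters$mass), , drop = FALSE]
    rownames(clusters) <- NULL
  } else {
    clusters <- data.frame(mass = numeric(0), n_cells = integer(0),
                           max_t = numeric(0), max_t_row_ms = numeric(0),
                           max_t_col_ms = numeric(0), p = numeric(0),
                           p_bonferroni = numeric(0), significant = logical(0))
  }
  structure(list(clusters = clusters, t_matrix = t_mat, labels = labels,
                 times = times, threshold = threshold_t, n_perm = n_perm,
                 seed = seed, alpha = alpha, n_tests = n_tests,
                 null_max = null_max),
            class = "cts_cluster_test")
}

#' @export
print.cts_cluster_test <- function(x, ...) {
  cat(sprintf("<cts_cluster_test> threshold t=%.2f, %d permutations, Bonferroni x%d\n",
              x$threshold, x$n_perm, x$n_tests))
  if (!nrow(x$clusters)) cat("  no suprathreshold clusters\n") else print(x$clusters, digits = 4)
  invisible(x)
}
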