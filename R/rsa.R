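#' Pearson correlation of two spatial patterns
#'
#' Correlation across channels of two channel vectors taken at a single time
#' sample. A vector with zero variance has no pattern to correlate, so the
#' result is the missing marker `NA` (never silently 0).
#'
#' @param x,y Numeric vectors of equal length (>= 2 channels).
#' @return A number in \[-1, 1\], or `NA` on zero variance.
#' @export
spatial_pattern_correlation <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Time-resolved pairwise representational similarity
#'
#' For every unordered pair of trials and every time sample, the Pearson
#' correlation across channels of the two spatial patterns. The pair order
#' is lexicographic by sentence id, matching [build_predictor_table()], so a
#' similarity series and a predictor table align row by row through their
#' pair keys.
#'
#' @param epochs An [epochs_tensor()] with at least two trials.
#' @return An object of class `pair_similarity`: a list with `pairs` (a
#'   data.frame `sent_i`, `sent_j`), `values` (pairs x samples matrix of r,
#'   `NA` where a pattern had zero variance), `times`, `rate` and
#'   `participant`.
#' @export
pairwise_rsa_series <- function(epochs) {
  stopifnot(inherits(epochs, "epochs_tensor"))
  if (length(epochs$trials) < 2L) stop("need at least two trials")
  ord <- order(epochs$trials)
  ids <- epochs$trials[ord]
  pairs <- unordered_pairs(ids)
  n <- length(ids)
  ut <- upper.tri(matrix(0, n, n))
  # upper.tri runs column-major: (1,2), (1,3), (2,3), ... which is exactly
  # lexicographic (i, j) order on sorted ids transposed; reorder to row-major
  idx <- which(ut, arr.ind = TRUE)
  ord_pairs <- order(idx[, 1L], idx[, 2L])
  n_samples <- length(epochs$times)
  values <- matrix(NA_real_, nrow = nrow(pairs), ncol = n_samples)
  for (s in seq_len(n_samples)) {
    M <- epochs$data[ord, , s, drop = TRUE]   # trials x channels
    r <- suppressWarnings(stats::cor(t(M)))   # trials x trials over channels
    sds <- apply(M, 1L, stats::sd)
    r[sds == 0, ] <- NA_real_
    r[, sds == 0] <- NA_real_
    values[, s] <- r[ut][ord_pairs]
  }
  structure(list(pairs = pairs, values = values, times = epochs$times,
                 rate = epochs$rate, participant = epochs$participant),
            class = "pair_similarity")
}

#' @export
print.pair_similarity <- function(x, ...) {
  cat(sprintf("<pair_similarity> participant %s: %d pairs x %d samples (%g..%g ms)\n",
              x$participant, nrow(x$pairs), length(x$times),
              min(x$times), max(x$times)))
  n_na <- sum(is.na(x$values))
  if (n_na) cat("  ", n_na, " missing values (zero-variance patterns)\n", sep = "")
  invisible(x)
}

#' Export a similarity series as long-format TSV
#'
#' @param series A [pairwise_rsa_series()] result.
#' @param file Output path; columns `pair_id`, `time_ms`, `r`.
#' @export
write_pair_similarity <- function(series, file) {
  stopifnot(inherits(series, "pair_similarity"))
  long <- data.frame(
    pair_id = rep(paste(series$pairs$sent_i, series$pairs$sent_j, sep = ":"),
                  times = length(series$times)),
    time_ms = rep(series$times, each = nrow(series$pairs)),
    r = as.vector(series$values))
  utils::write.table(long, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
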