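#' Cross-temporal similarity matrix for one trial pair
#'
#' Cell (k, l) is the Pearson correlation across channels between trial i's
#' spatial pattern at time sample k and trial j's pattern at time sample l.
#' Rows index time in the first trial, columns time in the second; swapping
#' the trials transposes the matrix, so only unordered pairs need storing
#' with the orientation fixed by sentence-id order.
#'
#' @param trial_i,trial_j Numeric channels x samples matrices with the same
#'   shape.
#' @return A samples x samples matrix of correlations (`NA` where a pattern
#'   has zero variance).
#' @export
cts_matrix <- function(trial_i, trial_j) {
  stopifnot(is.matrix(trial_i), is.matrix(trial_j),
            all(dim(trial_i) == dim(trial_j)))
  if (nrow(trial_i) < 2L) stop("need at least two channels")
  m <- suppressWarnings(stats::cor(trial_i, trial_j))
  sd_i <- apply(trial_i, 2L, stats::sd)
  sd_j <- apply(trial_j, 2L, stats::sd)
  m[sd_i == 0, ] <- NA_real_
  m[, sd_j == 0] <- NA_real_
  unname(m)
}

#' Regression decomposition of cross-temporal similarity
#'
#' Streams over unordered trial pairs in batches, computing each pair's
#' cross-temporal similarity matrix and accumulating the per-cell normal
#' equations of the same three-regressor model as [rrsa()]. The full pairs x
#' samples x samples stack is never held in memory at once.
#'
#' Cells where any pair's correlation is undefined (zero-variance pattern)
#' are flagged missing rather than fitted on a shifting pair set.
#'
#' @param epochs An [epochs_tensor()] (typically already downsampled, e.g.
#'   to 300 Hz, before the quadratic-cost computation).
#' @param predictors A [build_predictor_table()] result.
#' @param batch_size Number of pairs per streamed batch.
#' @param min_pairs Minimum pairs required (as in [rrsa()]).
#' @return An object of class `rcts`: list with `coefficients` (4 x S x S
#'   array), `sigma2` (S x S), `times`, `rate`, `participant`, `n_pairs`.
#' @export
fit_rcts <- function(epochs, predictors, batch_size = 200L, min_pairs = 5L) {
  stopifnot(inherits(epochs, "epochs_tensor"))
  if (length(epochs$trials) < 2L) stop("need at least two trials")
  ord <- order(epochs$trials)
  ids <- epochs$trials[ord]
  pairs <- unordered_pairs(ids)
  keys_p <- pair_key(predictors$sent_i, predictors$sent_j)
  hit <- match(pair_key(pairs$sent_i, pairs$sent_j), keys_p)
  if (anyNA(hit)) stop("pairs missing from the predictor table")
  X <- cbind(intercept = 1,
             word_specific = predictors$word_specific[hit],
             semantic = predictors$semantic[hit],
             form = predictors$form[hit])
  n_pairs <- nrow(pairs)
  if (n_pairs < min_pairs) stop("need at least ", min_pairs, " pairs")
  S <- length(epochs$times)
  p <- ncol(X)

  XtX <- crossprod(X)
  if (qr(XtX)$rank < p) stop("rank-deficient design across pairs")
  XtY <- matrix(0, nrow = p, ncol = S * S)
  yty <- numeric(S * S)
  na_cell <- logical(S * S)

  pos <- match(ids, epochs$trials)  # tensor row per sorted trial
  row_i <- match(pairs$sent_i, ids)
  row_j <- match(pairs$sent_j, ids)
  for (start in seq(1L, n_pairs, by = batch_size)) {
    batch <- start:min(start + batch_size - 1L, n_pairs)
    for (b in batch) {
      ti <- epochs$data[pos[row_i[b]], , , drop = TRUE]  # channels x samples
      tj <- epochs$data[pos[row_j[b]], , , drop = TRUE]
      m <- as.vector(cts_matrix(ti, tj))
      bad <- !is.finite(m)
      if (any(bad)) { na_cell[bad] <- TRUE; m[bad] <- 0 }
      XtY <- XtY + tcrossprod(X[b, ], m)
      yty <- yty + m^2
    }
  }

  betas <- solve(XtX, XtY)                       # p x S^2
  rss <- yty - colSums(betas * XtY)              # b'X'y = sum(b * X'y) per cell
  rss[rss < 0] <- 0                              # guard tiny negatives
  sigma2 <- rss / (n_pairs - p)
  betas[, na_cell] <- NA_real_
  sigma2[na_cell] <- NA_real_

  structure(list(coefficients = array(betas, dim = c(p, S, S),
                                      dimnames = list(colnames(X), NULL, NULL)),
                 sigma2 = matrix(sigma2, S, S),
                 times = epochs$times, rate = epochs$rate,
                 participant = epochs$participant, n_pairs = n_pairs),
            class = "rcts")
}

#' Predicted condition matrices from a fitted rCTS model
#'
#' Applies the same configuration algebra as [predict.rrsa()] cell-wise:
#' Unrelated = \eqn{\beta_0}; Semantic = \eqn{\beta_0 + \beta_{Sem}}; Form =
#' \eqn{\beta_0 + \beta_{Form}}; Word-Specific = \eqn{\beta_0 + \beta_{WS} +
#' \beta_{Sem} + \beta_{Form}}.
#'
#' @param object An [fit_rcts()] result.
#' @param newdata Optional configuration rows as in [predict.rrsa()].
#' @param ... Unused.
#' @return A named list of samples x samples matrices, one per configuration.
#' @export
predict.rcts <- function(object, newdata = NULL, ...) {
  cfg <- if (is.null(newdata)) {
    condition_configurations()
  } else {
    as.matrix(as.data.frame(newdata)[c("word_specific", "semantic", "form")])
  }
  B <- object$coefficients
  out <- lapply(seq_len(nrow(cfg)), function(k) {
    B["intercept", , ] + cfg[k, 1L] * B["word_specific", , ] +
      cfg[k, 2L] * B["semantic", , ] + cfg[k, 3L] * B["form", , ]
  })
  names(out) <- rownames(cfg)
  out
}

#' @export
print.rcts <- function(x, ...) {
  S <- length(x$times)
  cat(sprintf("<rcts> participant %s: %d x %d cells over %d pairs at %g Hz\n",
              x$participant, S, S, x$n_pairs, x$rate))
  invisible(x)
}

#' Export condition CTS matrices to long-format TSV
#'
#' @param matrices A named list of square matrices (see [predict.rcts()]).
#' @param times Time axis in ms.
#' @param file Output path; columns `condition`, `time_row_ms`,
#'   `time_col_ms`, `value`.
#' @export
write_condition_cts <- function(matrices, times, file) {
  S <- length(times)
  rows <- lapply(names(matrices), function(cd) {
    data.frame(condition = cd,
               time_row_ms = rep(times, times = S),
               time_col_ms = rep(times, each = S),
               value = as.vector(matrices[[cd]]))
  })
  utils::write.table(do.call(rbind, rows), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
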