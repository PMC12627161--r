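#' Regression-based RSA decomposition
#'
#' Fits, independently at every time sample, the ordinary least squares model
#'
#' \deqn{r \approx \beta_0 + \beta_{WS}\,\mathrm{WordSpecific}
#'       + \beta_{Sem}\,\mathrm{Semantic} + \beta_{Form}\,\mathrm{Form}
#'       + \varepsilon}
#'
#' across sentence pairs, where `r` is the pairwise spatial-pattern
#' correlation at that sample. This is the central model of the package: the
#' fitted object carries one set of betas per time sample and yields the four
#' predicted condition signals (Word-Specific, Semantic, Form, Unrelated)
#' through [predict.rrsa()].
#'
#' Pairs present in the similarity series are matched to predictor rows by
#' their unordered sentence-pair key; pairs missing from the series (e.g.
#' artifact-rejected epochs) are simply absent and the fit uses whatever
#' pairs survive. At samples where fewer than `min_pairs` finite values
#' remain, or where the surviving design is rank-deficient, the betas are
#' recorded as missing rather than extrapolated.
#'
#' @param similarity A [pairwise_rsa_series()] result (or a compatible list).
#' @param predictors A [build_predictor_table()] result covering every pair
#'   in `similarity`.
#' @param fisher_z If `TRUE`, correlations are Fisher z-transformed before
#'   fitting. Default `FALSE` (raw similarity is regressed).
#' @param min_pairs Minimum finite pairs required to fit a sample (default
#'   5 = number of coefficients + 1).
#' @return An object of class `rrsa` with components `coefficients` (samples
#'   x 4 matrix: intercept, word_specific, semantic, form), `sigma2`
#'   (residual variance per sample), `df.residual`, `n_pairs`, `times`,
#'   `participant`, plus the matched design kept for fitted values and
#'   residuals.
#' @seealso [predict.rrsa()], [condition_signals()], [grand_average()]
#' @export
rrsa <- function(similarity, predictors, fisher_z = FALSE, min_pairs = 5L) {
  stopifnot(inherits(similarity, "pair_similarity"),
            is.data.frame(predictors))
  keys_s <- pair_key(similarity$pairs$sent_i, similarity$pairs$sent_j)
  keys_p <- pair_key(predictors$sent_i, predictors$sent_j)
  hit <- match(keys_s, keys_p)
  if (anyNA(hit)) {
    stop(sum(is.na(hit)), " pairs in the similarity series are absent from ",
         "the predictor table")
  }
  X <- cbind(intercept = 1,
             word_specific = predictors$word_specific[hit],
             semantic = predictors$semantic[hit],
             form = predictors$form[hit])
  Y <- similarity$values
  if (fisher_z) Y <- atanh(pmin(pmax(Y, -1 + 1e-12), 1 - 1e-12))
  n_samples <- ncol(Y)
  p <- ncol(X)
  coefs <- matrix(NA_real_, nrow = n_samples, ncol = p,
                  dimnames = list(NULL, colnames(X)))
  sigma2 <- rep(NA_real_, n_samples)
  dfres <- rep(NA_real_, n_samples)
  n_pairs <- colSums(is.finite(Y))

  complete <- which(n_pairs == nrow(Y))
  if (length(complete)) {
    qr_x <- qr(X)
    if (qr_x$rank == p && nrow(Y) >= min_pairs) {
      b <- qr.coef(qr_x, Y[, complete, drop = FALSE])
      res <- Y[, complete, drop = FALSE] - X %*% b
      coefs[complete, ] <- t(b)
      dfres[complete] <- nrow(Y) - p
      sigma2[complete] <- colSums(res^2) / (nrow(Y) - p)
    } else {
      complete <- integer(0)  # fall through to per-sample handling
    }
  }
  partial <- setdiff(seq_len(n_samples), complete)
  for (s in partial) {
    ok <- is.finite(Y[, s])
    if (sum(ok) < min_pairs) next
    Xs <- X[ok, , drop = FALSE]
    qr_s <- qr(Xs)
    if (qr_s$rank < p) next  # rank-deficient design: flagged missing
    b <- qr.coef(qr_s, Y[ok, s])
    coefs[s, ] <- b
    dfres[s] <- sum(ok) - p
    sigma2[s] <- sum((Y[ok, s] - Xs %*% b)^2) / (sum(ok) - p)
  }

  structure(list(coefficients = coefs, sigma2 = sigma2, df.residual = dfres,
                 n_pairs = n_pairs, times = similarity$times,
                 participant = similarity$participant,
                 fisher_z = fisher_z, design = X, pair_keys = keys_s,
                 y = Y),
            class = "rrsa")
}

# canonical predictor configurations of the four conditions; identical words
# carry the maximum value 1 on all three predictors
condition_configurations <- function() {
  rbind(word_specific = c(1, 1, 1),
        semantic      = c(0, 1, 0),
        form          = c(0, 0, 1),
        unrelated     = c(0, 0, 0))
}

#' @export
coef.rrsa <- function(object, ...) object$coefficients

#' Predicted condition signals from a fitted rRSA model
#'
#' Evaluates the fitted per-sample model at predictor configurations. The
#' default configurations are the four canonical conditions: Unrelated
#' (0,0,0), Semantic (0,1,0), Form (0,0,1) and Word-Specific (1,1,1) —
#' identical words carry the maximum value on all three predictors.
#'
#' @param object An [rrsa()] fit.
#' @param newdata Optional data.frame/matrix with columns `word_specific`,
#'   `semantic`, `form`, one row per configuration to evaluate; rownames
#'   label the output columns.
#' @param ... Unused.
#' @return A samples x configurations matrix of predicted similarity.
#' @export
predict.rrsa <- function(object, newdata = NULL, ...) {
  cfg <- if (is.null(newdata)) {
    condition_configurations()
  } else {
    m <- as.matrix(as.data.frame(newdata)[c("word_specific", "semantic", "form")])
    rownames(m) <- rownames(newdata) %||% paste0("cfg", seq_len(nrow(m)))
    m
  }
  B <- object$coefficients
  out <- B[, "intercept"] + B[, c("word_specific", "semantic", "form"),
                              drop = FALSE] %*% t(cfg)
  colnames(out) <- rownames(cfg)
  out
}

#' Condition signals of one participant
#'
#' Convenience wrapper around [predict.rrsa()] returning a classed object
#' that [grand_average()] and the statistics layer consume.
#'
#' @param fit An [rrsa()] fit.
#' @return An object of class `condition_signals`: samples x 4 matrix plus
#'   `times` and `participant` attributes.
#' @export
condition_signals <- function(fit) {
  stopifnot(inherits(fit, "rrsa"))
  m <- predict(fit)
  structure(m, times = fit$times, participant = fit$participant,
            class = c("condition_signals", class(m)))
}

#' @export
fitted.rrsa <- function(object, ...) {
  object$design %*% t(object$coefficients)
}

#' @export
residuals.rrsa <- function(object, ...) {
  object$y - fitted(object)
}

#' Simulate similarity series from a fitted rRSA model
#'
#' Draws new pair x sample similarity values as fitted values plus Gaussian
#' noise with the per-sample residual standard deviation — a parametric
#' bootstrap of the similarity series under the fitted linear model.
#'
#' @param object An [rrsa()] fit.
#' @param nsim Number of simulated series.
#' @param seed RNG seed (mandatory for reproducibility).
#' @param ... Unused.
#' @return A list of `nsim` pairs x samples matrices.
#' @export
simulate.rrsa <- function(object, nsim = 1, seed, ...) {
  stopifnot(is_scalar_number(seed))
  mu <- fitted(object)
  sd_s <- sqrt(object$sigma2)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    noise <- matrix(stats::rnorm(length(mu)), nrow = nrow(mu))
    mu + sweep(noise, 2L, sd_s, `*`)
  }))
}

#' @export
print.rrsa <- function(x, ...) {
  fitted_n <- sum(is.finite(x$coefficients[, 1L]))
  cat(sprintf("<rrsa> participant %s: %d/%d samples fitted over %d pairs (%g..%g ms)\n",
              x$participant, fitted_n, length(x$times),
              max(x$n_pairs), min(x$times), max(x$times)))
  invisible(x)
}

#' @export
summary.rrsa <- function(object, ...) {
  B <- object$coefficients
  out <- list(participant = object$participant,
              n_samples = length(object$times),
              n_fitted = sum(is.finite(B[, 1L])),
              n_pairs = range(object$n_pairs),
              mean_beta = colMeans(B, na.rm = TRUE),
              mean_sigma = mean(sqrt(object$sigma2), na.rm = TRUE))
  class(out) <- "summary.rrsa"
  out
}

#' @export
print.summary.rrsa <- function(x, ...) {
  cat("Regression-based RSA fit, participant ", x$participant, "\n", sep = "")
  cat(sprintf("  samples fitted: %d of %d; pairs per sample: %d..%d\n",
              x$n_fitted, x$n_samples, x$n_pairs[1L], x$n_pairs[2L]))
  cat("  time-averaged coefficients:\n")
  print(round(x$mean_beta, 5))
  cat(sprintf("  mean residual sd: %.4f\n", x$mean_sigma))
  invisible(x)
}

#' @export
plot.rrsa <- function(x, ...) {
  sig <- condition_signals(x)
  cols <- c(word_specific = "purple", semantic = "red",
            form = "blue", unrelated = "grey40")
  graphics::matplot(attr(sig, "times"), unclass(sig), type = "l", lty = 1,
                    col = cols[colnames(sig)], xlab = "time (ms)",
                    ylab = "predicted similarity", ...)
  graphics::legend("topleft", legend = colnames(sig), col = cols[colnames(sig)],
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Grand average of condition signals across participants
#'
#' Pointwise mean of per-participant condition signals; samples missing for
#' a participant are excluded from the mean at that sample.
#'
#' @param signals A list of [condition_signals()] objects with identical
#'   time axes.
#' @return A samples x conditions matrix with attributes `times` and `n`
#'   (participant count).
#' @export
grand_average <- function(signals) {
  stopifnot(length(signals) >= 1L)
  times <- attr(signals[[1L]], "times")
  for (s in signals) {
    if (!isTRUE(all.equal(attr(s, "times"), times))) {
      stop("mismatched time axes across participants")
    }
  }
  arr <- simplify2array(lapply(signals, unclass))   # samples x cond x part
  avg <- apply(arr, c(1L, 2L), mean, na.rm = TRUE)
  avg[!is.finite(avg)] <- NA_real_
  structure(avg, times = times, n = length(signals))
}
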