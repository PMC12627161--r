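# Independent oracles, kept deliberately naive: each recomputes a quantity
# from its textbook definition, sharing no code with the package internals.

# full dynamic-programming edit-distance lattice
dp_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1L] <- 0:n
  d[1L, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1L, j + 1L] <- min(d[i, j + 1L] + 1L,
                             d[i + 1L, j] + 1L,
                             d[i, j] + (ca[i] != cb[j]))
  }
  d[n + 1L, m + 1L]
}

# Pearson r from the definition: covariance over the product of sds
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  num <- sum((x - mx) * (y - my))
  num / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# VIF by explicit normal equations: regress column k on the others
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(k) {
    Z <- cbind(1, X[, -k, drop = FALSE])
    y <- X[, k]
    beta <- solve(t(Z) %*% Z, t(Z) %*% y)
    rss <- sum((y - Z %*% beta)^2)
    tss <- sum((y - mean(y))^2)
    1 / (rss / tss)
  }, numeric(1))
}

# Benjamini-Yekutieli by hand: step-up with the harmonic-number factor
by_oracle <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ranked <- p[o] * m * cm / seq_len(m)
  adj <- rev(cummin(rev(ranked)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# toy taxonomy used across tests: entity{animal{dog:2, cat:2}, artifact{car:4}}
toy_taxonomy <- function() {
  taxonomy(child = c("animal", "artifact", "dog", "cat", "car"),
           parent = c("entity", "entity", "animal", "animal", "artifact"),
           own_count = c(0, 0, 2, 2, 4),
           word_map = c(dog = "dog", cat = "cat", car = "car"))
}

# noise-free similarity series generated directly from the rRSA linear model
model_series <- function(table, betas, times, participant = "sim") {
  X <- cbind(1, table$word_specific, table$semantic, table$form)
  y <- as.vector(X %*% betas)
  structure(list(pairs = data.frame(sent_i = table$sent_i,
                                    sent_j = table$sent_j),
                 values = matrix(y, nrow = nrow(table), ncol = length(times)),
                 times = times, rate = 1000, participant = participant),
            class = "pair_similarity")
}

random_word <- function(max_len = 12L) {
  paste0(sample(letters[1:6], sample.int(max_len + 1L, 1L) - 1L,
                replace = TRUE), collapse = "")
}
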