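# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# All unordered pairs of `ids`, lexicographically ordered: ids are sorted,
# then pairs enumerated (i, j) with i < j. This single helper fixes the pair
# order used by the predictor table and every similarity series, so rows
# align by construction.
unordered_pairs <- function(ids) {
  ids <- sort(unique(as.character(ids)))
  n <- length(ids)
  if (n < 2L) stop("need at least two ids to form pairs")
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
  data.frame(sent_i = ids[idx[, 1L]], sent_j = ids[idx[, 2L]],
             stringsAsFactors = FALSE)
}

pair_key <- function(i, j) paste(i, j, sep = "\r")

`%||%` <- function(a, b) if (is.null(a)) b else a

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Greatest common divisor, for rational resampling ratios.
gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 1e-9) { t <- b; b <- a %% b; a <- t }
  a
}
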