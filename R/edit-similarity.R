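#' Levenshtein edit distance
#'
#' Minimum number of single-character substitutions, insertions and deletions
#' transforming one string into another, with unit cost for every edit.
#' Vectorized over pairs of strings (arguments are recycled).
#'
#' @param a,b Character vectors. Empty strings are legal.
#' @return Integer vector of edit distances.
#' @examples
#' levenshtein_distance("dog", "doll")  # 2
#' levenshtein_distance("", "ab")       # 2
#' @export
levenshtein_distance <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (anyNA(a) || anyNA(b)) stop("NA strings are not allowed")
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  d <- integer(n)
  for (k in seq_len(n)) {
    d[k] <- as.integer(utils::adist(a[k], b[k],
                                    costs = list(ins = 1, del = 1, sub = 1))[1L, 1L])
  }
  d
}

#' Normalized edit similarity
#'
#' Length-normalized complement of the Levenshtein distance: with distance
#' \eqn{d} between strings of lengths \eqn{|a|} and \eqn{|b|} and unit edit
#' weights, the similarity is \eqn{1 - 2d / (|a| + |b| + d)}. It equals 1
#' exactly when the strings are identical (two empty strings included, by the
#' identity clause) and 0 when they share no characters; it is symmetric.
#'
#' @inheritParams levenshtein_distance
#' @return Numeric vector of similarities in \[0, 1\].
#' @examples
#' normalized_edit_similarity("cat", "cat")  # 1
#' normalized_edit_similarity("a", "b")      # 1/3
#' @export
normalized_edit_similarity <- function(a, b) {
  d <- levenshtein_distance(a, b)
  n <- max(length(a), length(b))
  len <- nchar(rep_len(as.character(a), n)) + nchar(rep_len(as.character(b), n))
  ifelse(len + d == 0, 1, 1 - 2 * d / (len + d))
}
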