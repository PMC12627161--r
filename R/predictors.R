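#' Sentence lexicon
#'
#' A table of sentences and the single word each sentence makes highly
#' predictable (its expected final word). Sentence ids must be unique and
#' expected words non-empty.
#'
#' @param sentences A data.frame with columns `sentence_id` and
#'   `expected_word`.
#' @return An object of class `lexicon` (a validated data.frame).
#' @export
lexicon <- function(sentences) {
  stopifnot(is.data.frame(sentences),
            all(c("sentence_id", "expected_word") %in% names(sentences)))
  sentences$sentence_id <- as.character(sentences$sentence_id)
  sentences$expected_word <- as.character(sentences$expected_word)
  if (anyDuplicated(sentences$sentence_id)) stop("duplicate sentence ids")
  if (any(is.na(sentences$expected_word) | !nzchar(sentences$expected_word))) {
    stop("every sentence needs a non-empty expected word")
  }
  sentences <- sentences[order(sentences$sentence_id), , drop = FALSE]
  rownames(sentences) <- NULL
  class(sentences) <- c("lexicon", "data.frame")
  sentences
}

#' @rdname lexicon
#' @param file Path to a TSV with columns `sentence_id`, `expected_word`.
#' @export
read_lexicon <- function(file) {
  lexicon(utils::read.delim(file, stringsAsFactors = FALSE,
                            colClasses = "character"))
}

#' @rdname lexicon
#' @param lex A `lexicon`.
#' @export
write_lexicon <- function(lex, file) {
  utils::write.table(as.data.frame(lex), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

# Canonical word key: lowercase + Unicode NFC. Accents are significant
# (Spanish orthography), so they are normalized but never stripped.
normalize_word <- function(w) stringi::stri_trans_nfc(tolower(w))

#' Build the pairwise predictor table
#'
#' For every unordered pair of sentences, three regressors describing the
#' relation between their expected words: `word_specific` (1 if the words
#' are identical, 0 otherwise), `semantic` (Lin similarity in \[0, 1\]) and
#' `form` (normalized edit similarity in \[0, 1\]). Word identity is exact
#' string equality after lowercasing and Unicode NFC normalization.
#'
#' @param lex A [lexicon()].
#' @param semantic_source Either a [taxonomy()] (Lin similarity is computed
#'   internally) or a symmetric numeric matrix with the distinct expected
#'   words as dimnames (a precomputed similarity matrix).
#' @return A data.frame of class `predictor_table` with one row per unordered
#'   pair: `pair_id`, `sent_i`, `sent_j`, `word_specific`, `semantic`,
#'   `form`. For `n` sentences there are exactly `n (n - 1) / 2` rows,
#'   ordered lexicographically by sentence id.
#' @export
build_predictor_table <- function(lex, semantic_source) {
  stopifnot(inherits(lex, "lexicon"))
  if (nrow(lex) < 2L) stop("need at least two sentences")
  pairs <- unordered_pairs(lex$sentence_id)
  word_of <- stats::setNames(normalize_word(lex$expected_word), lex$sentence_id)
  words <- sort(unique(unname(word_of)))

  sem_mat <- semantic_matrix(words, semantic_source)

  # word-level form similarity, computed once per distinct word pair
  form_mat <- diag(1, length(words))
  dimnames(form_mat) <- list(words, words)
  if (length(words) > 1L) {
    wp <- utils::combn(words, 2L)
    fs <- normalized_edit_similarity(wp[1L, ], wp[2L, ])
    form_mat[cbind(wp[1L, ], wp[2L, ])] <- fs
    form_mat[cbind(wp[2L, ], wp[1L, ])] <- fs
  }

  wi <- word_of[pairs$sent_i]
  wj <- word_of[pairs$sent_j]
  out <- data.frame(
    pair_id = paste(pairs$sent_i, pairs$sent_j, sep = ":"),
    sent_i = pairs$sent_i,
    sent_j = pairs$sent_j,
    word_specific = as.integer(wi == wj),
    semantic = sem_mat[cbind(wi, wj)],
    form = form_mat[cbind(wi, wj)],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  stopifnot(all(out$semantic >= -1e-12 & out$semantic <= 1 + 1e-12),
            all(out$form >= -1e-12 & out$form <= 1 + 1e-12))
  class(out) <- c("predictor_table", "data.frame")
  out
}

semantic_matrix <- function(words, semantic_source) {
  n <- length(words)
  if (inherits(semantic_source, "taxonomy")) {
    mat <- diag(1, n)
    dimnames(mat) <- list(words, words)
    if (n > 1L) {
      for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
        s <- lin_similarity(words[i], words[j], semantic_source)
        mat[i, j] <- s; mat[j, i] <- s
      }
    }
    return(mat)
  }
  if (is.matrix(semantic_source)) {
    missing <- setdiff(words, rownames(semantic_source))
    if (length(missing)) {
      stop("semantic matrix lacks words: ", paste(missing, collapse = ", "))
    }
    mat <- semantic_source[words, words, drop = FALSE]
    if (max(abs(mat - t(mat))) > 1e-8) stop("semantic matrix must be symmetric")
    return(mat)
  }
  stop("semantic_source must be a taxonomy or a named similarity matrix")
}

#' @rdname build_predictor_table
#' @param table A `predictor_table`.
#' @param file Output TSV path (similarities written at 6 decimals).
#' @export
write_predictor_table <- function(table, file) {
  out <- as.data.frame(table)
  out$semantic <- sprintf("%.6f", out$semantic)
  out$form <- sprintf("%.6f", out$form)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname build_predictor_table
#' @export
read_predictor_table <- function(file) {
  out <- utils::read.delim(file, stringsAsFactors = FALSE,
                           colClasses = c(sent_i = "character",
                                          sent_j = "character"))
  class(out) <- c("predictor_table", "data.frame")
  out
}

#' Variance inflation factors of the three regressors
#'
#' For each predictor, \eqn{VIF = 1 / (1 - R^2)} where \eqn{R^2} comes from
#' regressing that predictor on the other two (with intercept). Values are
#' at least 1; a perfectly collinear predictor is reported as `Inf` with a
#' warning rather than silently capped.
#'
#' @param table A [build_predictor_table()] result (or any data.frame with
#'   columns `word_specific`, `semantic`, `form`).
#' @return Named numeric vector of three VIFs.
#' @export
variance_inflation_factors <- function(table) {
  vars <- c("word_specific", "semantic", "form")
  stopifnot(all(vars %in% names(table)), nrow(table) >= 4L)
  X <- as.matrix(as.data.frame(table)[vars])
  if (any(apply(X, 2L, stats::var) == 0)) {
    stop("each predictor needs nonzero variance for a VIF")
  }
  out <- stats::setNames(numeric(3L), vars)
  for (k in seq_along(vars)) {
    fit <- stats::lm.fit(cbind(1, X[, -k, drop = FALSE]), X[, k])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, k] - mean(X[, k]))^2)
    out[k] <- if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  if (any(!is.finite(out))) {
    warning("perfect collinearity: ",
            paste(vars[!is.finite(out)], collapse = ", "))
  }
  out
}
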