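#' Synthetic lexicon with planted form and semantic structure
#'
#' Generates `n_words` pseudo-words grouped two ways: into form families
#' (words sharing a stem, hence high normalized edit similarity) and into
#' taxonomy branches (words under a common parent node, hence high Lin
#' similarity). The two groupings cross-cut each other (a seeded permutation
#' decouples them) so the form and semantic predictors stay distinguishable.
#' Each word is the expected final word of `n_sentences_per_word` sentences.
#'
#' @param n_words Number of distinct words (>= 2).
#' @param n_sentences_per_word Sentences per word (the motivating design
#'   used two highly constraining sentence frames per word).
#' @param form_family_size Words per shared-stem family.
#' @param semantic_family_size Words per taxonomy branch.
#' @param seed RNG seed; the same seed reproduces the same lexicon.
#' @return A list with `lexicon` (a [lexicon()]), `taxonomy` (a
#'   [taxonomy()] whose word map covers all words), `words`, and the two
#'   family assignments.
#' @export
make_lexicon <- function(n_words = 12L, n_sentences_per_word = 2L,
                         form_family_size = 3L, semantic_family_size = 3L,
                         seed = 1L) {
  stopifnot(n_words >= 2L, n_sentences_per_word >= 1L,
            form_family_size >= 1L, semantic_family_size >= 1L)
  with_seed(seed, {
    n_fam <- ceiling(n_words / form_family_size)
    stems <- character(0)
    while (length(unique(stems)) < n_fam) {
      stems <- unique(c(stems, paste0(
        sample(letters, 5L, replace = TRUE), collapse = "")))
    }
    stems <- stems[seq_len(n_fam)]
    form_family <- rep(seq_len(n_fam), each = form_family_size)[seq_len(n_words)]
    words <- character(n_words)
    for (f in seq_len(n_fam)) {
      members <- which(form_family == f)
      words[members] <- paste0(stems[f], letters[seq_along(members)])
    }
    stopifnot(!anyDuplicated(words))

    # semantic branches on a permuted word order, decoupled from form
    n_branch <- ceiling(n_words / semantic_family_size)
    perm <- sample(n_words)
    semantic_family <- integer(n_words)
    semantic_family[perm] <- rep(seq_len(n_branch),
                                 each = semantic_family_size)[seq_len(n_words)]
    branches <- sprintf("branch%02d", seq_len(n_branch))
    tax <- taxonomy(
      child = c(branches, words),
      parent = c(rep("entity", n_branch), branches[semantic_family]),
      own_count = c(rep(0, n_branch), rep(2, n_words)),
      word_map = stats::setNames(words, words))

    sent_ids <- sprintf("s%04d", seq_len(n_words * n_sentences_per_word))
    lex <- lexicon(data.frame(
      sentence_id = sent_ids,
      expected_word = rep(words, each = n_sentences_per_word)))
    list(lexicon = lex, taxonomy = tax, words = words,
         form_family = form_family, semantic_family = semantic_family,
         seed = seed)
  })
}

#' Planted effect schedule
#'
#' Which representational effect is active when, and how strongly. Each
#' effect occupies a latency window (ms) and has an amplitude expressed as a
#' pattern-share fraction: the proportion of the clean signal taken from the
#' shared (family or word) pattern at the window's peak, the rest staying
#' with the sentence-unique pattern. Activation follows a raised-cosine
#' profile inside the window (zero at the edges, maximal at the center), so
#' the peak latencies are well defined. The default windows plant a
#' semantic-before-form-before-word-specific ordering.
#'
#' @param semantic,form,word_specific Length-2 windows `c(start_ms, end_ms)`.
#' @param amplitudes Named pattern-share fractions in \[0, 1\].
#' @export
effect_schedule <- function(semantic = c(-672, -657),
                            form = c(-650, -644),
                            word_specific = c(-650, -614),
                            amplitudes = c(semantic = 0.6, form = 0.55,
                                           word_specific = 0.7)) {
  wins <- list(semantic = semantic, form = form, word_specific = word_specific)
  for (nm in names(wins)) {
    w <- wins[[nm]]
    if (!is.null(w)) stopifnot(length(w) == 2L, w[1L] < w[2L])
  }
  stopifnot(all(amplitudes >= 0 & amplitudes <= 1))
  structure(list(windows = wins, amplitudes = amplitudes),
            class = "effect_schedule")
}

# raised-cosine activation profile inside [start, end], zero outside
activation_profile <- function(times, window) {
  if (is.null(window)) return(numeric(length(times)))
  h <- numeric(length(times))
  inside <- times >= window[1L] & times <= window[2L]
  h[inside] <- sin(pi * (times[inside] - window[1L]) /
                     (window[2L] - window[1L]))^2
  h
}

#' Ground truth for an epoch simulation
#'
#' Draws the spatial patterns that the simulation plants: one unique pattern
#' per sentence, one per word, one per semantic branch and one per form
#' family. Patterns are zero-mean unit-norm channel vectors; with
#' `orthonormal = TRUE` they are mutually orthogonal (possible only when
#' their total count is below the channel count), which makes pairwise
#' correlations exactly zero outside planted windows — useful for exactness
#' tests.
#'
#' @param lexinfo A [make_lexicon()] result.
#' @param schedule An [effect_schedule()].
#' @param channels Number of scalp channels.
#' @param noise_sd Standard deviation of the additive sensor noise
#'   (microvolt-scale units; white Gaussian by default).
#' @param signal_scale Multiplier applied to the clean pattern signal.
#' @param seed RNG seed.
#' @param orthonormal Draw mutually orthogonal patterns (see above).
#' @param noise_model `"white"` (default) or `"pink"` (1/f-shaped).
#' @export
ground_truth <- function(lexinfo, schedule = effect_schedule(), channels = 34L,
                         noise_sd = 1, signal_scale = 2, seed = 1L,
                         orthonormal = FALSE,
                         noise_model = c("white", "pink")) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(schedule, "effect_schedule"), channels >= 2L,
            noise_sd >= 0, signal_scale > 0)
  lex <- lexinfo$lexicon
  n_sent <- nrow(lex)
  n_words <- length(lexinfo$words)
  n_sem <- max(lexinfo$semantic_family)
  n_form <- max(lexinfo$form_family)
  k <- n_sent + n_words + n_sem + n_form
  pats <- with_seed(seed, {
    if (orthonormal) {
      if (k > channels - 1L) {
        stop("orthonormal patterns need at most channels-1 = ", channels - 1L,
             " patterns, got ", k)
      }
      q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(channels * k), channels))))
      q[, -1L, drop = FALSE][, seq_len(k), drop = FALSE]
    } else {
      m <- matrix(stats::rnorm(channels * k), channels)
      m <- sweep(m, 2L, colMeans(m))            # zero-mean per pattern
      sweep(m, 2L, sqrt(colSums(m^2)), `/`)     # unit norm
    }
  })
  idx <- list(sentence = seq_len(n_sent),
              word = n_sent + seq_len(n_words),
              semantic = n_sent + n_words + seq_len(n_sem),
              form = n_sent + n_words + n_sem + seq_len(n_form))
  structure(list(lexinfo = lexinfo, schedule = schedule, channels = channels,
                 noise_sd = noise_sd, signal_scale = signal_scale,
                 seed = seed, orthonormal = orthonormal,
                 noise_model = noise_model, patterns = pats, index = idx),
            class = "rrsa_ground_truth")
}

#' @export
print.rrsa_ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d sentences, %d channels, noise sd %g, scale %g, seed %d\n",
              nrow(x$lexinfo$lexicon), x$channels, x$noise_sd,
              x$signal_scale, x$seed))
  invisible(x)
}

pink_noise <- function(n) {
  # 1/f-shaped Gaussian noise via spectral weighting, unit variance
  white <- stats::rnorm(n)
  spec <- stats::fft(white)
  f <- c(1, seq_len(n - 1L))
  f <- pmin(f, n - f + 1)             # symmetric frequency index
  shaped <- Re(stats::fft(spec / sqrt(f), inverse = TRUE)) / n
  shaped / stats::sd(shaped)
}

#' Simulate multichannel epochs with planted representational structure
#'
#' Each trial's spatial pattern at time `t` is a convex mixture of its
#' sentence-unique pattern with the shared patterns scheduled at `t`: the
#' semantic-branch pattern inside the semantic window, the form-family
#' pattern inside the form window, and the word pattern (shared only by
#' sentences expecting the same word) inside the word-specific window —
#' plus additive sensor noise. Pattern correlations therefore rise above
#' baseline exactly for the pair relations and latencies the schedule
#' plants. Every participant's patterns are rotated by a random orthogonal
#' map within the zero-mean channel subspace, so patterns differ across
#' participants while the planted correlation structure is preserved and
#' group statistics remain honest.
#'
#' @param truth A [ground_truth()].
#' @param n_participants Number of simulated participants.
#' @param rate Sampling rate in Hz.
#' @param t_start,t_end Epoch limits in ms; samples cover the half-open
#'   interval (800 samples for -800..0 at 1,000 Hz).
#' @param seed RNG seed.
#' @return A list of [epochs_tensor()] objects, one per participant.
#' @export
simulate_epochs <- function(truth, n_participants = 24L, rate = 1000,
                            t_start = -800, t_end = 0, seed = 1L) {
  stopifnot(inherits(truth, "rrsa_ground_truth"), n_participants >= 1L)
  lexinfo <- truth$lexinfo
  lex <- lexinfo$lexicon
  step <- 1000 / rate
  times <- seq(t_start, t_end - step, by = step)
  S <- length(times)
  sch <- truth$schedule
  for (w in sch$windows) {
    if (!is.null(w) && (w[1L] < t_start || w[2L] > t_end)) {
      stop("schedule window outside the epoch")
    }
  }
  amp <- sch$amplitudes
  h_sem <- amp[["semantic"]] * activation_profile(times, sch$windows$semantic)
  h_form <- amp[["form"]] * activation_profile(times, sch$windows$form)
  h_ws <- amp[["word_specific"]] *
    activation_profile(times, sch$windows$word_specific)
  h_unique <- 1 - h_sem - h_form - h_ws
  if (any(h_unique < 0)) {
    stop("overlapping effect amplitudes exceed 1; reduce pattern shares")
  }

  C <- truth$channels
  word_idx <- match(lex$expected_word, lexinfo$words)
  # per-trial weight rows are identical across trials; stack the four
  # pattern weights as a 4 x samples matrix once
  W <- rbind(unique = h_unique, sem = h_sem, form = h_form, ws = h_ws)

  # basis of the zero-mean subspace, for participant-specific rotations
  B <- qr.Q(qr(cbind(1, diag(C))))[, -1L, drop = FALSE]

  with_seed(seed, lapply(seq_len(n_participants), function(pp) {
    R <- qr.Q(qr(matrix(stats::rnorm((C - 1L)^2), C - 1L)))
    rot <- B %*% R %*% t(B)
    P <- rot %*% truth$patterns
    data <- array(0, dim = c(nrow(lex), C, S))
    for (tr in seq_len(nrow(lex))) {
      w <- word_idx[tr]
      pat4 <- P[, c(truth$index$sentence[tr],
                    truth$index$semantic[lexinfo$semantic_family[w]],
                    truth$index$form[lexinfo$form_family[w]],
                    truth$index$word[w])]
      # order must match W rows: unique, sem, form, ws
      clean <- truth$signal_scale * (pat4 %*% W)
      noise <- if (truth$noise_sd == 0) {
        0
      } else if (truth$noise_model == "white") {
        matrix(stats::rnorm(C * S, sd = truth$noise_sd), C, S)
      } else {
        truth$noise_sd * t(vapply(seq_len(C), function(ch) pink_noise(S),
                                  numeric(S)))
      }
      data[tr, , ] <- clean + noise
    }
    if (!all(is.finite(data))) stop("simulation produced non-finite values")
    epochs_tensor(data, times, rate, sprintf("p%02d", pp), lex$sentence_id)
  }))
}

#' Machine-readable ground-truth report
#'
#' Serializes the planted windows, amplitudes, noise level and seeds so
#' downstream tests can assert against them.
#'
#' @param truth A [ground_truth()].
#' @param path Optional JSON output path.
#' @return The report list, invisibly when written to `path`.
#' @export
planted_truth_report <- function(truth, path = NULL) {
  stopifnot(inherits(truth, "rrsa_ground_truth"))
  sch <- truth$schedule
  effects <- lapply(names(sch$windows), function(nm) {
    w <- sch$windows[[nm]]
    if (is.null(w)) return(NULL)
    list(effect = nm, start_ms = w[1L], end_ms = w[2L],
         amplitude = unname(sch$amplitudes[[nm]]))
  })
  effects <- Filter(Negate(is.null), effects)
  report <- list(effects = effects, noise_sd = truth$noise_sd,
                 signal_scale = truth$signal_scale,
                 channels = truth$channels, noise_model = truth$noise_model,
                 pattern_seed = truth$seed,
                 lexicon_seed = truth$lexinfo$seed,
                 n_words = length(truth$lexinfo$words),
                 n_sentences = nrow(truth$lexinfo$lexicon))
  if (!is.null(path)) {
    jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
    return(invisible(report))
  }
  report
}

#' @rdname planted_truth_report
#' @export
read_truth_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' Simulate a complete study
#'
#' Convenience recipe binding [make_lexicon()], [ground_truth()] and
#' [simulate_epochs()] with the package's default study conditions: a
#' 12-word / 24-sentence lexicon, 34 channels at 1,000 Hz over -800..0 ms,
#' 24 participants, and the default [effect_schedule()] planting semantic,
#' then form, then word-specific effects.
#'
#' @param n_participants Number of participants.
#' @param seed Single seed from which lexicon, pattern and epoch seeds are
#'   derived.
#' @param ... Passed on to [ground_truth()] (e.g. `noise_sd`) — plus
#'   `n_words`, `n_sentences_per_word` forwarded to [make_lexicon()] and
#'   `schedule`.
#' @param n_words,n_sentences_per_word Lexicon size.
#' @param schedule An [effect_schedule()].
#' @param rate,t_start,t_end Epoch grid.
#' @return A list with `lexinfo`, `truth`, `epochs` (list of tensors) and
#'   `predictors` (the matching predictor table).
#' @export
simulate_study <- function(n_participants = 24L, seed = 1L, n_words = 12L,
                           n_sentences_per_word = 2L,
                           schedule = effect_schedule(), rate = 1000,
                           t_start = -800, t_end = 0, ...) {
  lexinfo <- make_lexicon(n_words = n_words,
                          n_sentences_per_word = n_sentences_per_word,
                          seed = seed)
  truth <- ground_truth(lexinfo, schedule = schedule, seed = seed + 1L, ...)
  epochs <- simulate_epochs(truth, n_participants = n_participants,
                            rate = rate, t_start = t_start, t_end = t_end,
                            seed = seed + 2L)
  predictors <- build_predictor_table(lexinfo$lexicon, lexinfo$taxonomy)
  list(lexinfo = lexinfo, truth = truth, epochs = epochs,
       predictors = predictors)
}

#' Write a simulated dataset to disk
#'
#' Writes the epochs container, the lexicon TSV, the taxonomy edge list and
#' word map, and the ground-truth JSON — everything a pipeline run needs.
#'
#' @param study A [simulate_study()] result.
#' @param dir Output directory.
#' @export
write_synthetic_dataset <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_epochs(study$epochs, file.path(dir, "epochs"))
  write_lexicon(study$lexinfo$lexicon, file.path(dir, "lexicon.tsv"))
  write_taxonomy(study$lexinfo$taxonomy, file.path(dir, "taxonomy.tsv"),
                 file.path(dir, "word_map.tsv"))
  planted_truth_report(study$truth, file.path(dir, "ground_truth.json"))
  invisible(dir)
}
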