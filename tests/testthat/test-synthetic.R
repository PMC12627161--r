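test_that("lexicon generation is deterministic and correctly sized", {
  lx <- make_lexicon(n_words = 2, n_sentences_per_word = 1,
                     form_family_size = 1, semantic_family_size = 1, seed = 1)
  expect_identical(nrow(lx$lexicon), 2L)
  tab <- build_predictor_table(lx$lexicon, lx$taxonomy)
  expect_identical(nrow(tab), 1L)

  a <- make_lexicon(n_words = 10, seed = 42)
  b <- make_lexicon(n_words = 10, seed = 42)
  expect_identical(a$lexicon, b$lexicon)
  expect_identical(a$words, b$words)
  c <- make_lexicon(n_words = 10, seed = 43)
  expect_false(identical(a$words, c$words))
})

test_that("form families share stems and taxonomy branches raise Lin scores", {
  lx <- make_lexicon(n_words = 12, seed = 7)
  same_form <- outer(lx$form_family, lx$form_family, `==`)
  same_sem <- outer(lx$semantic_family, lx$semantic_family, `==`)
  form_sim <- outer(seq_along(lx$words), seq_along(lx$words),
                    Vectorize(function(i, j) {
                      normalized_edit_similarity(lx$words[i], lx$words[j])
                    }))
  sem_sim <- outer(seq_along(lx$words), seq_along(lx$words),
                   Vectorize(function(i, j) {
                     lin_similarity(lx$words[i], lx$words[j], lx$taxonomy)
                   }))
  off <- !diag(12)
  expect_gt(mean(form_sim[same_form & off]), mean(form_sim[!same_form]) + 0.3)
  expect_gt(mean(sem_sim[same_sem & off]), 0.4)
  expect_equal(max(sem_sim[!same_sem]), 0)
})

test_that("ground-truth reports round-trip and track their seeds", {
  lx <- make_lexicon(n_words = 6, seed = 2)
  tr <- ground_truth(lx, seed = 5)
  f <- tempfile(fileext = ".json")
  planted_truth_report(tr, f)
  back <- read_truth_report(f)
  expect_identical(back$pattern_seed, 5L)
  expect_identical(length(back$effects), 3L)
  expect_equal(back$effects[[1]]$start_ms, -672)
  tr2 <- ground_truth(lx, seed = 6)
  f2 <- tempfile(fileext = ".json")
  planted_truth_report(tr2, f2)
  expect_false(identical(readLines(f), readLines(f2)))
  # an empty schedule yields an empty effect list
  empty <- effect_schedule(semantic = NULL, form = NULL, word_specific = NULL)
  tr3 <- ground_truth(lx, schedule = empty, seed = 7)
  expect_identical(length(planted_truth_report(tr3)$effects), 0L)
})

test_that("identical-word trials correlate perfectly at a full-share peak", {
  lx <- make_lexicon(n_words = 4, seed = 3)
  sch <- effect_schedule(semantic = NULL, form = NULL,
                         word_specific = c(-650, -614),
                         amplitudes = c(semantic = 0, form = 0,
                                        word_specific = 1))
  tr <- ground_truth(lx, sch, noise_sd = 0, seed = 4, orthonormal = TRUE)
  ep <- simulate_epochs(tr, n_participants = 1, seed = 5)[[1]]
  ser <- pairwise_rsa_series(ep)
  tab <- build_predictor_table(lx$lexicon, lx$taxonomy)
  key <- paste(tab$sent_i, tab$sent_j)
  ws <- tab$word_specific[match(paste(ser$pairs$sent_i, ser$pairs$sent_j), key)]
  peak <- which(ep$times == -632)      # raised-cosine maximum of the window
  expect_equal(unname(ser$values[ws == 1, peak]), rep(1, sum(ws == 1)),
               tolerance = 1e-9)
  # unrelated pairs outside every window: exactly zero under orthogonal
  # patterns (the zero-variance policy never triggers: unique patterns stay)
  outside <- which(ep$times == -700)
  expect_equal(max(abs(ser$values[, outside])), 0, tolerance = 1e-9)
})

test_that("zero-noise semantic effects are confined to the planted window", {
  lx <- make_lexicon(n_words = 6, seed = 8)
  sch <- effect_schedule(semantic = c(-680, -650), form = NULL,
                         word_specific = NULL)
  tr <- ground_truth(lx, sch, noise_sd = 0, seed = 9, orthonormal = TRUE)
  ep <- simulate_epochs(tr, n_participants = 1, rate = 250, seed = 10)[[1]]
  tab <- build_predictor_table(lx$lexicon, lx$taxonomy)
  cs <- condition_signals(rrsa(pairwise_rsa_series(ep), tab))
  diffs <- cs[, "semantic"] - cs[, "unrelated"]
  inside <- ep$times > -680 & ep$times < -650   # edges carry zero activation
  expect_true(all(diffs[inside] > 0))
  expect_equal(max(abs(diffs[!inside])), 0, tolerance = 1e-10)
})

test_that("same seed reproduces epochs; different participants differ", {
  lx <- make_lexicon(n_words = 4, seed = 11)
  tr <- ground_truth(lx, seed = 12)
  e1 <- simulate_epochs(tr, n_participants = 2, rate = 250, seed = 13)
  e2 <- simulate_epochs(tr, n_participants = 2, rate = 250, seed = 13)
  expect_identical(e1[[1]]$data, e2[[1]]$data)
  expect_false(identical(e1[[1]]$data, e1[[2]]$data))
})

test_that("doubling the noise shrinks the recovered cluster mass", {
  masses <- sapply(c(0.5, 1, 2), function(noise) {
    reps <- sapply(1:3, function(r) {
      st <- simulate_study(n_participants = 8, seed = 100 + r,
                           noise_sd = noise)
      sigs <- lapply(st$epochs, function(ep) {
        ep <- crop_window(ep, -690, -640)
        condition_signals(rrsa(pairwise_rsa_series(ep), st$predictors))
      })
      tm <- attr(sigs[[1]], "times")
      sem <- t(sapply(sigs, function(s) unclass(s)[, "semantic"]))
      unr <- t(sapply(sigs, function(s) unclass(s)[, "unrelated"]))
      tt <- one_sample_t_series(sem - unr)$t
      cl <- rrsa:::find_clusters_1d(tt, 2.04)
      if (nrow(cl)) max(cl$mass) else 0
    })
    mean(reps)
  })
  expect_true(all(diff(masses) < 0))
})

test_that("a synthetic dataset round-trips through its on-disk container", {
  st <- simulate_study(n_participants = 2, seed = 55, n_words = 4,
                       rate = 250)
  dir <- tempfile()
  write_synthetic_dataset(st, dir)
  expect_true(file.exists(file.path(dir, "lexicon.tsv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  eps <- read_epochs(file.path(dir, "epochs"))
  expect_identical(length(eps), 2L)
  expect_equal(eps[["p01"]]$data, st$epochs[[1]]$data)
  expect_equal(eps[["p02"]]$times, st$epochs[[2]]$times)
  lex <- read_lexicon(file.path(dir, "lexicon.tsv"))
  expect_identical(as.data.frame(lex), as.data.frame(st$lexinfo$lexicon))
})
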