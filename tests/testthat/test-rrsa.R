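toy_table <- function(seed = 1, n_words = 10) {
  lexinfo <- make_lexicon(n_words = n_words, seed = seed)
  build_predictor_table(lexinfo$lexicon, lexinfo$taxonomy)
}

test_that("noise-free model series recover their betas to 1e-10", {
  tab <- toy_table()
  truth <- c(0.02, 0.05, 0.03, 0.01)
  ser <- model_series(tab, truth, times = seq(-800, -791))
  fit <- rrsa(ser, tab)
  for (s in seq_along(ser$times)) {
    expect_equal(unname(coef(fit)[s, ]), truth, tolerance = 1e-10)
  }
})

test_that("a constant series loads entirely on the intercept", {
  tab <- toy_table(seed = 2)
  ser <- model_series(tab, c(0.37, 0, 0, 0), times = -5:-1)
  fit <- rrsa(ser, tab)
  expect_equal(unname(coef(fit)[, "intercept"]), rep(0.37, 5))
  expect_equal(max(abs(coef(fit)[, -1])), 0, tolerance = 1e-12)
})

test_that("noisy fits stay within three standard errors of the truth", {
  lexinfo <- make_lexicon(n_words = 20, seed = 8)
  tab <- build_predictor_table(lexinfo$lexicon, lexinfo$taxonomy)
  truth <- c(0.02, 0.05, 0.03, 0.01)
  ser <- model_series(tab, truth, times = 1:3)
  set.seed(99)
  ser$values <- ser$values + matrix(rnorm(length(ser$values), sd = 0.1),
                                    nrow = nrow(ser$values))
  fit <- rrsa(ser, tab)
  X <- cbind(1, tab$word_specific, tab$semantic, tab$form)
  se <- sqrt(diag(solve(crossprod(X))) * fit$sigma2[1])
  expect_true(all(abs(coef(fit)[1, ] - truth) < 3 * se))
})

test_that("condition signals follow the configuration algebra", {
  tab <- toy_table(seed = 3)
  ser <- model_series(tab, c(0.02, 0, 0.03, 0), times = 1:4)
  fit <- rrsa(ser, tab)
  cs <- condition_signals(fit)
  expect_equal(unname(cs[, "semantic"]), rep(0.05, 4))
  expect_equal(unname(cs[, "form"]), rep(0.02, 4))
  expect_equal(unname(cs[, "unrelated"]), rep(0.02, 4))
  expect_equal(unname(cs[, "word_specific"]), rep(0.05, 4))
})

test_that("word-specific minus unrelated equals the summed betas everywhere", {
  tab <- toy_table(seed = 4)
  set.seed(17)
  ser <- model_series(tab, c(0.01, 0.04, -0.02, 0.03), times = 1:6)
  ser$values <- ser$values + matrix(rnorm(length(ser$values), sd = 0.05),
                                    nrow = nrow(ser$values))
  fit <- rrsa(ser, tab)
  cs <- condition_signals(fit)
  B <- coef(fit)
  expect_equal(unname(cs[, "word_specific"] - cs[, "unrelated"]),
               unname(B[, "word_specific"] + B[, "semantic"] + B[, "form"]),
               tolerance = 1e-12)
  # the triple-difference identity isolates the word-specific beta
  expect_equal(unname((cs[, "word_specific"] - cs[, "unrelated"]) -
                        (cs[, "semantic"] - cs[, "unrelated"]) -
                        (cs[, "form"] - cs[, "unrelated"])),
               unname(B[, "word_specific"]), tolerance = 1e-12)
})

test_that("randomly dropped pairs leave noise-free recovery exact", {
  tab <- toy_table(seed = 5)
  truth <- c(0.02, 0.05, 0.03, 0.01)
  ser <- model_series(tab, truth, times = 1:3)
  set.seed(41)
  keep <- sort(sample(nrow(tab), nrow(tab) - 40))
  ser$pairs <- ser$pairs[keep, ]
  ser$values <- ser$values[keep, , drop = FALSE]
  fit <- rrsa(ser, tab)
  expect_equal(unname(coef(fit)[1, ]), truth, tolerance = 1e-10)
})

test_that("rank-deficient designs are flagged missing, not fitted", {
  # all surviving pairs share word_specific = 0 AND semantic == form pattern
  tab <- toy_table(seed = 6)
  sub <- tab[tab$word_specific == 0, ]
  sub$semantic <- sub$form          # perfectly collinear
  ser <- model_series(sub, c(0.02, 0, 0.01, 0.01), times = 1:2)
  fit <- rrsa(ser, sub)
  expect_true(all(is.na(coef(fit))))
})

test_that("missing similarity values propagate as unfitted samples", {
  tab <- toy_table(seed = 7)
  ser <- model_series(tab, c(0.02, 0.05, 0.03, 0.01), times = 1:3)
  ser$values[, 2] <- NA_real_       # e.g. zero-variance patterns
  fit <- rrsa(ser, tab)
  expect_true(all(is.na(coef(fit)[2, ])))
  expect_false(anyNA(coef(fit)[c(1, 3), ]))
})

test_that("grand averages match explicit summation and handle sign flips", {
  tab <- toy_table(seed = 9)
  mk <- function(b) {
    condition_signals(rrsa(model_series(tab, b, times = 1:5), tab))
  }
  s <- mk(c(0.02, 0.05, 0.03, 0.01))
  neg <- mk(-c(0.02, 0.05, 0.03, 0.01))
  expect_equal(unclass(grand_average(list(s))), unclass(s),
               ignore_attr = TRUE)
  expect_equal(max(abs(grand_average(list(s, neg)))), 0, tolerance = 1e-12)
  sigs <- lapply(1:10, function(i) mk(c(0.01 * i, 0.01, 0, 0.02)))
  ga <- grand_average(sigs)
  manual <- Reduce(`+`, lapply(sigs, unclass)) / 10
  expect_equal(unclass(ga), manual, ignore_attr = TRUE)
})

test_that("simulate() is seed-reproducible and centered on the fit", {
  tab <- toy_table(seed = 10)
  ser <- model_series(tab, c(0.02, 0.05, 0.03, 0.01), times = 1:4)
  set.seed(3); ser$values <- ser$values +
    matrix(rnorm(length(ser$values), sd = 0.05), nrow = nrow(ser$values))
  fit <- rrsa(ser, tab)
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  big <- simulate(fit, nsim = 20, seed = 6)
  expect_equal(mean(Reduce(`+`, big) / 20 - fitted(fit)), 0, tolerance = 0.01)
})
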