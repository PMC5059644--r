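test_that("maximum-likelihood unigram matches counts", {
  m <- train_ngram(list(c("a", "b", "a", "b")), 1, smoothing = "none",
                   include_end = FALSE)
  expect_equal(exp(lm_logprob(m, "a")), 0.5)
  expect_equal(exp(lm_logprob(m, "b")), 0.5)
  expect_identical(lm_logprob(m, "c"), -Inf)
  expect_error(train_ngram(list(), 1), "empty")
  expect_error(train_ngram(list("a"), 0), "order")
})

test_that("Witten-Bell bigram matches hand computation", {
  # corpus "abab" without end symbols; V = 2
  m <- train_ngram(list(c("a", "b", "a", "b")), 2, include_end = FALSE)
  # unigram: c() = 4, T() = 2, lambda0 = 1/3; P1(a) = 2/6 + (1/3)(1/2) = 1/2
  expect_equal(exp(lm_logprob(m, "a", character(0))), 0.5)
  # history "a": c = 2 (both continuations "b"), T = 1, lambda = 1/3
  # P(b|a) = 2/3 + (1/3) * P1(b) = 2/3 + 1/6 = 5/6
  expect_equal(exp(lm_logprob(m, "b", "a")), 5 / 6)
  # unseen continuation backs off: P(a|a) = (1/3) * P1(a) = 1/6
  expect_equal(exp(lm_logprob(m, "a", "a")), 1 / 6)
})

test_that("conditional distributions are normalized for every history", {
  corp <- synthetic_kana_corpus(100, letters[1:6], seed = 3)
  for (k in 1:3) {
    m <- train_ngram(corp, k)
    events <- c(m$vocab, "</s>")
    for (h in list(character(0), "a", c("b", "c"), c("<s>", "a"))) {
      tot <- sum(vapply(events, function(w) exp(lm_logprob(m, w, h)),
                        numeric(1)))
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }
})

test_that("perplexity closed forms and token-by-token oracle agree", {
  # uniform unigram over the 70-character Kana inventory
  u <- train_ngram(list(kana_vocabulary()), 1, smoothing = "none",
                   include_end = FALSE)
  txt <- kana_vocabulary()[c(3, 10, 40, 69, 1, 22, 55, 70, 13, 31)]
  expect_equal(perplexity(u, txt), 70)
  # deterministic model on a repeating symbol
  d <- train_ngram(list(rep("a", 50)), 1, smoothing = "none",
                   include_end = FALSE)
  expect_equal(perplexity(d, rep("a", 10)), 1)
  # independent per-token log-prob sum on a 10-character string
  m <- train_ngram(synthetic_kana_corpus(50, letters[1:4], seed = 9), 2)
  txt <- c("a", "b", "b", "c", "a", "d", "c", "b", "a", "a")
  by_hand <- 0
  hist <- "<s>"
  for (w in txt) {
    by_hand <- by_hand + lm_logprob(m, w, hist)
    hist <- w
  }
  by_hand <- by_hand + lm_logprob(m, "</s>", hist)
  expect_equal(perplexity(m, txt), exp(-by_hand / 11))
  # unsmoothed zero-probability event warns and returns Inf
  expect_warning(pp <- perplexity(d, c("a", "b")), "zero-probability")
  expect_identical(pp, Inf)
})

test_that("higher orders fit the training corpus at least as well", {
  corp <- synthetic_kana_corpus(300, kana_vocabulary(), seed = 4)
  pp <- vapply(1:3, function(k)
    perplexity_corpus(train_ngram(corp, k, vocab = kana_vocabulary()), corp),
    numeric(1))
  expect_true(all(diff(pp) <= 1e-9))
})

test_that("ARPA files round-trip probabilities to 1e-9", {
  corp <- synthetic_kana_corpus(80, letters[1:5], seed = 6)
  for (k in c(1, 3)) {
    m <- train_ngram(corp, k)
    expect_true(roundtrip_check(m))
    path <- tempfile(fileext = ".arpa")
    write_arpa(m, path)
    y <- read_arpa(path)
    # spot-check a conditional probability through the backoff chain
    h <- corp[[1]][1]
    for (w in c(corp[[2]][1], "</s>"))
      expect_equal(lm_logprob(y, w, h), lm_logprob(m, w, h),
                   tolerance = 1e-9)
  }
  expect_error(read_arpa(textConnection("")), )
})

test_that("synthetic Kana corpus is reproducible with Zipf-like skew", {
  a <- synthetic_kana_corpus(50, seed = 8)
  b <- synthetic_kana_corpus(50, seed = 8)
  expect_identical(a, b)
  counts <- sort(table(unlist(a)), decreasing = TRUE)
  expect_gt(counts[1], tail(counts, 1))
  expect_true(all(unlist(a) %in% kana_vocabulary()))
})
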