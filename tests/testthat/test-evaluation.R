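test_that("alignment counts basic cases correctly", {
  eq <- align_and_count(letters[1:4], letters[1:4])
  expect_equal(c(eq$S, eq$D, eq$I, eq$N), c(0, 0, 0, 4))
  sub <- align_and_count(c("a", "b", "c", "d"), c("a", "b", "x", "d"))
  expect_equal(c(sub$S, sub$D, sub$I), c(1, 0, 0))
  del <- align_and_count(c("a", "b", "c"), c("a", "c"))
  expect_equal(c(del$S, del$D, del$I), c(0, 1, 0))
  ins <- align_and_count(c("a", "c"), c("a", "b", "c"))
  expect_equal(c(ins$S, ins$D, ins$I), c(0, 0, 1))
  # empty edge cases
  e1 <- align_and_count(character(0), c("a", "b"))
  expect_equal(c(e1$S, e1$D, e1$I, e1$N), c(0, 0, 2, 0))
  e2 <- align_and_count(c("a", "b"), character(0))
  expect_equal(c(e2$S, e2$D, e2$I), c(0, 2, 0))
})

test_that("S + D + I equals the Levenshtein distance on random pairs", {
  set.seed(42)
  syms <- letters[1:5]
  for (i in 1:500) {
    ref <- sample(syms, sample(0:10, 1), replace = TRUE)
    hyp <- sample(syms, sample(0:10, 1), replace = TRUE)
    counts <- align_and_count(ref, hyp)
    expect_equal(counts$S + counts$D + counts$I,
                 levenshtein_oracle(ref, hyp))
    expect_lte(counts$S + counts$D, length(ref))
  }
})

test_that("error rate follows 100 * (S + D + I) / N and can exceed 100%", {
  expect_equal(error_rate(list(S = 0, D = 0, I = 0, N = 5)), 0)
  expect_equal(error_rate(list(S = 1, D = 1, I = 0, N = 4)), 50)
  expect_equal(error_rate(list(S = 0, D = 0, I = 4, N = 4)), 100)
  # insertion-dominated hypothesis
  over <- align_and_count(c("a"), c("b", "b", "b"))
  expect_gt(error_rate(over), 100)
  expect_error(error_rate(list(S = 0, D = 0, I = 0, N = 0)), "positive")
})

test_that("corpus scoring pools counts rather than averaging rates", {
  outs <- list(c("a"), c("a", "b", "c", "d", "e", "f", "g", "x"))
  refs <- list(c("b"), c("a", "b", "c", "d", "e", "f", "g", "h"))
  ev <- evaluate_corpus(outs, refs)
  # pooled: (1 + 1) / (1 + 8); mean of rates would be (100 + 12.5) / 2
  expect_equal(ev$rate, 100 * 2 / 9)
  expect_false(isTRUE(all.equal(ev$rate, mean(ev$per_utterance$rate))))
  expect_error(evaluate_corpus(list(), list()), "empty")
  expect_error(evaluate_corpus(outs, refs[1]), "differ in length")
})

test_that("relative reduction reproduces its defining arithmetic", {
  expect_equal(relative_reduction(50, 25), 50)
  expect_equal(relative_reduction(10, 10), 0)
  expect_error(relative_reduction(0, 1))
})
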