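# A small trained system shared by the adaptation tests: single user,
# modest corpus, mono units (adaptation machinery is unit-kind agnostic).
adapt_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    p <- fixture_profile()
    corpus <- generate_corpus(10, profile = p, seed = 31)
    set <- train_system(corpus, "mono",
                        config = train_config(n_iterations = 3,
                                              mixture_schedule = 1))
    cache <<- list(set = set, profile = p, corpus = corpus)
    cache
  }
})

test_that("MLLR on self-generated data recovers the identity transform", {
  set.seed(41)
  toy <- make_mllr_toy()
  chains <- lapply(1:25, function(i) list(
    units = c("a", "b"), feats = sample_from_chain(toy, c("a", "b"), 50)))
  adapted <- mllr_adapt(toy, chains)
  tr <- attr(adapted, "mllr")[[1]]
  expect_lt(max(abs(tr$A - diag(toy$dim))), 0.05)
  expect_lt(max(abs(tr$b)), 0.05)
})

test_that("MLLR recovers a known global mean shift", {
  set.seed(42)
  toy <- make_mllr_toy()
  shift <- 0.5
  chains <- lapply(1:25, function(i) list(
    units = c("a", "b"),
    feats = sample_from_chain(toy, c("a", "b"), 50, shift = shift)))
  adapted <- mllr_adapt(toy, chains)
  tr <- attr(adapted, "mllr")[[1]]
  expect_lt(max(abs(tr$b - shift)), 0.05)
  expect_lt(max(abs(tr$A - diag(toy$dim))), 0.05)
  # the ML step does not decrease the adaptation-data likelihood
  ll <- function(s) sum(vapply(chains, function(ch)
    log_likelihood(s, make_chain_graph(s, ch$units), ch$feats), numeric(1)))
  expect_gte(ll(adapted), ll(toy) - 1e-6)
})

test_that("MAP interpolates between prior and data means", {
  fx <- adapt_fixture()
  set <- fx$set
  set.seed(43)
  units <- c("up", "center")
  chains <- list(list(units = units,
                      feats = sample_from_chain(set, units, 30, shift = 50)))
  # tau -> Inf limit: stay at the prior (use a huge but finite tau)
  huge <- map_adapt(set, chains, map_config(tau = 1e12))
  for (p in seq_along(set$pdfs))
    expect_equal(huge$pdfs[[p]]$means, set$pdfs[[p]]$means,
                 tolerance = 1e-6)
  # tau = 0: occupancy-weighted data means (check via a 1-component toy)
  toy <- make_hmm_set("u", 0, 1, n_states = 1)
  Xt <- matrix(c(1, 2, 3, 6), ncol = 1)
  t0 <- map_adapt(toy, list(list(units = "u", feats = Xt)),
                  map_config(tau = 0))
  expect_equal(t0$pdfs[[1]]$means[1, 1], mean(Xt), tolerance = 1e-9)
  # tau = 10 hand interpolation on the same toy
  t10 <- map_adapt(toy, list(list(units = "u", feats = Xt)),
                   map_config(tau = 10))
  prior <- toy$pdfs[[1]]$means[1, 1]
  expect_equal(t10$pdfs[[1]]$means[1, 1],
               (10 * prior + sum(Xt)) / (10 + 4), tolerance = 1e-9)
  # monotone in tau: adapted means lie between data mean and prior
  taus <- c(0, 1, 10, 100, 1e6)
  ms <- vapply(taus, function(tau)
    map_adapt(toy, list(list(units = "u", feats = Xt)),
              map_config(tau = tau))$pdfs[[1]]$means[1, 1], numeric(1))
  expect_true(all(diff(ms) * sign(prior - mean(Xt)) >= -1e-12))
  expect_error(map_config(tau = -1))
})

test_that("insertion-penalty tuning honors its argmin contract", {
  fx <- adapt_fixture()
  proto <- subset_protocol(build_default_protocol(1),
                           c("a", "ko", "e", "ka"))
  graph <- build_decoding_graph(fx$set, proto, NULL, "mono")
  set.seed(44)
  dev <- lapply(1:3, function(i) {
    word <- sample(c("a", "ko", "e", "ka"), 2)
    list(characters = word,
         recording = generate_recording(word_to_motions(word, proto),
                                        fx$profile))
  })
  # singleton grid returns its element
  expect_equal(tune_insertion_penalty(graph, dev, grid = 0)$penalty, 0)
  res <- tune_insertion_penalty(graph, dev, grid = c(-40, -10, 0, 10))
  expect_true(res$penalty %in% c(-40, -10, 0, 10))
  expect_true(all(res$cer <= res$grid_cer + 1e-12))
  # with equal CER at both grid points the tie breaks toward zero
  r2 <- tune_insertion_penalty(graph, dev, grid = c(0, -10))
  if (r2$grid_cer[["0"]] == r2$grid_cer[["-10"]])
    expect_equal(r2$penalty, 0)
})
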