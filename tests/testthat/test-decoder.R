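# Shared fixture: a 2-character protocol and a mono system trained on a
# small corpus, for structural decoder checks.
decoder_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    proto <- subset_protocol(build_default_protocol(1), c("a", "ko"))
    p <- fixture_profile()
    set.seed(51)
    corpus <- unlist(lapply(1:3, function(i) generate_training_unit(p)),
                     recursive = FALSE)
    cfg <- train_config(n_iterations = 3, mixture_schedule = 1)
    sets <- list(
      mono = train_system(corpus, "mono", config = cfg),
      tri = train_system(corpus, "tri", config = cfg)
    )
    cache <<- list(proto = proto, profile = p, sets = sets)
    cache
  }
})

test_that("graph topology is independent of the language model", {
  fx <- decoder_fixture()
  lm1 <- train_ngram(list(c("a", "ko"), c("ko", "a"), c("a", "ko", "a")), 1)
  g0 <- build_decoding_graph(fx$sets$mono, fx$proto, NULL, "mono")
  g1 <- build_decoding_graph(fx$sets$mono, fx$proto, lm1, "mono")
  expect_identical(g0$arc_from, g1$arc_from)
  expect_identical(g0$arc_to, g1$arc_to)
  expect_identical(g0$arc_logp, g1$arc_logp)   # acoustic scores unchanged
  expect_false(isTRUE(all.equal(g0$arc_lm, g1$arc_lm)))
  # mono graph has one chain per character: 4 states x (4+8) motions + sil
  expect_equal(length(g0$pdf_ids), 4 * (4 + 4) + 2 * 4)
})

test_that("tri graphs exchange contexts across character boundaries", {
  fx <- decoder_fixture()
  g <- build_decoding_graph(fx$sets$tri, fx$proto, NULL, "tri")
  # /a/ = up,down,up,center followed by /ko/ = up,center,up,center:
  # the boundary expansion per the context-unit rule
  a_code <- char_to_motions("a", fx$proto)
  ko_code <- char_to_motions("ko", fx$proto)
  expanded <- expand_units(c(a_code, ko_code), "tri")
  # the cross-boundary units must exist (possibly tying-synthesized) in
  # the graph's resolved model set
  boundary_units <- expanded[c(4, 5)]   # "up-center+up", "center-up+center"
  for (u in boundary_units) {
    r <- resolve_decoding_unit(g$set, u)
    expect_true(r$name %in% names(r$set$units))
  }
  # arcs that emit characters carry the insertion-score component
  expect_true(all(g$arc_ins[!is.na(g$arc_out)] == 1))
  expect_true(all(g$arc_ins[is.na(g$arc_out)] == 0))
})

test_that("clean recordings of known words decode exactly", {
  fx <- decoder_fixture()
  g <- build_decoding_graph(fx$sets$tri, fx$proto, NULL, "tri")
  set.seed(52)
  for (word in list(c("a", "ko"), c("ko", "a", "ko"), "a")) {
    rec <- generate_recording(word_to_motions(word, fx$proto), fx$profile)
    hyp <- decode(six_channel_features(rec)$vectors, g)
    expect_identical(hyp$characters, word)
    expect_identical(hyp$motions, word_to_motions(word, fx$proto))
  }
})

test_that("exact search matches exhaustive hypothesis enumeration", {
  fx <- decoder_fixture()
  set <- fx$sets$mono
  g <- build_decoding_graph(set, fx$proto, NULL, "mono", use_sil = FALSE)
  set.seed(53)
  p_short <- eog_profile(motion_duration_mean = 0.09,
                         motion_duration_std = 0, rise_time = 0.05,
                         sil_pad = 0, noise_std = 20, drift_rate = 0,
                         gaze_jitter = 0.05, rise_jitter = 0.05)
  rec <- generate_recording(char_to_motions("a", fx$proto), p_short)
  X <- six_channel_features(rec)$vectors   # ~36 frames
  cfg <- decode_config(insertion_penalty = -1)
  hyp <- decode(X, g, cfg)
  # oracle: score every character sequence up to length 2 by forced
  # alignment through the same models plus the insertion penalty
  cand <- list("a", "ko", c("a", "ko"), c("ko", "a"), c("a", "a"),
               c("ko", "ko"))
  scores <- vapply(cand, function(w) {
    units <- expand_units(word_to_motions(w, fx$proto), "mono")
    gr <- make_chain_graph(set, units)
    viterbi_align(set, gr, X)$score + cfg$insertion_penalty * length(w)
  }, numeric(1))
  expect_equal(hyp$log_score, max(scores), tolerance = 1e-8)
  expect_identical(hyp$characters, cand[[which.max(scores)]])
})

test_that("decoding is deterministic and penalties curb insertions", {
  fx <- decoder_fixture()
  g <- build_decoding_graph(fx$sets$mono, fx$proto, NULL, "mono")
  set.seed(54)
  rec <- generate_recording(word_to_motions(c("a", "ko"), fx$proto),
                            fx$profile)
  X <- six_channel_features(rec)$vectors
  h1 <- decode(X, g)
  h2 <- decode(X, g)
  expect_identical(h1$characters, h2$characters)
  expect_identical(h1$log_score, h2$log_score)
  # stronger negative penalties never increase the output length
  lens <- vapply(c(0, -50, -200, -1000), function(pen)
    length(decode(X, g, decode_config(insertion_penalty = pen))$characters),
    numeric(1))
  expect_true(all(diff(lens) <= 0))
  # and the exact-search score is non-increasing as the penalty drops
  scores <- vapply(c(0, -50, -200), function(pen)
    decode(X, g, decode_config(insertion_penalty = pen))$log_score,
    numeric(1))
  expect_true(all(diff(scores) <= 1e-9))
})

test_that("an impossible observation yields a flagged empty hypothesis", {
  fx <- decoder_fixture()
  g <- build_decoding_graph(fx$sets$mono, fx$proto, NULL, "mono",
                            use_sil = FALSE)
  X <- matrix(rnorm(12), 2, 6)   # far shorter than any character chain
  expect_warning(hyp <- decode(X, g), "no complete")
  expect_identical(hyp$characters, character(0))
  expect_identical(hyp$log_score, -Inf)
  expect_true(hyp$no_path)
})
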