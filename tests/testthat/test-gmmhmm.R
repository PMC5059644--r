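test_that("single-state forward likelihood equals the Gaussian closed form", {
  set.seed(1)
  X <- matrix(rnorm(30, 1, 2), ncol = 1)
  set <- make_hmm_set("u", global_mean = 1, global_var = 4, n_states = 1)
  # self-loop 0.6 / exit 0.4: per-frame density plus transition terms
  g <- make_chain_graph(set, "u")
  ll <- log_likelihood(set, g, X)
  dens <- sum(dnorm(X, 1, 2, log = TRUE))
  expect_equal(ll, dens + (nrow(X) - 1) * log(0.6) + log(0.4),
               tolerance = 1e-10)
})

test_that("forward and Viterbi match brute-force path enumeration", {
  set.seed(77)
  for (i in 1:40) {
    cs <- random_small_case()
    ll <- eogdeco:::forward_loglik_cpp(cs$logobs, cs$pdf0, cs$start,
                                       cs$final, cs$af - 1L, cs$at - 1L,
                                       cs$alp)
    vt <- eogdeco:::viterbi_cpp(cs$logobs, cs$pdf0, cs$start, cs$final,
                                cs$af - 1L, cs$at - 1L, cs$alp, Inf)
    oracle <- brute_force_scores(cs$logobs, cs$pdf0, cs$start, cs$final,
                                 cs$af, cs$at, cs$alp)
    if (is.finite(oracle$forward)) {
      expect_equal(ll, oracle$forward, tolerance = 1e-10)
      expect_equal(vt$score, oracle$viterbi, tolerance = 1e-10)
    } else {
      expect_identical(ll, -Inf)
      expect_identical(vt$score, -Inf)
    }
    expect_lte(vt$score, ll + 1e-10)
  }
})

test_that("observations shorter than the chain give -Inf", {
  set <- make_hmm_set(c("a", "b"), 0, 1, n_states = 4)
  g <- make_chain_graph(set, c("a", "b"))  # minimum path: 8 frames
  X <- matrix(rnorm(5), ncol = 1)
  expect_identical(log_likelihood(set, g, X), -Inf)
  v <- viterbi_align(set, g, X)
  expect_identical(v$score, -Inf)
  expect_null(v$path)
  expect_error(log_likelihood(set, g, matrix(0, 10, 3)), "dimension")
})

test_that("a forced single path is recovered by alignment", {
  set <- make_hmm_set("u", 0, 1, n_states = 3)
  # deterministic advance: no self loops
  tr <- matrix(0, 3, 4)
  tr[1, 2] <- 1; tr[2, 3] <- 1; tr[3, 4] <- 1
  set$units$u$trans <- tr
  g <- make_chain_graph(set, "u")
  al <- viterbi_align(set, g, matrix(rnorm(3), ncol = 1))
  expect_equal(al$path$state_pos, 1:3)
})

test_that("EM fixed point: one state recovers sample moments", {
  set.seed(3)
  X <- matrix(rnorm(400, 5, 3), ncol = 1)
  set <- make_hmm_set("u", 0, 1, n_states = 1)
  tr <- baum_welch(set, list(list(units = "u", feats = X)),
                   train_config(n_iterations = 2, mixture_schedule = 1))
  expect_equal(tr$pdfs[[1]]$means[1, 1], mean(X), tolerance = 1e-8)
  expect_equal(tr$pdfs[[1]]$vars[1, 1],
               mean((X - mean(X))^2), tolerance = 1e-8)
})

test_that("EM increases the likelihood monotonically and keeps invariants", {
  p <- fixture_profile()
  corpus <- generate_corpus(5, profile = p, seed = 4)
  items <- lapply(corpus, function(it) list(
    units = c("sil", it$motions, "sil"),
    feats = six_channel_features(it$recording)$vectors))
  X <- do.call(rbind, lapply(items, `[[`, "feats"))
  set <- make_hmm_set(unique(unlist(lapply(items, `[[`, "units"))),
                      colMeans(X), apply(X, 2, var))
  tr <- baum_welch(set, items,
                   train_config(n_iterations = 6, mixture_schedule = c(1, 2)))
  trace <- attr(tr, "loglik_trace")
  # monotone within each mixture stage; a split may perturb slightly
  expect_true(all(diff(trace[1:6]) > -1e-6 * abs(trace[2:6])))
  for (u in names(tr$units))
    expect_equal(rowSums(tr$units[[u]]$trans), rep(1, 4), tolerance = 1e-9)
  for (pdf in tr$pdfs) {
    expect_equal(sum(pdf$weights), 1, tolerance = 1e-9)
    expect_true(all(t(pdf$vars) >= tr$var_floor - 1e-12))
  }
})

test_that("training data from a known 2-state chain recovers its means", {
  set.seed(10)
  gen_mean <- c(-2, 2)
  seqs <- replicate(100, {
    n1 <- sample(5:15, 1); n2 <- sample(5:15, 1)
    matrix(c(rnorm(n1, gen_mean[1], 0.5), rnorm(n2, gen_mean[2], 0.5)),
           ncol = 1)
  }, simplify = FALSE)
  set <- make_hmm_set("u", 0, 4, n_states = 2)
  tr <- baum_welch(set, lapply(seqs, function(X) list(units = "u", feats = X)),
                   train_config(n_iterations = 12, mixture_schedule = 1))
  mns <- sort(vapply(tr$pdfs[tr$units$u$pdf_ids],
                     function(p) p$means[1, 1], numeric(1)))
  expect_lt(max(abs(mns - gen_mean)), 0.1)
})

test_that("one EM pass matches an R forward-backward oracle on a tiny case", {
  # 2 states, 3 frames, 1-dim: hand-rolled forward-backward in R
  set <- make_hmm_set("u", 0, 1, n_states = 2)
  X <- matrix(c(-1, 0.2, 1.4), ncol = 1)
  g <- make_chain_graph(set, "u")
  lo <- eogdeco:::graph_logobs(set, g, X)
  fb <- eogdeco:::forward_backward_cpp(lo$logobs, lo$pdf0, g$start, g$final,
                                       g$arc_from - 1L, g$arc_to - 1L,
                                       g$arc_logp)
  # R oracle: enumerate the 4 admissible paths (1->1->1? must end in 2)
  dens <- function(t, s) exp(lo$logobs[t, lo$pdf0[s] + 1])
  paths <- list(c(1, 1, 2), c(1, 2, 2))
  w <- vapply(paths, function(pt) {
    pr <- dens(1, pt[1])
    for (t in 2:3) {
      a <- if (pt[t - 1] == pt[t]) 0.6 else 0.4
      pr <- pr * a * dens(t, pt[t])
    }
    pr * 0.4   # exit from state 2
  }, numeric(1))
  gamma_oracle <- sapply(1:2, function(s)
    sapply(1:3, function(t)
      sum(w[vapply(paths, function(pt) pt[t] == s, logical(1))]) / sum(w)))
  expect_equal(fb$loglik, log(sum(w)), tolerance = 1e-10)
  expect_equal(unname(fb$gamma), unname(gamma_oracle), tolerance = 1e-10)
})

test_that("mixture splitting preserves likelihood at split time", {
  set.seed(6)
  X <- matrix(rnorm(200, 0, 1.5), ncol = 1)
  set <- make_hmm_set("u", 0, 2, n_states = 1)
  tr <- baum_welch(set, list(list(units = "u", feats = X)),
                   train_config(n_iterations = 3, mixture_schedule = 1))
  g <- make_chain_graph(tr, "u")
  before <- log_likelihood(tr, g, X)
  split <- split_mixtures(tr, 2)
  after <- log_likelihood(split, make_chain_graph(split, "u"), X)
  # components sit symmetrically (+/- 0.2 sd) about the old mean
  expect_equal(after, before, tolerance = 0.02 * abs(before))
  expect_length(split$pdfs[[1]]$weights, 2)
})
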