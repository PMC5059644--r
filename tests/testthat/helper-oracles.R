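# Independent oracles used across the suite: brute-force HMM path
# enumeration, a textbook quadratic edit-distance DP, and small random
# graph generators.  These never call the package's own recursions.

# Enumerate all state paths of length T through an arc-list graph and
# return the log-sum (forward) and max (Viterbi) path scores.
brute_force_scores <- function(logobs, pdf0, start, final, af, at, alp) {
  T_ <- nrow(logobs)
  scores <- numeric(0)
  rec <- function(path, sc) {
    t <- length(path)
    if (t == T_) {
      s <- path[t]
      if (is.finite(final[s]))
        scores[length(scores) + 1] <<- sc + final[s]
      return()
    }
    for (a in which(af == path[t]))
      rec(c(path, at[a]), sc + alp[a] + logobs[t + 1, pdf0[at[a]] + 1])
  }
  for (s in which(is.finite(start)))
    rec(s, start[s] + logobs[1, pdf0[s] + 1])
  if (length(scores) == 0) return(list(forward = -Inf, viterbi = -Inf))
  m <- max(scores)
  list(forward = m + log(sum(exp(scores - m))), viterbi = m)
}

# A random small arc-list graph plus observations.
random_small_case <- function(max_states = 3, max_T = 6) {
  S <- sample(seq_len(max_states), 1)
  T_ <- sample(seq_len(max_T), 1)
  logobs <- matrix(rnorm(T_ * S), T_, S)
  start <- log(runif(S))
  final <- log(runif(S))
  if (S > 1 && runif(1) < 0.5) start[sample(S, S - 1)] <- -Inf
  A <- sample(seq_len(S * S), 1)
  list(logobs = logobs, pdf0 = 0:(S - 1), start = start, final = final,
       af = sample(S, A, TRUE), at = sample(S, A, TRUE),
       alp = log(runif(A)), T_ = T_, S = S)
}

# Textbook quadratic Levenshtein distance (costs 1/1/1), no backtrace.
levenshtein_oracle <- function(ref, hyp) {
  n <- length(ref); m <- length(hyp)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m)) {
    d[i + 1, j + 1] <- min(d[i, j] + (ref[i] != hyp[j]),
                           d[i, j + 1] + 1L, d[i + 1, j] + 1L)
  }
  d[n + 1, m + 1]
}

# Sliding-window majority recount (independent of vote_filter's loop).
vote_oracle <- function(labels, win, shift, prefs) {
  n <- length(labels)
  starts <- if (n <= win) 1L else seq(1L, n - win + 1L, by = shift)
  sapply(starts, function(s) {
    w <- labels[s:min(s + win - 1L, n)]
    counts <- sapply(prefs, function(p) sum(w == p))
    prefs[which.max(counts)]
  })
}

# Tiny deterministic recording fixture shared by several tests.
fixture_profile <- function(...) {
  eog_profile(noise_std = 20, drift_rate = 5, ...)
}

# Sample observations directly from a unit's left-to-right chain.
sample_from_chain <- function(set, units, n_frames_per_state = 20,
                              shift = 0) {
  X <- NULL
  for (u in units) {
    unit <- set$units[[u]]
    for (s in seq_along(unit$pdf_ids)) {
      pdf <- set$pdfs[[unit$pdf_ids[s]]]
      m <- sample(length(pdf$weights), n_frames_per_state, TRUE,
                  prob = pdf$weights)
      pts <- pdf$means[m, , drop = FALSE] +
        matrix(rnorm(n_frames_per_state * set$dim), n_frames_per_state) *
          sqrt(pdf$vars[m, , drop = FALSE])
      X <- rbind(X, sweep(pts, 2, rep(shift, length.out = set$dim), "+"))
    }
  }
  X
}


# A small 2-D toy model whose state means span the feature space, so MLLR
# transforms are identifiable from sampled data.
make_mllr_toy <- function() {
  toy <- make_hmm_set(c("a", "b"), global_mean = c(0, 0),
                      global_var = c(0.25, 0.25), n_states = 2)
  ms <- list(c(-2, -2), c(-1, 1), c(1, -1), c(2, 2))
  i <- 1
  for (u in c("a", "b")) for (s in 1:2) {
    toy$pdfs[[toy$units[[u]]$pdf_ids[s]]]$means[1, ] <- ms[[i]]
    i <- i + 1
  }
  toy
}
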