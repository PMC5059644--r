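test_that("unit expansion reproduces the published example", {
  seq <- c("up", "down", "up", "center")
  expect_equal(expand_units(seq, "mono"), seq)
  expect_equal(expand_units(seq, "bi"),
               c("up", "up-down", "down-up", "up-center"))
  expect_equal(expand_units(seq, "tri"),
               c("up+down", "up-down+up", "down-up+center", "up-center"))
  expect_equal(expand_units("left", "tri"), "left")
  expect_error(expand_units(character(0), "tri"), "empty")
  # names parse back
  pu <- parse_unit_name("up-down+up")
  expect_equal(pu, list(target = "down", left = "up", right = "up",
                        kind = "tri"))
  expect_equal(parse_unit_name("up-center")$kind, "bi_left")
  expect_equal(parse_unit_name("center+up")$kind, "bi_right")
  expect_equal(parse_unit_name("sil")$kind, "sil")
})

test_that("the untied state inventory matches direct enumeration", {
  expect_identical(count_state_inventory(5, 4), 480L)
  # brute-force oracle for a 2-motion alphabet with 1 state per model
  ab <- c("m1", "m2")
  n_brute <- 0L
  for (t in ab) {
    for (p in setdiff(ab, t)) for (s in setdiff(ab, t)) n_brute <- n_brute + 1L
    for (p in setdiff(ab, t)) n_brute <- n_brute + 1L
    for (s in setdiff(ab, t)) n_brute <- n_brute + 1L
  }
  expect_identical(count_state_inventory(2, 1), n_brute)
  expect_identical(count_state_inventory(3, 0), 0L)
})

# hand-built tying statistics for one target at one position:
# three left contexts with distinct means and unit occupancies
toy_tying_setup <- function(means, occs = rep(20, length(means))) {
  n_states <- 1
  units <- paste0(names(means), "-up")
  set <- make_hmm_set(units, global_mean = 0, global_var = 1,
                      n_states = n_states)
  stats <- list()
  for (i in seq_along(units)) {
    pid <- set$units[[units[i]]]$pdf_ids[1]
    stats[[pid]] <- list(occ = occs[i], sx = occs[i] * means[[i]],
                         sxx = occs[i] * (means[[i]]^2 + 1))
  }
  list(set = set, stats = stats)
}

test_that("greedy first split equals exhaustive question search", {
  means <- c(down = -4, left = 0.2, right = 0.3)
  ts <- toy_tying_setup(means)
  tied <- tie_states(ts$set, ts$stats, threshold = 0, min_occ = 1)
  # exhaustive oracle: evaluate every question's single-Gaussian gain
  qs <- default_questions()
  items <- lapply(names(means), function(l)
    list(left = l, right = NA, occ = 20, sx = 20 * means[[l]],
         sxx = 20 * (means[[l]]^2 + 1)))
  pool_L <- function(its) {
    occ <- sum(sapply(its, `[[`, "occ"))
    if (occ == 0) return(0)
    mu <- sum(sapply(its, `[[`, "sx")) / occ
    v <- max(sum(sapply(its, `[[`, "sxx")) / occ - mu^2, 1e-4)
    -0.5 * occ * (1 * (log(2 * pi) + 1) + log(v))
  }
  gains <- vapply(qs, function(q) {
    ans <- vapply(items, function(it)
      eogdeco:::answer_question(q, it$left, it$right), logical(1))
    if (!any(ans) || all(ans)) return(-Inf)
    pool_L(items[ans]) + pool_L(items[!ans]) - pool_L(items)
  }, numeric(1))
  best_q <- qs[[which.max(gains)]]
  # the best split must isolate the outlying "down" context
  tree <- tied$set$tying$trees[["up/1"]]
  expect_false(isTRUE(tree$leaf))
  chosen <- tied$set$tying$questions[[tree$question]]
  expect_equal(sort(unlist(chosen[c("side", "motions")])),
               sort(unlist(best_q[c("side", "motions")])))
  expect_equal(tree$gain, max(gains), tolerance = 1e-8)
})

test_that("degenerate thresholds give fully tied or fully split states", {
  means <- c(down = -4, left = 0.2, right = 3)
  ts <- toy_tying_setup(means)
  all_tied <- tie_states(ts$set, ts$stats, threshold = Inf, min_occ = 1)
  expect_equal(all_tied$n_tied, 1)       # one target, one position
  full <- tie_states(ts$set, ts$stats, threshold = 0, min_occ = 1)
  expect_equal(full$n_tied, 3)           # all-distinct data fully splits
  # five motions, four states, threshold Inf -> 20 tied states
  p <- fixture_profile()
  corpus <- generate_corpus(8, profile = p, seed = 21)
  items <- lapply(corpus, function(it) list(
    units = expand_units(it$motions, "tri"),
    feats = six_channel_features(it$recording)$vectors))
  X <- do.call(rbind, lapply(items, `[[`, "feats"))
  set <- make_hmm_set(unique(unlist(lapply(items, `[[`, "units"))),
                      colMeans(X), apply(X, 2, var))
  set <- baum_welch(set, items, train_config(2, 1))
  stats <- accumulate_state_stats(set, items)
  tied <- tie_states(set, stats, threshold = Inf)
  expect_equal(tied$n_tied, 20)
})

test_that("tied-state count is non-increasing in the threshold", {
  p <- fixture_profile()
  corpus <- generate_corpus(10, profile = p, seed = 22)
  items <- lapply(corpus, function(it) list(
    units = expand_units(it$motions, "tri"),
    feats = six_channel_features(it$recording)$vectors))
  X <- do.call(rbind, lapply(items, `[[`, "feats"))
  set <- make_hmm_set(unique(unlist(lapply(items, `[[`, "units"))),
                      colMeans(X), apply(X, 2, var))
  set <- baum_welch(set, items, train_config(2, 1))
  stats <- accumulate_state_stats(set, items)
  counts <- vapply(c(0, 10, 1000, 1e5, Inf), function(th)
    tie_states(set, stats, threshold = th)$n_tied, numeric(1))
  expect_true(all(diff(counts) <= 0))
  # every accepted split's gain clears the threshold
  tied <- tie_states(set, stats, threshold = 1000)
  gains <- unlist(lapply(tied$set$tying$trees, eogdeco:::collect_gains))
  if (length(gains) > 0) expect_true(all(gains >= 1000))
})

test_that("unseen units resolve through the trees to one physical model", {
  p <- fixture_profile()
  corpus <- generate_corpus(12, profile = p, seed = 23)
  items <- lapply(corpus, function(it) list(
    units = expand_units(it$motions, "tri"),
    feats = six_channel_features(it$recording)$vectors))
  X <- do.call(rbind, lapply(items, `[[`, "feats"))
  set <- make_hmm_set(unique(unlist(lapply(items, `[[`, "units"))),
                      colMeans(X), apply(X, 2, var))
  set <- baum_welch(set, items, train_config(2, 1))
  stats <- accumulate_state_stats(set, items)
  tied <- tie_states(set, stats)$set
  for (nm in c("left-up+right", "down-center+up", "right-left")) {
    r <- resolve_unit(tied, nm)
    expect_true(nm %in% names(r$units))
    expect_length(r$units[[nm]]$pdf_ids, 4)
    expect_true(all(r$units[[nm]]$pdf_ids %in% seq_along(r$pdfs)))
  }
  # tree dump renders
  expect_gt(length(format_tying_trees(tied)), 10)
})
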