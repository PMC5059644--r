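#' Desk-scale experiment harness
#'
#' Scripted reproductions of the three experimental designs on synthetic
#' data: the threshold-baseline versus HMM comparison (motion error rates),
#' the unit-kind by n-gram-order grid (character error rates), and the user
#' adaptation curves.  All runs are deterministic given the configuration
#' seed.  The absolute error rates depend on the synthetic world and are
#' not comparable to error rates measured on human recordings; the
#' qualitative orderings (context-dependent beating context-independent,
#' adaptation beating no adaptation, HMMs beating thresholding) are the
#' reproducible content.
#'
#' @name experiments
NULL

#' Experiment configuration
#'
#' Defaults are desk-scale: 5 synthetic users, a reduced character
#' vocabulary, short mixture schedules, and a test corpus rendered at two
#' noise states (the user's own noise level and an elevated one emulating
#' degraded electrode contact).
#'
#' @param n_users Number of synthetic users; default 5.
#' @param units_per_user Units of training data per user; one unit is the
#'   designed-coverage set of 22 sequences of
#'   [training_unit_sequences()]; default 10 (desk scale; the full-scale
#'   recording effort was 50 units per participant).
#' @param n_test_words Test words per user; default 10.
#' @param word_length_range Characters per test word; default `c(2, 3)`
#'   (8 to 24 motions with derived characters, the published test-set
#'   range).
#' @param n_protocol_chars Decoding vocabulary size (basic characters drawn
#'   from the default protocol, plus one derived character); default 6.
#' @param unit_kinds Unit kinds to evaluate; default all three.
#' @param ngram_orders N-gram orders (0 = no language model); default 0:3.
#' @param adaptation_amounts Units of adaptation data; default
#'   `c(0.2, 0.3, 0.5, 1, 2, 5)`.
#' @param n_repeats Repeats with resampled adaptation data; default 10.
#' @param mixture_schedule Mixture schedule for training; default 1
#'   (single Gaussians: at desk-scale data volumes larger mixtures overfit;
#'   the full-scale schedule ends at 16 components).
#' @param penalty_grid Insertion-penalty grid tuned per user on dev words
#'   before decoding; default `c(0, -50, -150, -400, -1000, -2500)`,
#'   log-spaced up to about one character's worth of acoustic score.
#' @param n_iterations EM iterations per stage; default 4.
#' @param test_noise_factors Noise multipliers for the test corpus's two
#'   noise states; default `c(1, 1.5)` (test words are recorded under the
#'   user's own conditions with mild session-to-session variation).
#' @param lm_words Synthetic training words for the n-gram models; default
#'   3000.
#' @param seed Master seed; default 1.
#' @return A list of class `eog_experiment_config`.
#' @export
experiment_config <- function(n_users = 5, units_per_user = 10,
                              n_test_words = 10,
                              word_length_range = c(2, 3),
                              n_protocol_chars = 6,
                              unit_kinds = c("mono", "bi", "tri"),
                              ngram_orders = 0:3,
                              adaptation_amounts = c(0.2, 0.3, 0.5, 1, 2, 5),
                              n_repeats = 10,
                              mixture_schedule = 1,
                              penalty_grid = c(0, -50, -150, -400, -1000, -2500),
                              n_iterations = 4,
                              test_noise_factors = c(1, 1.5),
                              lm_words = 3000,
                              seed = 1) {
  stopifnot(n_users >= 1, units_per_user >= 1,
            n_test_words >= 1, all(adaptation_amounts > 0), n_repeats >= 1)
  structure(
    list(n_users = n_users, units_per_user = units_per_user,
         n_test_words = n_test_words,
         word_length_range = word_length_range,
         n_protocol_chars = n_protocol_chars,
         unit_kinds = unit_kinds, ngram_orders = ngram_orders,
         adaptation_amounts = adaptation_amounts, n_repeats = n_repeats,
         mixture_schedule = mixture_schedule, penalty_grid = penalty_grid,
         n_iterations = n_iterations,
         test_noise_factors = test_noise_factors, lm_words = lm_words,
         seed = seed),
    class = "eog_experiment_config"
  )
}

# Reduced decoding protocol: the printed basic characters first, then
# further basic characters, plus the printed derived character /ga/.
experiment_protocol <- function(config) {
  proto <- build_default_protocol(seed = config$seed)
  basics <- unique(c(names(printed_protocol_entries()), proto$basic))
  keep <- basics[seq_len(min(config$n_protocol_chars, length(basics)))]
  subset_protocol(proto, c(keep, "ga"))
}

experiment_chars <- function(proto) sort(setdiff(names(proto$table),
                                                 proto$marks))

# A user's world: profile, training corpus, test words, and a small dev
# word set (used for insertion-penalty tuning; never the test words).
make_user <- function(config, proto, user_idx, seed) {
  profile <- sample_user_profiles(1, seed = seed)[[1]]
  train <- with_seed(seed + 1, unlist(lapply(
    seq_len(config$units_per_user), function(i)
      generate_training_unit(profile)), recursive = FALSE))
  chars <- experiment_chars(proto)
  make_words <- function(n, sub_seed) with_seed(sub_seed, {
    lapply(seq_len(n), function(w) {
      len <- sample(seq(config$word_length_range[1],
                        config$word_length_range[2]), 1)
      word <- sample(chars, len, replace = TRUE,
                     prob = 1 / seq_along(chars))
      motions <- word_to_motions(word, proto)
      noise_f <- config$test_noise_factors[
        1 + (w - 1) %% length(config$test_noise_factors)]
      p2 <- profile
      p2$noise_std <- profile$noise_std * noise_f
      list(characters = word, motions = motions,
           recording = generate_recording(motions, p2))
    })
  })
  list(profile = profile, train = train,
       test = make_words(config$n_test_words, seed + 2),
       dev = make_words(config$n_test_words, seed + 3))
}

experiment_lms <- function(config, proto) {
  chars <- experiment_chars(proto)
  corpus <- synthetic_kana_corpus(config$lm_words, chars,
                                  length_range = config$word_length_range,
                                  seed = config$seed + 77)
  lms <- list()
  for (k in setdiff(config$ngram_orders, 0))
    lms[[as.character(k)]] <- train_ngram(corpus, k, vocab = chars)
  lms
}

experiment_train_config <- function(config) {
  train_config(n_iterations = config$n_iterations,
               mixture_schedule = config$mixture_schedule)
}

decode_test_set <- function(set, graph, test, config_dec = decode_config()) {
  hyps <- lapply(test, function(it)
    suppressWarnings(
      decode(system_features(set, it$recording), graph, config_dec)))
  list(
    chars = evaluate_corpus(lapply(hyps, `[[`, "characters"),
                            lapply(test, `[[`, "characters")),
    motions = evaluate_corpus(lapply(hyps, `[[`, "motions"),
                              lapply(test, `[[`, "motions"))
  )
}

#' Baseline-versus-HMM motion recognition comparison
#'
#' For each user, trains user-dependent mono HMMs on the 2-channel and
#' 6-channel front-ends and compares their motion error rates with the
#' threshold-plus-voting baseline on the same test recordings.
#'
#' @param config An [experiment_config()].
#' @return A data frame with one row per method (`threshold`, `hmm_2ch`,
#'   `hmm_6ch`) and the pooled motion error rate over all users.
#' @export
run_baseline_comparison <- function(config = experiment_config()) {
  proto <- experiment_protocol(config)
  cfg_t <- experiment_train_config(config)
  pool <- list(threshold = list(o = list(), r = list()),
               hmm_2ch = list(o = list(), r = list()),
               hmm_6ch = list(o = list(), r = list()))
  for (u in seq_len(config$n_users)) {
    user <- make_user(config, proto, u, seed = config$seed + 1000 * u)
    thr_cfg <- threshold_config(0.5 * user$profile$amplitude_scale)
    set2 <- train_system(user$train, "mono", features = "two", config = cfg_t)
    set6 <- train_system(user$train, "mono", features = "six", config = cfg_t)
    g2 <- build_decoding_graph(set2, proto, NULL, "mono")
    g6 <- build_decoding_graph(set6, proto, NULL, "mono")
    d2 <- decode_config(insertion_penalty = tune_insertion_penalty(
      g2, user$dev, grid = config$penalty_grid)$penalty)
    d6 <- decode_config(insertion_penalty = tune_insertion_penalty(
      g6, user$dev, grid = config$penalty_grid)$penalty)
    for (it in user$test) {
      pool$threshold$o <- c(pool$threshold$o,
                            list(baseline_recognize(it$recording, thr_cfg)))
      pool$threshold$r <- c(pool$threshold$r, list(it$motions))
      h2 <- suppressWarnings(
        decode(system_features(set2, it$recording), g2, d2))
      h6 <- suppressWarnings(
        decode(system_features(set6, it$recording), g6, d6))
      pool$hmm_2ch$o <- c(pool$hmm_2ch$o, list(h2$motions))
      pool$hmm_2ch$r <- c(pool$hmm_2ch$r, list(it$motions))
      pool$hmm_6ch$o <- c(pool$hmm_6ch$o, list(h6$motions))
      pool$hmm_6ch$r <- c(pool$hmm_6ch$r, list(it$motions))
    }
  }
  data.frame(
    method = names(pool),
    motion_error_rate = vapply(pool, function(p)
      evaluate_corpus(p$o, p$r)$rate, numeric(1)),
    row.names = NULL
  )
}

#' Unit-kind by n-gram-order recognition grid
#'
#' Trains user-dependent systems for each requested unit kind, decodes the
#' users' test words with each n-gram order (0 = no language model), and
#' pools character error rates over users.  Also reports the relative CER
#' reduction of the best context-dependent unit over the mono unit at each
#' order.
#'
#' @param config An [experiment_config()].
#' @return A list with `cer` (data frame unit_kind x ngram_order -> CER)
#'   and `relative_reduction` (data frame per order).
#' @export
run_unit_comparison <- function(config = experiment_config()) {
  proto <- experiment_protocol(config)
  lms <- experiment_lms(config, proto)
  cfg_t <- experiment_train_config(config)
  cells <- expand.grid(unit_kind = config$unit_kinds,
                       order = config$ngram_orders,
                       stringsAsFactors = FALSE)
  pool_o <- replicate(nrow(cells), list(), simplify = FALSE)
  pool_r <- replicate(nrow(cells), list(), simplify = FALSE)
  for (u in seq_len(config$n_users)) {
    user <- make_user(config, proto, u, seed = config$seed + 1000 * u)
    for (kind in unique(cells$unit_kind)) {
      set <- train_system(user$train, kind, config = cfg_t)
      g0 <- build_decoding_graph(set, proto, NULL, kind)
      # standard decoding practice: tune the insertion penalty per user
      # and system on held-out dev words, never on the test words
      pen <- tune_insertion_penalty(g0, user$dev,
                                    grid = config$penalty_grid)$penalty
      dcfg <- decode_config(insertion_penalty = pen)
      for (ord in unique(cells$order)) {
        graph <- if (ord == 0) g0 else
          build_decoding_graph(set, proto, lms[[as.character(ord)]], kind)
        i <- which(cells$unit_kind == kind & cells$order == ord)
        for (it in user$test) {
          hyp <- suppressWarnings(
            decode(system_features(set, it$recording), graph, dcfg))
          pool_o[[i]] <- c(pool_o[[i]], list(hyp$characters))
          pool_r[[i]] <- c(pool_r[[i]], list(it$characters))
        }
      }
    }
  }
  cells$cer <- vapply(seq_len(nrow(cells)), function(i)
    evaluate_corpus(pool_o[[i]], pool_r[[i]])$rate, numeric(1))
  rr <- NULL
  if ("mono" %in% cells$unit_kind) {
    rr <- do.call(rbind, lapply(unique(cells$order), function(ord) {
      mono <- cells$cer[cells$unit_kind == "mono" & cells$order == ord]
      best_kind <- setdiff(unique(cells$unit_kind), "mono")
      if (length(best_kind) == 0 || mono <= 0) return(NULL)
      best <- min(cells$cer[cells$unit_kind %in% best_kind &
                              cells$order == ord])
      data.frame(order = ord, mono_cer = mono, best_context_cer = best,
                 relative_reduction = relative_reduction(mono, best))
    }))
  }
  list(cer = cells, relative_reduction = rr)
}

#' User adaptation curves
#'
#' For each target user, trains a user-independent tri system on the other
#' users' data, then evaluates no adaptation, MLLR, MAP, and MAP plus
#' insertion-penalty tuning at each adaptation amount, with `n_repeats`
#' resampled adaptation subsets, pooling CERs over targets and repeats.
#'
#' @param config An [experiment_config()].
#' @param ngram_order N-gram order for decoding; default 3.
#' @param unit_kind Unit kind of the systems; default `"tri"`.
#' @param penalty_grid Insertion-penalty grid for tuning; defaults to the
#'   configuration's grid.
#' @param n_targets Number of target users (cycled from the user list);
#'   default all users.
#' @return A data frame: method x amount -> mean CER (over targets and
#'   repeats).
#' @export
run_adaptation_curve <- function(config = experiment_config(),
                                 ngram_order = 3, unit_kind = "tri",
                                 penalty_grid = config$penalty_grid,
                                 n_targets = config$n_users) {
  stopifnot(config$n_users >= 2)
  proto <- experiment_protocol(config)
  lms <- if (ngram_order > 0) {
    cfg2 <- config; cfg2$ngram_orders <- ngram_order
    experiment_lms(cfg2, proto)
  } else list()
  lm <- if (ngram_order > 0) lms[[as.character(ngram_order)]] else NULL
  cfg_t <- experiment_train_config(config)
  users <- lapply(seq_len(config$n_users), function(u)
    make_user(config, proto, u, seed = config$seed + 1000 * u))

  methods <- c("no_adapt", "mllr", "map", "map_inspen")
  rows <- list()
  for (tgt in seq_len(min(n_targets, config$n_users))) {
    ui_train <- unlist(lapply(users[-tgt], `[[`, "train"), recursive = FALSE)
    ui_set <- train_system(ui_train, unit_kind, config = cfg_t)
    target <- users[[tgt]]
    ui_graph <- build_decoding_graph(ui_set, proto, lm, unit_kind)
    base_res <- decode_test_set(ui_set, ui_graph, target$test)

    for (amount in config$adaptation_amounts) {
      n_seq <- max(1L, round(amount * 22))
      for (rep_i in seq_len(config$n_repeats)) {
        adapt_data <- with_seed(
          config$seed + 13 * tgt + 101 * rep_i + round(1000 * amount),
          target$train[sample(length(target$train),
                              min(n_seq, length(target$train)))])
        res <- list(no_adapt = base_res$chars$rate)
        ml_set <- mllr_adapt(ui_set, adapt_data)
        g <- build_decoding_graph(ml_set, proto, lm, unit_kind)
        res$mllr <- decode_test_set(ml_set, g, target$test)$chars$rate
        mp_set <- map_adapt(ui_set, adapt_data)
        g <- build_decoding_graph(mp_set, proto, lm, unit_kind)
        res$map <- decode_test_set(mp_set, g, target$test)$chars$rate
        tuned <- tune_insertion_penalty(g, target$dev,
                                        grid = penalty_grid)
        res$map_inspen <- decode_test_set(
          mp_set, g, target$test,
          decode_config(insertion_penalty = tuned$penalty))$chars$rate
        for (m in methods) {
          rows[[length(rows) + 1]] <- data.frame(
            target = tgt, amount = amount, repeat_i = rep_i, method = m,
            cer = res[[m]])
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  agg <- stats::aggregate(cer ~ method + amount, df, mean)
  agg[order(agg$method, agg$amount), ]
}
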