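#' Backoff character n-gram language models
#'
#' Character n-grams over the Kana vocabulary (default size 70), used to
#' rescore decoder hypotheses at character boundaries.  The default
#' smoothing is interpolated Witten-Bell:
#' `P(w | h) = c(h)/(c(h)+T(h)) * ML(w | h) + T(h)/(c(h)+T(h)) * P(w | h-)`
#' where `c(h)` is the history count, `T(h)` the number of distinct
#' continuations of `h`, and `h-` the history shortened by one symbol; the
#' recursion bottoms out at the uniform distribution 1/V.  This form is
#' exactly normalized and maps directly onto the ARPA backoff format with
#' back-off weight `bow(h) = T(h)/(c(h)+T(h))`.
#'
#' @name char_ngram
NULL

BOS <- "<s>"
EOS <- "</s>"
ROOT <- "<root>"   # sentinel key for the empty (unigram) history

ng_key <- function(syms) paste(syms, collapse = " ")

count_ngrams <- function(corpus, order, include_end = TRUE) {
  counts <- vector("list", order)
  for (k in seq_len(order)) counts[[k]] <- new.env(parent = emptyenv())
  for (sent in corpus) {
    syms <- c(rep(BOS, order - 1), sent, if (include_end) EOS)
    n <- length(syms)
    if (n < order) next
    for (i in seq.int(order, n)) {   # skip the <s> padding positions
      if (syms[i] == BOS) next
      for (k in seq_len(order)) {
        if (i - k + 1 < 1) break
        key <- ng_key(syms[(i - k + 1):i])
        e <- counts[[k]]
        e[[key]] <- (if (is.null(e[[key]])) 0L else e[[key]]) + 1L
      }
    }
  }
  lapply(counts, as.list)
}

#' Train a character n-gram model
#'
#' @param corpus List of character vectors (sequences of character labels),
#'   or a single character vector treated as one sequence.
#' @param order Model order N in 1..3 (higher orders work but are untested
#'   at scale).
#' @param smoothing `"witten_bell"` (default, interpolated) or `"none"`
#'   (maximum likelihood; unseen events have probability zero).
#' @param vocab Optional character vector fixing the vocabulary; defaults to
#'   the symbols observed in the corpus.  The end-of-sequence symbol is
#'   always included.
#' @param include_end If `TRUE` (default), each sequence is terminated with
#'   an end symbol that the model predicts.
#' @return An object of class `char_ngram`.
#' @export
train_ngram <- function(corpus, order, smoothing = c("witten_bell", "none"),
                        vocab = NULL, include_end = TRUE) {
  smoothing <- match.arg(smoothing)
  if (order < 1) stop("order must be >= 1")
  if (is.character(corpus)) corpus <- list(corpus)
  if (length(corpus) == 0 || all(lengths(corpus) == 0))
    stop("corpus is empty")
  if (is.null(vocab)) vocab <- sort(unique(unlist(corpus)))
  if (any(c(BOS, EOS) %in% unlist(corpus)))
    stop("corpus must not contain the reserved symbols <s>, </s>")
  vocab <- setdiff(unique(vocab), c(BOS, EOS))
  pred_vocab <- c(vocab, if (include_end) EOS)
  V <- length(pred_vocab)

  counts <- count_ngrams(corpus, order, include_end)

  logp <- vector("list", order)   # named numeric: key "h w" -> log P(w|h)
  bows <- vector("list", order)   # named numeric: key "h" -> log bow(h)
  # probability of w given history of length k-1, computed bottom-up
  prob_of <- function(k, key_hist, w) {
    # interpolated probability at level k (1 = unigram)
    if (k == 0) return(1 / V)
    key <- if (k == 1) w else paste(key_hist, w)
    p <- logp[[k]][[key]]
    if (!is.null(p)) return(exp(p))
    lam <- bow_of(k, key_hist)
    lam * prob_of(k - 1, drop_first(key_hist), w)
  }
  drop_first <- function(key_hist) {
    if (is.null(key_hist) || !nzchar(key_hist)) return("")
    parts <- strsplit(key_hist, " ", fixed = TRUE)[[1]]
    if (length(parts) <= 1) "" else ng_key(parts[-1])
  }
  bow_of <- function(k, key_hist) {
    if (smoothing == "none") return(0)
    b <- bows[[k]][[if (k == 1) ROOT else key_hist]]
    if (is.null(b)) 1 else exp(b)   # unseen history: all mass backs off
  }

  for (k in seq_len(order)) {
    ck <- counts[[k]]
    keys <- names(ck)
    if (length(keys) == 0) { logp[[k]] <- list(); bows[[k]] <- list(); next }
    parts <- strsplit(keys, " ", fixed = TRUE)
    hist_keys <- vapply(parts, function(p)
      if (length(p) == 1) ROOT else ng_key(p[-length(p)]), character(1))
    targets <- vapply(parts, function(p) p[length(p)], character(1))
    cnt <- unlist(ck, use.names = FALSE)
    hist_tot <- tapply(cnt, hist_keys, sum)
    hist_typ <- tapply(rep(1L, length(cnt)), hist_keys, sum)

    lp <- new.env(parent = emptyenv())
    bw <- new.env(parent = emptyenv())
    for (h in names(hist_tot)) {
      c_h <- hist_tot[[h]]; t_h <- hist_typ[[h]]
      lam <- if (smoothing == "witten_bell") t_h / (c_h + t_h) else 0
      bw[[h]] <- if (lam > 0) log(lam) else -Inf
    }
    for (i in seq_along(keys)) {
      h <- hist_keys[i]; w <- targets[i]
      c_h <- hist_tot[[h]]; t_h <- hist_typ[[h]]
      if (smoothing == "witten_bell") {
        lower <- prob_of(k - 1, drop_first(h), w)
        p <- cnt[i] / (c_h + t_h) + (t_h / (c_h + t_h)) * lower
      } else {
        p <- cnt[i] / c_h
      }
      lp[[keys[i]]] <- log(p)
    }
    logp[[k]] <- as.list(lp)
    bows[[k]] <- as.list(bw)
  }

  # probability of an unseen symbol at the unigram level: escape mass times
  # uniform (the ARPA open-vocabulary <unk> convention)
  b0 <- bows[[1]][[ROOT]]
  unk_log <- if (smoothing == "witten_bell" && !is.null(b0)) b0 - log(V) else -Inf
  structure(
    list(order = as.integer(order), vocab = vocab, smoothing = smoothing,
         include_end = include_end, logp = logp, bows = bows,
         unk_log = unk_log),
    class = "char_ngram"
  )
}

#' Conditional log-probability under a character n-gram
#'
#' @param model A `char_ngram`.
#' @param symbol The predicted symbol (a character label or `"</s>"`).
#' @param history Character vector of preceding symbols (may be empty; use
#'   `"<s>"` padding for sentence-initial context or pass the bare prefix —
#'   the model truncates to its order).
#' @return Natural log probability (can be `-Inf` without smoothing).
#' @export
lm_logprob <- function(model, symbol, history = character(0)) {
  stopifnot(inherits(model, "char_ngram"))
  n_hist <- model$order - 1
  if (length(history) > n_hist)
    history <- utils::tail(history, n_hist)
  k <- length(history) + 1
  repeat {
    key <- ng_key(c(history, symbol))
    p <- model$logp[[k]][[key]]
    if (!is.null(p)) return(p)
    if (k == 1) return(model$unk_log)  # unseen at the unigram level
    hkey <- ng_key(history)
    b <- model$bows[[k]][[hkey]]
    if (is.null(b)) b <- 0          # unseen history: full backoff
    if (model$smoothing == "none" || identical(b, -Inf)) {
      if (model$smoothing == "none") return(-Inf)
    }
    history <- history[-1]
    k <- k - 1
    if (!identical(b, 0)) {
      rest <- lm_logprob(model,  symbol, history)
      return(b + rest)
    }
  }
}

#' Log-probability of a full sequence
#'
#' Sums `lm_logprob` over the sequence with `<s>` initial context and, if
#' the model was trained with end symbols and `include_end` is `TRUE`, the
#' final `</s>` event.
#'
#' @param model A `char_ngram`.
#' @param text Character vector of symbols.
#' @param include_end Whether to score the end-of-sequence event; defaults
#'   to the model's training setting.
#' @return List with `logprob` (total natural log) and `n_events`.
#' @export
lm_sequence_logprob <- function(model, text, include_end = model$include_end) {
  stopifnot(length(text) > 0)
  syms <- c(rep(BOS, model$order - 1), text, if (include_end) EOS)
  idx <- (model$order):length(syms)
  if (model$order == 1) idx <- seq_along(syms)
  total <- 0
  n_ev <- 0L
  for (i in idx) {
    if (syms[i] == BOS) next
    h <- if (model$order > 1) syms[max(1, i - model$order + 1):(i - 1)] else character(0)
    total <- total + lm_logprob(model, syms[i], h)
    n_ev <- n_ev + 1L
  }
  list(logprob = total, n_events = n_ev)
}

#' Perplexity of text under a character n-gram
#'
#' `exp(-mean log P)` per predicted symbol.  Without smoothing a
#' zero-probability event yields `+Inf` with a warning.
#'
#' @param model A `char_ngram`.
#' @param text Character vector of symbols (non-empty).
#' @param include_end Whether the end-of-sequence event is scored.
#' @return Perplexity (>= 1; lower is better).
#' @export
perplexity <- function(model, text, include_end = model$include_end) {
  if (length(text) == 0) stop("text is empty")
  r <- lm_sequence_logprob(model, text, include_end)
  if (!is.finite(r$logprob)) {
    warning("zero-probability event; perplexity is infinite")
    return(Inf)
  }
  exp(-r$logprob / r$n_events)
}

#' Perplexity over a corpus of sequences
#'
#' Pools the log-probabilities and event counts of every sequence (each
#' with its own sentence-boundary context) and reports the corpus-level
#' perplexity.
#'
#' @param model A `char_ngram`.
#' @param corpus List of character vectors.
#' @param include_end Whether end-of-sequence events are scored.
#' @return Perplexity over all pooled events.
#' @export
perplexity_corpus <- function(model, corpus,
                              include_end = model$include_end) {
  stopifnot(length(corpus) > 0)
  total <- 0; n_ev <- 0L
  for (s in corpus) {
    r <- lm_sequence_logprob(model, s, include_end)
    total <- total + r$logprob
    n_ev <- n_ev + r$n_events
  }
  if (!is.finite(total)) {
    warning("zero-probability event; perplexity is infinite")
    return(Inf)
  }
  exp(-total / n_ev)
}

#' Generate a synthetic Kana training corpus
#'
#' Stands in for a large Kana text corpus, which is licensed and not
#' shipped: character sequences are sampled from a seeded first-order Markov
#' chain whose conditional distributions are Zipf weights (1/rank) over a
#' per-predecessor random permutation of the inventory.  Marginals are
#' Zipf-like and there is genuine bigram structure for higher-order models
#' to exploit.
#'
#' @param n_words Number of sequences to generate.
#' @param chars Character inventory (default: the 70-character Kana
#'   inventory of [kana_vocabulary()]).
#' @param length_range Word length range in characters; default `c(2, 5)`.
#' @param seed Integer seed.
#' @return List of character vectors.
#' @export
synthetic_kana_corpus <- function(n_words, chars = kana_vocabulary(),
                                  length_range = c(2, 5), seed = NULL) {
  stopifnot(n_words >= 0, length_range[1] >= 1)
  V <- length(chars)
  with_seed(seed, {
    zipf <- (1 / seq_len(V))
    # per-predecessor permuted Zipf conditionals (row 0 = sentence start)
    perm <- lapply(0:V, function(i) sample.int(V))
    draw <- function(prev_idx) {
      w <- zipf[order(perm[[prev_idx + 1]])]
      sample.int(V, 1, prob = w)
    }
    lapply(seq_len(n_words), function(i) {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      out <- integer(len)
      prev <- 0L
      for (j in seq_len(len)) {
        out[j] <- draw(prev)
        prev <- out[j]
      }
      chars[out]
    })
  })
}

#' The default 70-character Kana inventory
#'
#' The 48 basic characters plus the first 22 derived (voiced) characters:
#' 70 symbols in total, the size of the Kana character set used as the
#' language-model vocabulary.
#'
#' @return Character vector of length 70.
#' @export
kana_vocabulary <- function() {
  derived <- c(unname(dakuten_map()), unname(handakuten_map()))
  c(basic_kana_names(), derived[seq_len(22)])
}

#' Write a model in ARPA format
#'
#' Standard backoff-LM interchange format: log10 probabilities and back-off
#' weights, `\\data\\` header with n-gram counts, one section per order.
#'
#' @param model A `char_ngram`.
#' @param path Output path.
#' @export
write_arpa <- function(model, path) {
  stopifnot(inherits(model, "char_ngram"))
  fmt <- function(x) {
    if (identical(x, -Inf)) "-99" else sprintf("%.17g", x / log(10))
  }
  sections <- vector("list", model$order)
  for (k in seq_len(model$order)) {
    keys <- names(model$logp[[k]])
    # histories of (k+1)-grams must appear at order k to carry their
    # back-off weight, even when never predicted themselves (e.g. <s>)
    if (k < model$order) keys <- union(keys, names(model$bows[[k + 1]]))
    if (k == 1) {
      keys <- setdiff(keys, "")                 # empty history: see <unk>
      if (is.finite(model$unk_log)) keys <- union(keys, "<unk>")
    }
    rows <- vapply(sort(keys), function(key) {
      lp <- if (key == "<unk>") model$unk_log else model$logp[[k]][[key]]
      row <- paste0(if (is.null(lp)) "-99" else fmt(lp), "\t", key)
      if (k < model$order && key != "<unk>") {
        b <- model$bows[[k + 1]][[key]]
        if (!is.null(b) && is.finite(b)) row <- paste0(row, "\t", fmt(b))
      }
      row
    }, character(1))
    sections[[k]] <- rows
  }
  lines <- "\\data\\"
  for (k in seq_len(model$order))
    lines <- c(lines, sprintf("ngram %d=%d", k, length(sections[[k]])))
  for (k in seq_len(model$order))
    lines <- c(lines, "", sprintf("\\%d-grams:", k), sections[[k]])
  lines <- c(lines, "", "\\end\\")
  writeLines(lines, path)
  invisible(path)
}

#' Read an ARPA language model
#'
#' Reads models written by [write_arpa()] (and standard ARPA files over
#' whitespace-free symbols).  Back-off weights attach to the history entry
#' one order below, as in the ARPA convention.
#'
#' @param path ARPA file path.
#' @param smoothing Tag recorded on the model; `"witten_bell"` by default.
#' @param include_end Whether `</s>` events are scored by default.
#' @return A `char_ngram`.
#' @export
read_arpa <- function(path, smoothing = "witten_bell", include_end = TRUE) {
  lines <- readLines(path)
  counts <- integer(0)
  i <- match("\\data\\", lines)
  if (is.na(i)) stop("not an ARPA file: missing \\data\\ header")
  i <- i + 1
  while (grepl("^ngram ", lines[i])) {
    counts <- c(counts, as.integer(sub("^ngram \\d+=", "", lines[i])))
    i <- i + 1
  }
  order <- length(counts)
  logp <- lapply(seq_len(order), function(k) list())
  bows <- lapply(seq_len(order), function(k) list())
  unk_log <- -Inf
  for (k in seq_len(order)) {
    hdr <- sprintf("\\%d-grams:", k)
    j <- match(hdr, lines)
    if (is.na(j)) stop("missing section ", hdr)
    j <- j + 1
    lp <- new.env(parent = emptyenv()); bw <- new.env(parent = emptyenv())
    while (j <= length(lines) && nzchar(trimws(lines[j])) &&
           !startsWith(lines[j], "\\")) {
      fields <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
      p10 <- as.numeric(fields[1])
      syms <- fields[2:(k + 1)]
      lpval <- if (p10 <= -99) -Inf else p10 * log(10)
      if (k == 1 && syms == "<unk>") {
        unk_log <- lpval
      } else if (is.finite(lpval)) {
        lp[[ng_key(syms)]] <- lpval
      }
      if (length(fields) > k + 1 && !(k == 1 && syms == "<unk>")) {
        bw[[ng_key(syms)]] <- as.numeric(fields[k + 2]) * log(10)
      }
      j <- j + 1
    }
    logp[[k]] <- as.list(lp)
    if (k < order) bows[[k + 1]] <- as.list(bw)
  }
  vocab <- setdiff(names(logp[[1]]), c(BOS, EOS, "<unk>"))
  structure(
    list(order = order, vocab = vocab, smoothing = smoothing,
         include_end = include_end, logp = logp, bows = bows,
         unk_log = unk_log),
    class = "char_ngram"
  )
}

#' @export
print.char_ngram <- function(x, ...) {
  cat(sprintf("Character %d-gram (%s smoothing), vocabulary %d\n",
              x$order, x$smoothing, length(x$vocab)))
  invisible(x)
}
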