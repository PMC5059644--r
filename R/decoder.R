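#' Continuous character decoding
#'
#' Composes the trained unit HMMs with the input protocol's character codes
#' and an optional character n-gram into a single search graph, and runs
#' exact Viterbi (token passing) over it.  Each character expands to the
#' chain of its motion units; for context-dependent units the boundary
#' units are expanded into variants so that the last unit of one character
#' and the first unit of the next receive each other's motions as context.
#' Language-model scores and the per-character insertion penalty are kept
#' as separate arc components, so the same graph topology serves all
#' n-gram orders and decode settings.
#'
#' @name decoder
NULL

#' Decoding configuration
#'
#' @param lm_weight Language-model scale (>= 0); default 1.
#' @param insertion_penalty Additive log-domain score per emitted character
#'   (typically <= 0; more negative means fewer output characters).
#' @param beam Viterbi pruning beam (log width); `Inf` (default) is exact
#'   search.
#' @return A list of class `eog_decode_config`.
#' @export
decode_config <- function(lm_weight = 1, insertion_penalty = 0, beam = Inf) {
  stopifnot(lm_weight >= 0, beam > 0)
  structure(
    list(lm_weight = lm_weight, insertion_penalty = insertion_penalty,
         beam = beam),
    class = "eog_decode_config"
  )
}

# Find a usable model for a decoding unit: exact, tying-tree synthesis,
# then context-stripped backoff down to the mono unit.
resolve_decoding_unit <- function(set, name) {
  if (name %in% names(set$units)) return(list(set = set, name = name))
  if (!is.null(set$tying)) {
    pu <- parse_unit_name(name)
    key1 <- paste(pu$target, 1, sep = "/")
    if (!is.null(set$tying$trees[[key1]]))
      return(list(set = resolve_unit(set, name), name = name))
  }
  pu <- parse_unit_name(name)
  for (cand in c(make_unit_name(pu$target, left = pu$left),
                 make_unit_name(pu$target, right = pu$right),
                 pu$target)) {
    if (!is.na(cand) && cand %in% names(set$units))
      return(list(set = set, name = cand))
  }
  stop("cannot resolve decoding unit '", name, "'")
}

# Unit name for character position i of code m under the given unit kind
# and boundary contexts (NA = utterance boundary).
position_unit_name <- function(m, i, kind, left_ctx = NA, right_ctx = NA) {
  k <- length(m)
  if (kind == "mono") return(m[i])
  left <- if (i > 1) m[i - 1] else left_ctx
  if (kind == "bi") return(make_unit_name(m[i], left = left))
  right <- if (i < k) m[i + 1] else right_ctx
  make_unit_name(m[i], left = left, right = right)
}

#' Build a character decoding graph
#'
#' @param set A trained `eog_hmm_set` (tied for tri units).
#' @param proto An `eog_protocol`; its basic and derived characters form
#'   the decoding vocabulary (standalone marks are not output symbols).
#' @param lm Optional `char_ngram`; `NULL` decodes without a language model
#'   (0-gram).
#' @param unit_kind `"mono"`, `"bi"`, or `"tri"`.
#' @param use_sil Allow an optional "sil" model at the utterance
#'   boundaries; defaults to whether the set contains one.
#' @return An object of class `eog_decode_graph` (an `eog_graph` plus the
#'   language-model and insertion-score components and the resolved model
#'   set).
#' @export
build_decoding_graph <- function(set, proto, lm = NULL,
                                 unit_kind = c("tri", "bi", "mono"),
                                 use_sil = "sil" %in% names(set$units)) {
  unit_kind <- match.arg(unit_kind)
  stopifnot(inherits(set, "eog_hmm_set"), inherits(proto, "eog_protocol"))
  if (!is.null(lm)) stopifnot(inherits(lm, "char_ngram"))

  chars <- sort(setdiff(names(proto$table), proto$marks))
  if (length(chars) == 0) stop("protocol has no decodable characters")
  codes <- lapply(proto$table[chars], identity)
  first_m <- vapply(codes, `[`, character(1), 1)
  last_m <- vapply(codes, function(x) x[length(x)], character(1))

  entry_ctxs <- if (unit_kind == "mono") "*" else c("<none>", unique(last_m))
  exit_ctxs <- if (unit_kind == "tri") c("<none>", unique(first_m)) else "*"

  # language-model histories (BFS over reachable truncated histories);
  # "<0>" is the sentinel for the empty history of 0/1-gram decoding
  # (R lists cannot be indexed by an empty-string name)
  order <- if (is.null(lm)) 0L else lm$order
  h0 <- if (order >= 2) ng_key(rep(BOS, order - 1)) else "<0>"
  hist_syms <- function(hkey) {
    if (hkey == "<0>" || !nzchar(hkey)) character(0)
    else strsplit(hkey, " ", fixed = TRUE)[[1]]
  }
  shift_hist <- function(hkey, c) {
    if (order < 2) return("<0>")
    ng_key(utils::tail(c(hist_syms(hkey), c), order - 1))
  }
  hists <- h0
  frontier <- h0
  while (length(frontier) > 0) {
    nxt <- unique(unlist(lapply(frontier, function(h)
      vapply(chars, shift_hist, character(1), hkey = h))))
    nxt <- setdiff(nxt, hists)
    hists <- c(hists, nxt)
    frontier <- nxt
  }

  lm_score <- function(c_or_eos, hkey) {
    if (is.null(lm)) return(0)
    lm_logprob(lm, c_or_eos, hist_syms(hkey))
  }

  # resolve every needed unit up front (possibly augmenting the set)
  need <- character(0)
  for (c in chars) {
    m <- codes[[c]]; k <- length(m)
    for (ec in entry_ctxs) {
      lc <- if (ec %in% c("*", "<none>")) NA else ec
      need <- c(need, position_unit_name(m, 1, unit_kind, left_ctx = lc))
    }
    if (k > 2)
      for (i in 2:(k - 1))
        need <- c(need, position_unit_name(m, i, unit_kind))
    for (xc in exit_ctxs) {
      rc <- if (xc %in% c("*", "<none>")) NA else xc
      need <- c(need, position_unit_name(m, k, unit_kind, right_ctx = rc))
    }
  }
  resolved <- list()
  for (nm in unique(need)) {
    r <- resolve_decoding_unit(set, nm)
    set <- r$set
    resolved[[nm]] <- r$name
  }

  # ---- assemble states and arcs ----------------------------------------
  pdf_ids <- integer(0); state_unit_name <- character(0)
  n <- set$n_states
  af <- list(); at <- list(); alp <- list(); alm <- list(); ains <- list()
  aout <- list()
  n_states_total <- 0L

  add_block <- function(unit_name) {
    # returns c(first_state, last_state, exit_logp); appends loop arcs
    real <- resolved[[unit_name]]
    if (is.null(real)) real <- unit_name   # sil and pre-resolved names
    unit <- set$units[[real]]
    base <- n_states_total
    pdf_ids <<- c(pdf_ids, unit$pdf_ids)
    state_unit_name <<- c(state_unit_name, rep(real, n))
    lt <- log(unit$trans)
    from <- integer(0); to <- integer(0); lp <- numeric(0)
    for (s in seq_len(n)) {
      if (is.finite(lt[s, s])) {
        from <- c(from, base + s); to <- c(to, base + s)
        lp <- c(lp, lt[s, s])
      }
      if (s < n && is.finite(lt[s, s + 1])) {
        from <- c(from, base + s); to <- c(to, base + s + 1)
        lp <- c(lp, lt[s, s + 1])
      }
    }
    push_arcs(from, to, lp)
    n_states_total <<- base + n
    c(base + 1L, base + n, lt[n, n + 1])
  }
  push_arcs <- function(from, to, lp, lmv = 0, ins = 0, out = NA_character_) {
    i <- length(af) + 1L
    af[[i]] <<- from; at[[i]] <<- to; alp[[i]] <<- lp
    alm[[i]] <<- rep_len(lmv, length(from))
    ains[[i]] <<- rep_len(ins, length(from))
    aout[[i]] <<- rep_len(out, length(from))
  }

  # instance bookkeeping: blocks[[hist]][[char]] = list(entry = named list
  # lc -> block, exit = named list rc -> block)
  instances <- list()
  for (h in hists) {
    instances[[h]] <- list()
    for (c in chars) {
      m <- codes[[c]]; k <- length(m)
      entry <- list()
      for (ec in entry_ctxs) {
        lc <- if (ec %in% c("*", "<none>")) NA else ec
        entry[[ec]] <- add_block(
          position_unit_name(m, 1, unit_kind, left_ctx = lc))
      }
      mids <- list()
      if (k > 2)
        for (i in 2:(k - 1))
          mids[[i - 1]] <- add_block(position_unit_name(m, i, unit_kind))
      exit <- list()
      for (xc in exit_ctxs) {
        rc <- if (xc %in% c("*", "<none>")) NA else xc
        exit[[xc]] <- add_block(
          position_unit_name(m, k, unit_kind, right_ctx = rc))
      }
      # chain: every entry variant -> first mid (or every exit variant)
      next_first <- if (k > 2) mids[[1]][1] else NA
      for (ec in names(entry)) {
        b <- entry[[ec]]
        if (!is.na(next_first)) {
          push_arcs(b[2], next_first, b[3])
        } else {
          for (xc in names(exit)) push_arcs(b[2], exit[[xc]][1], b[3])
        }
      }
      if (k > 2) {
        if (length(mids) > 1)
          for (i in seq_len(length(mids) - 1))
            push_arcs(mids[[i]][2], mids[[i + 1]][1], mids[[i]][3])
        lastmid <- mids[[length(mids)]]
        for (xc in names(exit))
          push_arcs(lastmid[2], exit[[xc]][1], lastmid[3])
      }
      instances[[h]][[c]] <- list(entry = entry, exit = exit)
    }
  }

  sil_start <- NULL; sil_end <- NULL
  if (use_sil) {
    sil_start <- add_block(sil_label())
    sil_end <- add_block(sil_label())
  }

  # cross-character arcs, start and final vectors
  start <- rep(-Inf, n_states_total); start_lm <- rep(0, n_states_total)
  start_ins <- rep(0, n_states_total)
  start_out <- rep(NA_character_, n_states_total)
  final_lp <- rep(-Inf, n_states_total); final_lm <- rep(0, n_states_total)

  entry_key <- function(c_prev) {
    if (unit_kind == "mono") "*" else c_prev  # last motion key or "*"
  }
  for (h in hists) {
    for (c in chars) {
      inst <- instances[[h]][[c]]
      h_next <- shift_hist(h, c)
      eos_lm <- if (!is.null(lm) && lm$include_end)
        lm_score(EOS, ng_key(c(hist_syms(h), c))) else 0
      for (xc in names(inst$exit)) {
        b <- inst$exit[[xc]]
        if (xc %in% c("<none>", "*")) {
          # utterance end: directly final, or via trailing sil
          final_lp[b[2]] <- b[3]
          final_lm[b[2]] <- eos_lm
          if (use_sil) {
            push_arcs(b[2], sil_end[1], b[3], lmv = eos_lm)
          }
        }
        if (xc != "<none>") {
          succ <- if (unit_kind == "tri") chars[first_m == xc] else chars
          for (c2 in succ) {
            inst2 <- instances[[h_next]][[c2]]
            ek <- if (unit_kind == "mono") "*" else last_m[[c]]
            b2 <- inst2$entry[[ek]]
            lmv <- lm_score(c2, ng_key(c(hist_syms(h), c)))
            push_arcs(b[2], b2[1], b[3], lmv = lmv, ins = 1, out = c2)
          }
        }
      }
    }
  }
  # utterance starts (history h0): entry with no left context
  ek0 <- if (unit_kind == "mono") "*" else "<none>"
  for (c in chars) {
    b <- instances[[h0]][[c]]$entry[[ek0]]
    lmv <- lm_score(c, h0)
    start[b[1]] <- 0
    start_lm[b[1]] <- lmv
    start_ins[b[1]] <- 1
    start_out[b[1]] <- c
    if (use_sil)
      push_arcs(sil_start[2], b[1], sil_start[3], lmv = lmv, ins = 1,
                out = c)
  }
  if (use_sil) {
    start[sil_start[1]] <- 0
    final_lp[sil_end[2]] <- sil_end[3]
  }

  graph <- structure(
    list(
      pdf_ids = pdf_ids, start = start, final = final_lp,
      arc_from = unlist(af), arc_to = unlist(at), arc_logp = unlist(alp),
      arc_lm = unlist(alm), arc_ins = unlist(ains), arc_out = unlist(aout),
      start_lm = start_lm, start_ins = start_ins, start_out = start_out,
      final_lm = final_lm,
      state_unit = rep(NA_integer_, n_states_total),
      state_pos = rep(NA_integer_, n_states_total),
      unit_names = unique(state_unit_name),
      state_unit_name = state_unit_name,
      unit_kind = unit_kind, chars = chars,
      char_motions = codes, set = set
    ),
    class = c("eog_decode_graph", "eog_graph")
  )
  graph
}

#' @export
print.eog_decode_graph <- function(x, ...) {
  cat(sprintf(
    "Decoding graph: %d characters (%s units), %d states, %d arcs\n",
    length(x$chars), x$unit_kind, length(x$pdf_ids), length(x$arc_from)))
  invisible(x)
}

#' Decode an observation sequence to a character hypothesis
#'
#' Exact Viterbi search over the decoding graph; the hypothesis score is
#' acoustic + `lm_weight` x language model + `insertion_penalty` x number
#' of characters.
#'
#' @param feats An `eog_features` object or T x d matrix.
#' @param graph An `eog_decode_graph` from [build_decoding_graph()].
#' @param config An [decode_config()].
#' @return A list of class `eog_hypothesis`: `characters`, `motions` (the
#'   concatenated protocol codes), `log_score`, and `no_path` flag.
#' @export
decode <- function(feats, graph, config = decode_config()) {
  stopifnot(inherits(graph, "eog_decode_graph"),
            inherits(config, "eog_decode_config"))
  set <- graph$set
  X <- feature_matrix(set, feats)
  lo <- graph_logobs(set, graph, X)
  lw <- config$lm_weight; ip <- config$insertion_penalty
  eff <- graph$arc_logp + lw * graph$arc_lm + ip * graph$arc_ins
  eff_start <- graph$start + lw * graph$start_lm + ip * graph$start_ins
  eff_final <- graph$final + lw * graph$final_lm
  r <- viterbi_cpp(lo$logobs, lo$pdf0, eff_start, eff_final,
                   graph$arc_from - 1L, graph$arc_to - 1L, eff,
                   beam = config$beam)
  if (!is.finite(r$score) || length(r$path) == 0) {
    warning("no complete decoding path")
    return(structure(
      list(characters = character(0), motions = character(0),
           log_score = -Inf, no_path = TRUE),
      class = "eog_hypothesis"))
  }
  chars <- character(0)
  s0 <- r$path[1]
  if (!is.na(graph$start_out[s0])) chars <- graph$start_out[s0]
  if (length(r$arcs) > 0) {
    outs <- graph$arc_out[r$arcs]
    chars <- c(chars, outs[!is.na(outs)])
  }
  motions <- unlist(lapply(chars, function(c) graph$char_motions[[c]]))
  if (is.null(motions)) motions <- character(0)
  structure(
    list(characters = chars, motions = motions, log_score = r$score,
         no_path = FALSE),
    class = "eog_hypothesis"
  )
}

#' @export
print.eog_hypothesis <- function(x, ...) {
  if (x$no_path) cat("Hypothesis: <no path>\n")
  else cat(sprintf("Hypothesis: %s  (score %.2f)\n",
                   paste(x$characters, collapse = " "), x$log_score))
  invisible(x)
}
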