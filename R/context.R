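#' Context-dependent eye-motion units
#'
#' A modeling unit is an eye motion with optional left (preceding) and
#' right (succeeding) motion contexts, written `p-t+s` in the triphone
#' convention: `t` alone (mono), `p-t` (left bi), `t+s` (right bi), or
#' `p-t+s` (tri).  Under the input protocol no motion repeats, so contexts
#' always differ from the target.  Tri-unit states are shared across
#' contexts with a likelihood-driven binary decision tree over context
#' questions, which also lets unseen context combinations be synthesized at
#' decoding time.
#'
#' @name context_units
NULL

make_unit_name <- function(target, left = NA, right = NA) {
  nm <- target
  if (!is.na(left)) nm <- paste0(left, "-", nm)
  if (!is.na(right)) nm <- paste0(nm, "+", right)
  nm
}

#' Parse a unit name into target and contexts
#' @param name Unit name such as `"up"`, `"up-down"`, `"down+up"`, or
#'   `"up-down+up"`.
#' @return List with `target`, `left`, `right` (contexts `NA` when absent)
#'   and `kind` (`"mono"`, `"bi_left"`, `"bi_right"`, `"tri"`, or `"sil"`).
#' @export
parse_unit_name <- function(name) {
  if (name == sil_label())
    return(list(target = name, left = NA, right = NA, kind = "sil"))
  left <- NA_character_; right <- NA_character_
  rest <- name
  if (grepl("-", rest, fixed = TRUE)) {
    parts <- strsplit(rest, "-", fixed = TRUE)[[1]]
    left <- parts[1]; rest <- parts[2]
  }
  if (grepl("+", rest, fixed = TRUE)) {
    parts <- strsplit(rest, "+", fixed = TRUE)[[1]]
    rest <- parts[1]; right <- parts[2]
  }
  kind <- if (!is.na(left) && !is.na(right)) "tri"
          else if (!is.na(left)) "bi_left"
          else if (!is.na(right)) "bi_right" else "mono"
  list(target = rest, left = left, right = right, kind = kind)
}

#' Expand a motion sequence into context-dependent units
#'
#' For `kind = "mono"` every motion maps to its context-free unit.  For
#' `"bi"` the first unit is context-free and each later unit carries its
#' left (preceding) context.  For `"tri"` interior units carry both
#' contexts, the first only its right context, and the last only its left
#' context; a singleton sequence has no contexts at all.
#'
#' @param motions Character vector of motion labels (validated).
#' @param kind `"mono"`, `"bi"`, or `"tri"`.
#' @return Character vector of unit names, same length as `motions`.
#' @export
expand_units <- function(motions, kind = c("mono", "bi", "tri")) {
  kind <- match.arg(kind)
  validate_motion_sequence(motions)
  n <- length(motions)
  if (kind == "mono") return(motions)
  vapply(seq_len(n), function(i) {
    left <- if (i > 1) motions[i - 1] else NA
    right <- if (i < n) motions[i + 1] else NA
    if (kind == "bi") make_unit_name(motions[i], left = left)
    else make_unit_name(motions[i], left = left, right = right)
  }, character(1))
}

#' Enumerate all valid context-dependent units
#'
#' Valid tri units have left and right contexts both differing from the
#' target; valid one-sided bi units have a single context differing from
#' the target.  (Contexts equal to the target cannot occur because the
#' protocol forbids adjacent repeats.)
#'
#' @param motions Motion alphabet to enumerate over; defaults to the five
#'   eye motions.
#' @return Character vector of unit names: all tri, left-bi and right-bi
#'   units.
#' @export
enumerate_context_units <- function(motions = motion_alphabet()) {
  out <- character(0)
  for (t in motions) {
    others <- setdiff(motions, t)
    for (p in others) for (s in others)
      out <- c(out, make_unit_name(t, left = p, right = s))
    for (p in others) out <- c(out, make_unit_name(t, left = p))
    for (s in others) out <- c(out, make_unit_name(t, right = s))
  }
  out
}

#' Size of the untied context-dependent state inventory
#'
#' Enumerates every valid tri-eye-motion unit (left and right contexts each
#' differing from the target) plus the one-sided bi units over an alphabet
#' of `n_motions` motions, and multiplies the model count by
#' `states_per_model`.  For the five eye motions and 4-state models this is
#' 4 x (4 x 5 x 4 + 4 x 5 + 5 x 4) = 480.
#'
#' @param n_motions Number of distinct motions (>= 2).
#' @param states_per_model States per unit model (>= 0).
#' @return Integer state count.
#' @export
count_state_inventory <- function(n_motions, states_per_model) {
  stopifnot(n_motions >= 2, states_per_model >= 0)
  alphabet <- paste0("m", seq_len(n_motions))
  units <- enumerate_context_units(alphabet)
  as.integer(states_per_model * length(units))
}

#' The default context question set
#'
#' For each side (left/right context) there is a singleton question per
#' motion ("is the context this motion?") plus group questions for the
#' horizontal pair (left/right), the vertical pair (up/down), and center.
#' An absent ("none") context answers no to every question.
#'
#' @return A list of questions, each a list with `name`, `side`
#'   (`"left"`/`"right"`) and `motions` (the yes-set).
#' @export
default_questions <- function() {
  qs <- list()
  for (side in c("left", "right")) {
    for (m in motion_alphabet()) {
      qs[[length(qs) + 1]] <- list(
        name = paste0(side, "=", m), side = side, motions = m)
    }
    qs[[length(qs) + 1]] <- list(
      name = paste0(side, "_horizontal"), side = side,
      motions = c("left", "right"))
    qs[[length(qs) + 1]] <- list(
      name = paste0(side, "_vertical"), side = side,
      motions = c("up", "down"))
  }
  qs
}

answer_question <- function(q, left, right) {
  ctx <- if (q$side == "left") left else right
  !is.na(ctx) && ctx %in% q$motions
}

#' Accumulate single-Gaussian state statistics for tying
#'
#' Runs one forward-backward pass over the corpus and accumulates, per pdf,
#' the occupancy and the first and second moments of the aligned frames —
#' the sufficient statistics the tying trees use to score splits.
#'
#' @param set An `eog_hmm_set` (typically the untied single-Gaussian tri
#'   set after initial training).
#' @param corpus Training corpus as for [baum_welch()].
#' @return A list indexed by pdf id: each element has `occ`, `sx`, `sxx`.
#' @export
accumulate_state_stats <- function(set, corpus) {
  d <- set$dim
  stats <- lapply(seq_along(set$pdfs), function(i)
    list(occ = 0, sx = numeric(d), sxx = numeric(d)))
  for (item in corpus) {
    X <- feature_matrix(set, item$feats)
    graph <- make_chain_graph(set, item$units)
    lo <- graph_logobs(set, graph, X)
    fb <- forward_backward_cpp(lo$logobs, lo$pdf0, graph$start, graph$final,
                               graph$arc_from - 1L, graph$arc_to - 1L,
                               graph$arc_logp)
    if (!is.finite(fb$loglik)) next
    for (s in seq_along(graph$pdf_ids)) {
      pid <- graph$pdf_ids[s]
      g <- fb$gamma[, s]
      if (sum(g) <= 0) next
      stats[[pid]]$occ <- stats[[pid]]$occ + sum(g)
      stats[[pid]]$sx <- stats[[pid]]$sx + colSums(X * g)
      stats[[pid]]$sxx <- stats[[pid]]$sxx + colSums(X^2 * g)
    }
  }
  stats
}

# Pooled single-Gaussian log-likelihood of a set of state stats
# (HTK-style approximation): L = -0.5 * occ * (d (log 2 pi + 1) +
# sum_j log var_j), with variances floored.
pool_loglik <- function(items, var_floor) {
  occ <- sum(vapply(items, `[[`, numeric(1), "occ"))
  if (occ <= 0) return(list(L = 0, occ = 0, mean = NULL, var = NULL))
  d <- length(items[[1]]$sx)
  sx <- Reduce(`+`, lapply(items, `[[`, "sx"))
  sxx <- Reduce(`+`, lapply(items, `[[`, "sxx"))
  mu <- sx / occ
  v <- pmax(sxx / occ - mu^2, var_floor)
  L <- -0.5 * occ * (d * (log(2 * pi) + 1) + sum(log(v)))
  list(L = L, occ = occ, mean = mu, var = v)
}

# Evaluate all questions at a node; returns best question and gain.
best_split <- function(items, questions, var_floor, min_occ) {
  parent <- pool_loglik(items, var_floor)
  best <- list(gain = -Inf, q = NULL, yes = NULL, no = NULL)
  for (qi in seq_along(questions)) {
    q <- questions[[qi]]
    ans <- vapply(items, function(it)
      answer_question(q, it$left, it$right), logical(1))
    if (!any(ans) || all(ans)) next
    yes <- items[ans]; no <- items[!ans]
    py <- pool_loglik(yes, var_floor); pn <- pool_loglik(no, var_floor)
    if (py$occ < min_occ || pn$occ < min_occ) next
    gain <- py$L + pn$L - parent$L
    if (gain > best$gain) best <- list(gain = gain, q = qi, yes = yes, no = no)
  }
  best
}

grow_tree <- function(items, questions, var_floor, min_occ) {
  pooled <- pool_loglik(items, var_floor)
  sig <- vapply(items, function(it)
    paste(it$left, it$right), character(1))
  if (length(items) <= 1 || length(unique(sig)) <= 1) {
    return(list(leaf = TRUE, items = items, stats = pooled))
  }
  b <- best_split(items, questions, var_floor, min_occ)
  if (is.null(b$q) || !is.finite(b$gain)) {
    return(list(leaf = TRUE, items = items, stats = pooled))
  }
  list(leaf = FALSE, question = b$q, gain = b$gain, stats = pooled,
       items = items,
       yes = grow_tree(b$yes, questions, var_floor, min_occ),
       no = grow_tree(b$no, questions, var_floor, min_occ))
}

# Apply a stopping threshold top-down: any node whose recorded gain falls
# below the threshold becomes a leaf.  Growth is threshold-independent, so
# this reproduces greedy growth with the stop rule exactly and makes the
# tied-state count monotone in the threshold.
prune_tree <- function(node, threshold) {
  if (isTRUE(node$leaf)) return(node)
  if (node$gain < threshold)
    return(list(leaf = TRUE, items = node$items, stats = node$stats))
  list(leaf = FALSE, question = node$question, gain = node$gain,
       stats = node$stats, items = node$items,
       yes = prune_tree(node$yes, threshold),
       no = prune_tree(node$no, threshold))
}

collect_gains <- function(node) {
  if (isTRUE(node$leaf)) return(numeric(0))
  c(node$gain, collect_gains(node$yes), collect_gains(node$no))
}

count_leaves <- function(node, threshold) {
  if (isTRUE(node$leaf) || node$gain < threshold) return(1L)
  count_leaves(node$yes, threshold) + count_leaves(node$no, threshold)
}

#' Tie tri-unit states with likelihood-driven decision trees
#'
#' For every (target motion, state position) pair, all context variants'
#' states are pooled at the root of a binary tree and greedily split on the
#' context question with the largest gain in pooled single-Gaussian
#' log-likelihood, until the best gain falls below `threshold`.  Each leaf
#' becomes one tied state whose Gaussian is re-estimated from the pooled
#' statistics; units of the set are re-pointed at the leaf pdfs.  Units
#' with a missing context (boundary bi and mono units) ride the same trees,
#' answering "no" to every question about the absent side.  Unseen context
#' combinations can later be routed through the stored trees, which is how
#' the decoder synthesizes units absent from the training set.
#'
#' @param set The untied `eog_hmm_set` (single-Gaussian tri system).
#' @param stats Per-pdf statistics from [accumulate_state_stats()] (or
#'   constructed by hand).
#' @param threshold Likelihood-gain stopping threshold (>= 0), or `NULL`
#'   (default) to auto-calibrate: the smallest recorded gain is chosen so
#'   that about `target_ratio` of the seen states survive as tied states.
#' @param questions Question set; default [default_questions()].
#' @param target_ratio Tied/seen state ratio for auto-calibration; default
#'   0.32.
#' @param min_occ Minimum occupancy on each side of an accepted split;
#'   default 0.
#' @return A list with `set` (the tied model set, carrying the tying in
#'   `set$tying`), `map` (old pdf id -> new pdf id), `n_tied` and
#'   `n_seen` state counts, and `threshold` (the value applied).
#' @export
tie_states <- function(set, stats, threshold = NULL,
                       questions = default_questions(),
                       target_ratio = 0.32, min_occ = 0, occ_eps = 1e-3) {
  stopifnot(inherits(set, "eog_hmm_set"))
  n <- set$n_states
  # group every non-sil unit's states by (target, position); states that
  # never occurred in training (occupancy ~ 0) do not enter the pools and
  # are routed through the finished trees instead
  pools <- list()
  unseen <- list()
  for (u in names(set$units)) {
    pu <- parse_unit_name(u)
    if (pu$kind == "sil") next
    for (pos in seq_len(n)) {
      key <- paste(pu$target, pos, sep = "/")
      pid <- set$units[[u]]$pdf_ids[pos]
      st <- stats[[pid]]
      item <- list(unit = u, pdf = pid, left = pu$left, right = pu$right,
                   occ = st$occ, sx = st$sx, sxx = st$sxx)
      if (st$occ > occ_eps) pools[[key]] <- c(pools[[key]], list(item))
      else unseen[[key]] <- c(unseen[[key]], list(item))
    }
  }
  if (length(pools) == 0) stop("no occupied states to tie")
  trees <- lapply(pools, grow_tree, questions = questions,
                  var_floor = set$var_floor, min_occ = min_occ)

  n_seen <- sum(lengths(pools))
  if (is.null(threshold)) {
    gains <- sort(unique(unlist(lapply(trees, collect_gains))),
                  decreasing = TRUE)
    target_leaves <- max(length(pools), ceiling(target_ratio * n_seen))
    threshold <- Inf
    for (g in gains) {
      leaves <- sum(vapply(trees, count_leaves, integer(1), threshold = g))
      if (leaves >= target_leaves) { threshold <- g; break }
    }
    if (!is.finite(threshold) && length(gains) > 0)
      threshold <- gains[length(gains)]
    if (!is.finite(threshold)) threshold <- 0
  }
  pruned <- lapply(trees, prune_tree, threshold = threshold)

  # create one pdf per leaf; build the old->new map
  new_pdfs <- list()
  map <- integer(length(set$pdfs))
  assign_leaves <- function(node) {
    if (isTRUE(node$leaf)) {
      s <- node$stats
      mu <- if (is.null(s$mean)) numeric(set$dim) else s$mean
      v <- if (is.null(s$var)) pmax(set$var_floor, 1) else s$var
      new_pdfs[[length(new_pdfs) + 1]] <<- new_pdf(
        1, matrix(mu, 1), matrix(v, 1))
      id <- length(new_pdfs)
      for (it in node$items) map[it$pdf] <<- id
      node$pdf <- id
      return(node)
    }
    node$yes <- assign_leaves(node$yes)
    node$no <- assign_leaves(node$no)
    node
  }
  pruned <- lapply(pruned, assign_leaves)

  # unseen states route through the finished trees
  for (key in names(unseen)) {
    tree <- pruned[[key]]
    for (it in unseen[[key]]) {
      map[it$pdf] <- if (is.null(tree)) 0L
                     else walk_tree(tree, questions, it$left, it$right)
    }
  }

  # sil (and any unpooled) pdfs are carried over untouched
  for (p in seq_along(set$pdfs)) {
    if (map[p] == 0) {
      new_pdfs[[length(new_pdfs) + 1]] <- set$pdfs[[p]]
      map[p] <- length(new_pdfs)
    }
  }

  # representative transition matrix per target, for synthesizing unseen
  # units
  trans_by_target <- list()
  for (u in names(set$units)) {
    t0 <- parse_unit_name(u)$target
    trans_by_target[[t0]] <- c(trans_by_target[[t0]],
                               list(set$units[[u]]$trans))
  }
  trans_by_target <- lapply(trans_by_target, function(ms)
    Reduce(`+`, ms) / length(ms))

  tying <- structure(
    list(trees = pruned, questions = questions, n_states = n,
         trans_by_target = trans_by_target, threshold = threshold),
    class = "eog_tying"
  )
  tied <- set
  tied$pdfs <- new_pdfs
  for (u in names(tied$units))
    tied$units[[u]]$pdf_ids <- map[tied$units[[u]]$pdf_ids]
  tied$tying <- tying
  n_tied <- sum(vapply(pruned, function(tr) count_leaves(tr, -Inf),
                       integer(1)))
  list(set = tied, map = map, n_tied = n_tied, n_seen = n_seen,
       threshold = threshold)
}

# Walk a tied tree to the leaf pdf for an arbitrary context pair.
walk_tree <- function(node, questions, left, right) {
  while (!isTRUE(node$leaf)) {
    q <- questions[[node$question]]
    node <- if (answer_question(q, left, right)) node$yes else node$no
  }
  node$pdf
}

#' Resolve (synthesize) a unit through the tying trees
#'
#' Returns the model set with the named unit present: if absent, its state
#' pdfs are found by routing the unit's contexts through the tying trees
#' and its transitions are the per-target average of the seen units.
#'
#' @param set A tied `eog_hmm_set` (with `set$tying`).
#' @param unit_name The unit to resolve, e.g. `"left-up+right"`.
#' @return The (possibly augmented) model set.
#' @export
resolve_unit <- function(set, unit_name) {
  if (unit_name %in% names(set$units)) return(set)
  if (is.null(set$tying))
    stop("unit '", unit_name, "' not in model set and no tying available")
  pu <- parse_unit_name(unit_name)
  ty <- set$tying
  pdf_ids <- vapply(seq_len(ty$n_states), function(pos) {
    key <- paste(pu$target, pos, sep = "/")
    tree <- ty$trees[[key]]
    if (is.null(tree))
      stop("no tying tree for target '", pu$target, "' (unit '",
           unit_name, "')")
    walk_tree(tree, ty$questions, pu$left, pu$right)
  }, integer(1))
  trans <- ty$trans_by_target[[pu$target]]
  if (is.null(trans))
    stop("no transition template for target '", pu$target, "'")
  set$units[[unit_name]] <- list(pdf_ids = pdf_ids, trans = trans)
  set
}

#' Dump tying trees as indented text
#' @param set A tied `eog_hmm_set`.
#' @return Character vector of lines (question / yes / no / leaf ids).
#' @export
format_tying_trees <- function(set) {
  stopifnot(!is.null(set$tying))
  ty <- set$tying
  out <- character(0)
  rec <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (isTRUE(node$leaf)) {
      out <<- c(out, paste0(pad, "leaf pdf=", node$pdf,
                            " occ=", signif(node$stats$occ, 4)))
    } else {
      out <<- c(out, paste0(pad, "? ", ty$questions[[node$question]]$name,
                            " (gain=", signif(node$gain, 4), ")"))
      out <<- c(out, paste0(pad, "yes:")); rec(node$yes, indent + 1)
      out <<- c(out, paste0(pad, "no:")); rec(node$no, indent + 1)
    }
  }
  for (key in names(ty$trees)) {
    out <- c(out, paste0("tree ", key))
    rec(ty$trees[[key]], 1)
  }
  out
}
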