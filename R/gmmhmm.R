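#' Left-to-right Gaussian-mixture HMMs
#'
#' Each modeling unit (a mono/bi/tri eye-motion unit or "sil") is a
#' left-to-right HMM with `n_states` emitting states (default 4) and no
#' skips: state i may loop to itself or advance to i+1, and the last state
#' may exit.  Emission densities are diagonal-covariance Gaussian mixtures
#' shared through a pdf table, so that state tying amounts to several
#' states pointing at the same pdf.  All computation is in the log domain;
#' the forward, forward-backward and Viterbi recursions run in compiled
#' code over an explicit arc-list graph.
#'
#' @name gmm_hmm
NULL

new_pdf <- function(weights, means, vars) {
  list(weights = weights, means = means, vars = vars)  # means/vars: M x d
}

#' Create a flat-start model set
#'
#' All pdfs are initialized to a single Gaussian at the global data mean
#' and variance, and all transition rows to (self 0.6, advance 0.4);
#' embedded Baum-Welch training then breaks the symmetry.  The variance
#' floor is fixed at `floor_scale` times the global variance per dimension.
#'
#' @param unit_names Character vector of unit names (e.g. `"up"`,
#'   `"up-down+up"`, `"sil"`).
#' @param global_mean,global_var Numeric vectors (length d) of the training
#'   data's global mean and variance.
#' @param n_states Emitting states per unit; default 4.
#' @param floor_scale Variance floor as a fraction of the global variance;
#'   default 1e-4.
#' @return An object of class `eog_hmm_set`.
#' @export
make_hmm_set <- function(unit_names, global_mean, global_var,
                         n_states = 4, floor_scale = 1e-4) {
  stopifnot(length(unit_names) > 0, n_states >= 1,
            length(global_mean) == length(global_var), all(global_var > 0))
  d <- length(global_mean)
  pdfs <- list()
  units <- list()
  for (i in seq_along(unit_names)) {
    ids <- length(pdfs) + seq_len(n_states)
    for (j in seq_len(n_states)) {
      pdfs[[length(pdfs) + 1]] <- new_pdf(
        1, matrix(global_mean, 1, d), matrix(global_var, 1, d))
    }
    trans <- matrix(0, n_states, n_states + 1)
    for (s in seq_len(n_states)) {
      trans[s, s] <- 0.6
      trans[s, s + 1] <- 0.4
    }
    units[[unit_names[i]]] <- list(pdf_ids = ids, trans = trans)
  }
  structure(
    list(units = units, pdfs = pdfs, dim = d, n_states = n_states,
         var_floor = floor_scale * global_var),
    class = "eog_hmm_set"
  )
}

#' @export
print.eog_hmm_set <- function(x, ...) {
  m <- vapply(x$pdfs, function(p) length(p$weights), integer(1))
  cat(sprintf(
    "HMM set: %d units x %d states, %d pdfs (%d distinct), %d-dim, <=%d mixture components\n",
    length(x$units), x$n_states, length(x$pdfs),
    length(unique(unlist(lapply(x$units, `[[`, "pdf_ids")))),
    x$dim, max(m)
  ))
  invisible(x)
}

# Per-component log densities: T x M matrix for one pdf.
gmm_component_logdens <- function(pdf, X) {
  M <- length(pdf$weights)
  T_ <- nrow(X)
  out <- matrix(0, T_, M)
  d <- ncol(X)
  for (m in seq_len(M)) {
    mu <- pdf$means[m, ]
    v <- pdf$vars[m, ]
    z <- sweep(X, 2, mu)
    q <- rowSums(sweep(z^2, 2, v, "/"))
    out[, m] <- -0.5 * (d * log(2 * pi) + sum(log(v)) + q) +
      log(pdf$weights[m])
  }
  out
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1, max)
  bad <- !is.finite(mx)
  out <- mx + log(rowSums(exp(m - mx)))
  out[bad] <- -Inf
  out
}

# T-vector of log N(x | pdf) mixture densities.
gmm_logdens <- function(pdf, X) {
  cl <- gmm_component_logdens(pdf, X)
  if (ncol(cl) == 1) drop(cl) else logsumexp_rows(cl)
}

#' Build a linear (chain) recognition graph for a unit sequence
#'
#' Concatenates the named units' left-to-right HMMs: entry at the first
#' unit's first state, exits feed the next unit's first state, and the
#' final probability sits on the last unit's exit.  Used for embedded
#' training and forced alignment.
#'
#' @param set An `eog_hmm_set`.
#' @param unit_names Character vector of unit names in order.
#' @return An object of class `eog_graph`.
#' @export
make_chain_graph <- function(set, unit_names) {
  stopifnot(inherits(set, "eog_hmm_set"), length(unit_names) > 0)
  missing <- setdiff(unit_names, names(set$units))
  if (length(missing) > 0)
    stop("unit(s) not in model set: ", paste(unique(missing), collapse = ", "))
  n <- set$n_states
  S <- n * length(unit_names)
  pdf_ids <- integer(S)
  state_unit <- integer(S)   # position in unit_names
  state_pos <- integer(S)
  arc_from <- integer(0); arc_to <- integer(0); arc_logp <- numeric(0)
  arc_unit <- integer(0); arc_row <- integer(0); arc_col <- integer(0)
  at <- 0L
  for (u in seq_along(unit_names)) {
    unit <- set$units[[unit_names[u]]]
    pdf_ids[at + seq_len(n)] <- unit$pdf_ids
    state_unit[at + seq_len(n)] <- u
    state_pos[at + seq_len(n)] <- seq_len(n)
    lt <- log(unit$trans)
    for (s in seq_len(n)) {
      if (is.finite(lt[s, s])) {
        arc_from <- c(arc_from, at + s); arc_to <- c(arc_to, at + s)
        arc_logp <- c(arc_logp, lt[s, s])
        arc_unit <- c(arc_unit, u); arc_row <- c(arc_row, s)
        arc_col <- c(arc_col, s)
      }
      if (s < n && is.finite(lt[s, s + 1])) {
        arc_from <- c(arc_from, at + s); arc_to <- c(arc_to, at + s + 1)
        arc_logp <- c(arc_logp, lt[s, s + 1])
        arc_unit <- c(arc_unit, u); arc_row <- c(arc_row, s)
        arc_col <- c(arc_col, s + 1)
      }
    }
    if (u < length(unit_names) && is.finite(lt[n, n + 1])) {
      arc_from <- c(arc_from, at + n); arc_to <- c(arc_to, at + n + 1L)
      arc_logp <- c(arc_logp, lt[n, n + 1])
      arc_unit <- c(arc_unit, u); arc_row <- c(arc_row, n)
      arc_col <- c(arc_col, n + 1L)
    }
    at <- at + n
  }
  start <- rep(-Inf, S); start[1] <- 0
  final <- rep(-Inf, S)
  last_unit <- set$units[[unit_names[length(unit_names)]]]
  final[S] <- log(last_unit$trans[n, n + 1])
  structure(
    list(pdf_ids = pdf_ids, start = start, final = final,
         arc_from = arc_from, arc_to = arc_to, arc_logp = arc_logp,
         arc_unit = arc_unit, arc_row = arc_row, arc_col = arc_col,
         state_unit = state_unit, state_pos = state_pos,
         unit_names = unit_names,
         arc_out = rep(NA_character_, length(arc_from)),
         start_out = rep(NA_character_, S)),
    class = "eog_graph"
  )
}

# Log emission densities for the pdfs a graph uses: returns list(logobs =
# T x P matrix, pdf0 = 0-based pdf column per graph state).
graph_logobs <- function(set, graph, X) {
  used <- sort(unique(graph$pdf_ids))
  logobs <- vapply(used, function(p) gmm_logdens(set$pdfs[[p]], X),
                   numeric(nrow(X)))
  if (nrow(X) == 1) logobs <- matrix(logobs, nrow = 1)
  list(logobs = logobs, pdf0 = match(graph$pdf_ids, used) - 1L, used = used)
}

#' Forward log-likelihood of an observation sequence under a graph
#'
#' Sum over all state paths (forward algorithm); `-Inf` when no complete
#' path exists, e.g. when the observation is shorter than the graph's
#' minimum path length.
#'
#' @param set An `eog_hmm_set`.
#' @param graph An `eog_graph` (from [make_chain_graph()] or
#'   [build_decoding_graph()]).
#' @param feats An `eog_features` object or a numeric matrix (T x d).
#' @return Log-likelihood (natural log).
#' @export
log_likelihood <- function(set, graph, feats) {
  X <- feature_matrix(set, feats)
  lo <- graph_logobs(set, graph, X)
  forward_loglik_cpp(lo$logobs, lo$pdf0, graph$start, graph$final,
                     graph$arc_from - 1L, graph$arc_to - 1L, graph$arc_logp)
}

feature_matrix <- function(set, feats) {
  X <- if (inherits(feats, "eog_features")) feats$vectors else as.matrix(feats)
  if (ncol(X) != set$dim)
    stop("feature dimension ", ncol(X), " does not match model dimension ",
         set$dim)
  X
}

#' Viterbi alignment of an observation sequence to a graph
#'
#' @inheritParams log_likelihood
#' @return A list with `score` (log probability of the best path; `-Inf`
#'   with empty alignment if no path), `path` (data frame: frame, state,
#'   unit index, unit name, state position), and `arcs` (indices of the
#'   arcs taken).
#' @export
viterbi_align <- function(set, graph, feats) {
  X <- feature_matrix(set, feats)
  lo <- graph_logobs(set, graph, X)
  r <- viterbi_cpp(lo$logobs, lo$pdf0, graph$start, graph$final,
                   graph$arc_from - 1L, graph$arc_to - 1L, graph$arc_logp,
                   beam = Inf)
  if (!is.finite(r$score) || length(r$path) == 0) {
    return(list(score = -Inf, path = NULL, arcs = integer(0)))
  }
  path <- data.frame(
    frame = seq_len(nrow(X)),
    state = r$path,
    unit = graph$state_unit[r$path],
    unit_name = graph$unit_names[graph$state_unit[r$path]],
    state_pos = graph$state_pos[r$path],
    stringsAsFactors = FALSE
  )
  list(score = r$score, path = path, arcs = r$arcs)
}

#' Training configuration for embedded Baum-Welch
#'
#' @param n_iterations EM iterations per mixture stage; default 5.
#' @param mixture_schedule Mixture component counts grown by binary
#'   splitting; default `c(1, 2, 4, 8, 16)` ending at the full 16-component
#'   mixtures.
#' @param convergence_tol Stop a stage early when the per-frame total
#'   log-likelihood improves by less than this; default 1e-4.
#' @param min_occupancy States with less expected occupancy than this keep
#'   their previous parameters (with a warning); default 1e-2 frames.
#' @return A list of class `eog_train_config`.
#' @export
train_config <- function(n_iterations = 5, mixture_schedule = c(1, 2, 4, 8, 16),
                         convergence_tol = 1e-4, min_occupancy = 1e-2) {
  stopifnot(n_iterations >= 1, convergence_tol > 0,
            all(diff(mixture_schedule) > 0), mixture_schedule[1] >= 1)
  structure(
    list(n_iterations = n_iterations, mixture_schedule = mixture_schedule,
         convergence_tol = convergence_tol, min_occupancy = min_occupancy),
    class = "eog_train_config"
  )
}

#' Embedded Baum-Welch training
#'
#' Re-estimates all pdfs and transition matrices of a model set from a
#' corpus of continuous observation sequences with unit-level labels (no
#' pre-segmentation): each sequence's label chain is expanded into a linear
#' graph and forward-backward occupancies are accumulated over it.  After
#' each stage of `config$mixture_schedule` iterations, mixtures are grown
#' by perturbed-mean binary splitting.  The total log-likelihood is
#' non-decreasing across EM iterations at fixed mixture size (up to
#' numerical tolerance).
#'
#' @param set An `eog_hmm_set`.
#' @param corpus List of elements with `units` (character chain of unit
#'   names) and `feats` (T x d matrix or `eog_features`).
#' @param config An [train_config()].
#' @param tying Optional tying map (integer vector: pdf id -> tied pdf id)
#'   applied before training, see [tie_states()].
#' @return The trained `eog_hmm_set`, with an attribute
#'   `"loglik_trace"` (per-iteration total log-likelihood).
#' @export
baum_welch <- function(set, corpus, config = train_config(), tying = NULL) {
  stopifnot(inherits(set, "eog_hmm_set"), length(corpus) > 0)
  if (!is.null(tying)) set <- apply_tying(set, tying)
  trace <- numeric(0)
  target_now <- max(vapply(set$pdfs, function(p) length(p$weights),
                           integer(1)))
  sched <- config$mixture_schedule[config$mixture_schedule >= target_now]
  if (length(sched) == 0) sched <- target_now
  for (stage in seq_along(sched)) {
    if (sched[stage] > target_now) {
      set <- split_mixtures(set, sched[stage])
      target_now <- sched[stage]
    }
    prev_ll <- -Inf
    for (iter in seq_len(config$n_iterations)) {
      r <- bw_iteration(set, corpus, config$min_occupancy)
      set <- r$set
      trace <- c(trace, r$loglik)
      n_frames <- sum(vapply(corpus, function(u)
        nrow(feature_matrix(set, u$feats)), numeric(1)))
      if (is.finite(prev_ll) &&
          (r$loglik - prev_ll) / n_frames < config$convergence_tol) break
      prev_ll <- r$loglik
    }
  }
  attr(set, "loglik_trace") <- trace
  set
}

# One accumulation + M-step pass; returns list(set, loglik) where loglik is
# the total likelihood of the corpus under the *input* parameters.
bw_iteration <- function(set, corpus, min_occupancy = 1e-2) {
  P <- length(set$pdfs)
  d <- set$dim
  acc <- lapply(set$pdfs, function(p) {
    M <- length(p$weights)
    list(occ = numeric(M), sx = matrix(0, M, d), sxx = matrix(0, M, d))
  })
  trans_acc <- lapply(set$units, function(u) matrix(0, nrow(u$trans),
                                                    ncol(u$trans)))
  total_ll <- 0
  skipped <- 0L
  for (item in corpus) {
    X <- feature_matrix(set, item$feats)
    graph <- make_chain_graph(set, item$units)
    lo <- graph_logobs(set, graph, X)
    fb <- forward_backward_cpp(lo$logobs, lo$pdf0, graph$start, graph$final,
                               graph$arc_from - 1L, graph$arc_to - 1L,
                               graph$arc_logp)
    if (!is.finite(fb$loglik)) { skipped <- skipped + 1L; next }
    total_ll <- total_ll + fb$loglik

    # pdf occupancies: sum gamma over states sharing a pdf
    for (p_used in seq_along(lo$used)) {
      pid <- lo$used[p_used]
      cols <- which(graph$pdf_ids == pid)
      occ_t <- if (length(cols) == 1) fb$gamma[, cols, drop = TRUE]
               else rowSums(fb$gamma[, cols, drop = FALSE])
      if (sum(occ_t) <= 0) next
      pdf <- set$pdfs[[pid]]
      M <- length(pdf$weights)
      if (M == 1) {
        w <- occ_t
        acc[[pid]]$occ <- acc[[pid]]$occ + sum(w)
        acc[[pid]]$sx[1, ] <- acc[[pid]]$sx[1, ] + colSums(X * w)
        acc[[pid]]$sxx[1, ] <- acc[[pid]]$sxx[1, ] + colSums(X^2 * w)
      } else {
        cl <- gmm_component_logdens(pdf, X)
        resp <- exp(cl - logsumexp_rows(cl))
        w <- resp * occ_t
        acc[[pid]]$occ <- acc[[pid]]$occ + colSums(w)
        acc[[pid]]$sx <- acc[[pid]]$sx + t(w) %*% X
        acc[[pid]]$sxx <- acc[[pid]]$sxx + t(w) %*% X^2
      }
    }

    # transition counts (self/advance/cross-unit exit arcs + final exit)
    for (a in seq_along(graph$arc_from)) {
      u <- graph$unit_names[graph$arc_unit[a]]
      trans_acc[[u]][graph$arc_row[a], graph$arc_col[a]] <-
        trans_acc[[u]][graph$arc_row[a], graph$arc_col[a]] + fb$arc_post[a]
    }
    u_last <- item$units[length(item$units)]
    n <- set$n_states
    trans_acc[[u_last]][n, n + 1] <-
      trans_acc[[u_last]][n, n + 1] + fb$final_post[length(graph$final)]
  }
  if (skipped == length(corpus))
    stop("no training sequence admits a complete path (all too short?)")

  # M-step
  for (p in seq_len(P)) {
    a <- acc[[p]]
    tot <- sum(a$occ)
    if (tot < min_occupancy) {
      if (tot > 0)
        warning("pdf ", p, " starved (occupancy ", signif(tot, 3),
                "); keeping previous parameters")
      next
    }
    keep <- a$occ > min_occupancy / length(a$occ)
    if (!all(keep)) {
      # starved components keep their old parameters but get tiny weight
      a$occ[!keep] <- min_occupancy / length(a$occ)
    }
    w <- a$occ / sum(a$occ)
    means <- set$pdfs[[p]]$means
    vars <- set$pdfs[[p]]$vars
    means[keep, ] <- a$sx[keep, , drop = FALSE] / a$occ[keep]
    v <- a$sxx[keep, , drop = FALSE] / a$occ[keep] -
      means[keep, , drop = FALSE]^2
    vars[keep, ] <- sweep(v, 2, set$var_floor, pmax)
    set$pdfs[[p]] <- new_pdf(w, means, vars)
  }
  for (u in names(set$units)) {
    cnt <- trans_acc[[u]]
    tr <- set$units[[u]]$trans
    for (s in seq_len(nrow(cnt))) {
      row_tot <- sum(cnt[s, ])
      if (row_tot > min_occupancy) {
        mask <- tr[s, ] > 0            # keep the left-to-right structure
        newrow <- cnt[s, ] * mask
        if (sum(newrow) > 0) tr[s, ] <- newrow / sum(newrow)
      }
    }
    # guard against absorbing states: keep a minimum advance probability
    n <- nrow(tr)
    for (s in seq_len(n)) {
      adv <- if (s < n) s + 1 else n + 1
      if (tr[s, adv] < 1e-6) {
        tr[s, adv] <- 1e-6
        tr[s, ] <- tr[s, ] / sum(tr[s, ])
      }
    }
    set$units[[u]]$trans <- tr
  }
  list(set = set, loglik = total_ll)
}

#' Grow mixtures by perturbed-mean binary splitting
#'
#' Each pdf's components are split (largest-weight first) until
#' `target` components: a component splits into two copies with means
#' displaced by +/- `perturb` standard deviations, each carrying half the
#' weight.  At split time the model's likelihood is essentially unchanged
#' (the two halves sit symmetrically about the old mean).
#'
#' @param set An `eog_hmm_set`.
#' @param target Target component count per pdf.
#' @param perturb Mean displacement in standard deviations; default 0.2.
#' @return The model set with grown mixtures.
#' @export
split_mixtures <- function(set, target, perturb = 0.2) {
  stopifnot(target >= 1)
  for (p in seq_along(set$pdfs)) {
    pdf <- set$pdfs[[p]]
    while (length(pdf$weights) < target) {
      m <- which.max(pdf$weights)
      sd_m <- sqrt(pdf$vars[m, ])
      up <- pdf$means[m, ] + perturb * sd_m
      dn <- pdf$means[m, ] - perturb * sd_m
      w2 <- pdf$weights[m] / 2
      pdf$weights <- c(pdf$weights[-m], w2, w2)
      pdf$means <- rbind(pdf$means[-m, , drop = FALSE], up, dn)
      pdf$vars <- rbind(pdf$vars[-m, , drop = FALSE],
                        pdf$vars[m, ], pdf$vars[m, ])
      rownames(pdf$means) <- NULL; rownames(pdf$vars) <- NULL
    }
    set$pdfs[[p]] <- pdf
  }
  set
}

# Replace pdf pointers according to a tying map (old pdf id -> new pdf id).
apply_tying <- function(set, tying) {
  stopifnot(length(tying) == length(set$pdfs))
  for (u in names(set$units))
    set$units[[u]]$pdf_ids <- tying[set$units[[u]]$pdf_ids]
  set
}
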