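#' User adaptation of a user-independent model set
#'
#' Two standard adaptation techniques borrowed from speech recognition are
#' provided.  MLLR estimates an affine transform `mu' = A mu + b` of the
#' Gaussian means per regression class by maximum likelihood from
#' forward-backward occupancies (mean-only MLLR; variances untouched).
#' MAP interpolates each component mean between its user-independent prior
#' and the adaptation-data mean, weighted by a prior count tau:
#' `mu' = (tau mu0 + sum_t gamma_t x_t) / (tau + sum_t gamma_t)`.
#' Insertion-penalty tuning grid-searches the decoder's per-character
#' penalty on held-out data, compensating for user-specific input speed.
#'
#' @name adaptation
NULL

# Adaptation data may be raw (motions + recording) or pre-expanded chains
# (units + feats), e.g. observations sampled directly from a model.
as_adaptation_chains <- function(set, corpus) {
  stopifnot(length(corpus) > 0)
  if (!is.null(corpus[[1]]$units)) return(list(set = set, chains = corpus))
  system_chains(set, corpus)
}

# Per-component occupancy and weighted data sums over a corpus of chains.
accumulate_component_stats <- function(set, chains) {
  d <- set$dim
  acc <- lapply(set$pdfs, function(p) {
    M <- length(p$weights)
    list(occ = numeric(M), sx = matrix(0, M, d))
  })
  for (item in chains) {
    X <- feature_matrix(set, item$feats)
    graph <- make_chain_graph(set, item$units)
    lo <- graph_logobs(set, graph, X)
    fb <- forward_backward_cpp(lo$logobs, lo$pdf0, graph$start, graph$final,
                               graph$arc_from - 1L, graph$arc_to - 1L,
                               graph$arc_logp)
    if (!is.finite(fb$loglik)) next
    for (p_used in seq_along(lo$used)) {
      pid <- lo$used[p_used]
      cols <- which(graph$pdf_ids == pid)
      occ_t <- if (length(cols) == 1) fb$gamma[, cols, drop = TRUE]
               else rowSums(fb$gamma[, cols, drop = FALSE])
      if (sum(occ_t) <= 0) next
      pdf <- set$pdfs[[pid]]
      if (length(pdf$weights) == 1) {
        acc[[pid]]$occ <- acc[[pid]]$occ + sum(occ_t)
        acc[[pid]]$sx[1, ] <- acc[[pid]]$sx[1, ] + colSums(X * occ_t)
      } else {
        cl <- gmm_component_logdens(pdf, X)
        resp <- exp(cl - logsumexp_rows(cl))
        w <- resp * occ_t
        acc[[pid]]$occ <- acc[[pid]]$occ + colSums(w)
        acc[[pid]]$sx <- acc[[pid]]$sx + t(w) %*% X
      }
    }
  }
  acc
}

#' MLLR mean adaptation
#'
#' Estimates, per regression class, the affine transform of the component
#' means that maximizes the adaptation data's likelihood given the
#' forward-backward alignment, and applies it.  With diagonal covariances
#' the solution decomposes row-wise: for output dimension i,
#' `w_i = G_i^{-1} k_i` with
#' `G_i = sum_m (occ_m / var_mi) xi_m xi_m'` and
#' `k_i = sum_m (sx_mi / var_mi) xi_m`, where `xi_m = (mu_m, 1)` is the
#' extended mean.  Components are assigned to classes by k-means on their
#' means; a class with fewer occupied frames than `min_frames` falls back
#' to the global (single-class) transform with a warning.
#'
#' @param set A trained `eog_hmm_set` (the user-independent models).
#' @param corpus Adaptation data: list of `motions` + `recording` items.
#' @param n_classes Number of regression classes; default 1 (global).
#' @param min_frames Minimum occupancy for a class-specific transform;
#'   default `set$dim + 1` frames.
#' @return The adapted model set; the transform(s) are attached as
#'   attribute `"mllr"` (per class: `A`, `b`).
#' @export
mllr_adapt <- function(set, corpus, n_classes = 1,
                       min_frames = set$dim + 1) {
  sc <- as_adaptation_chains(set, corpus)
  set <- sc$set
  acc <- accumulate_component_stats(set, sc$chains)
  d <- set$dim

  comp_tab <- list()  # one row per component: pdf, m, occ, sx, mean, var
  for (p in seq_along(set$pdfs)) {
    pdf <- set$pdfs[[p]]
    for (m in seq_along(pdf$weights)) {
      comp_tab[[length(comp_tab) + 1]] <- list(
        pdf = p, m = m, occ = acc[[p]]$occ[m], sx = acc[[p]]$sx[m, ],
        mean = pdf$means[m, ], var = pdf$vars[m, ])
    }
  }

  assign_class <- rep(1L, length(comp_tab))
  if (n_classes > 1) {
    means <- do.call(rbind, lapply(comp_tab, `[[`, "mean"))
    km <- stats::kmeans(means, centers = min(n_classes, nrow(means)))
    assign_class <- km$cluster
  }

  solve_transform <- function(idx) {
    G <- array(0, c(d, d + 1, d + 1))
    k <- matrix(0, d, d + 1)
    for (ci in idx) {
      cm <- comp_tab[[ci]]
      if (cm$occ <= 0) next
      xi <- c(cm$mean, 1)
      xx <- tcrossprod(xi)
      for (i in seq_len(d)) {
        G[i, , ] <- G[i, , ] + (cm$occ / cm$var[i]) * xx
        k[i, ] <- k[i, ] + (cm$sx[i] / cm$var[i]) * xi
      }
    }
    W <- matrix(0, d, d + 1)
    for (i in seq_len(d)) W[i, ] <- solve(G[i, , ], k[i, ])
    list(A = W[, seq_len(d), drop = FALSE], b = W[, d + 1])
  }

  occ_by_class <- tapply(vapply(comp_tab, `[[`, numeric(1), "occ"),
                         assign_class, sum)
  global <- solve_transform(seq_along(comp_tab))
  transforms <- list()
  for (cl in sort(unique(assign_class))) {
    if (is.na(occ_by_class[as.character(cl)]) ||
        occ_by_class[as.character(cl)] < min_frames) {
      warning("regression class ", cl, " has insufficient occupancy; ",
              "using the global transform")
      transforms[[cl]] <- global
    } else {
      transforms[[cl]] <- solve_transform(which(assign_class == cl))
    }
  }

  for (ci in seq_along(comp_tab)) {
    cm <- comp_tab[[ci]]
    tr <- transforms[[assign_class[ci]]]
    set$pdfs[[cm$pdf]]$means[cm$m, ] <- drop(tr$A %*% cm$mean + tr$b)
  }
  attr(set, "mllr") <- transforms
  set
}

#' MAP configuration
#' @param tau Prior weight in frames (>= 0, finite); default 10.
#' @return A list of class `eog_map_config`.
#' @export
map_config <- function(tau = 10) {
  stopifnot(is.finite(tau), tau >= 0)
  structure(list(tau = tau), class = "eog_map_config")
}

#' MAP mean adaptation
#'
#' Per Gaussian component: `mu' = (tau mu0 + sum gamma x) / (tau + sum
#' gamma)`.  Components with no adaptation occupancy keep their prior
#' means; as `tau -> 0` the means move to the occupancy-weighted data
#' means, and as `tau -> Inf` they stay at the prior.
#'
#' @param set A trained `eog_hmm_set` (the user-independent models).
#' @param corpus Adaptation data: list of `motions` + `recording` items.
#' @param config An [map_config()].
#' @return The adapted model set.
#' @export
map_adapt <- function(set, corpus, config = map_config()) {
  stopifnot(inherits(config, "eog_map_config"))
  sc <- as_adaptation_chains(set, corpus)
  set <- sc$set
  acc <- accumulate_component_stats(set, sc$chains)
  tau <- config$tau
  for (p in seq_along(set$pdfs)) {
    pdf <- set$pdfs[[p]]
    for (m in seq_along(pdf$weights)) {
      occ <- acc[[p]]$occ[m]
      if (occ <= 0 && tau == 0) next   # no data, no prior weight: keep
      set$pdfs[[p]]$means[m, ] <-
        (tau * pdf$means[m, ] + acc[[p]]$sx[m, ]) / (tau + occ)
    }
  }
  set
}

#' Tune the decoder's insertion penalty on development data
#'
#' Decodes the development recordings at every grid value and returns the
#' penalty minimizing the pooled character error rate; ties are broken
#' towards the value closest to zero (then the larger value).
#'
#' @param graph An `eog_decode_graph`.
#' @param dev List of elements with `characters` (reference) and
#'   `recording`.
#' @param grid Numeric vector of candidate penalties (non-empty).
#' @param config Base [decode_config()]; its `insertion_penalty` is
#'   overridden by each grid value.
#' @return A list with `penalty` (the selected value), `cer` (its pooled
#'   dev CER), and `grid_cer` (named vector over the grid).
#' @export
tune_insertion_penalty <- function(graph, dev, grid,
                                   config = decode_config()) {
  stopifnot(length(grid) > 0, length(dev) > 0)
  set <- graph$set
  feats <- lapply(dev, function(it) system_features(set, it$recording))
  refs <- lapply(dev, `[[`, "characters")
  cers <- vapply(grid, function(pen) {
    cfg <- decode_config(lm_weight = config$lm_weight,
                         insertion_penalty = pen, beam = config$beam)
    hyps <- lapply(feats, function(f)
      suppressWarnings(decode(f, graph, cfg))$characters)
    evaluate_corpus(hyps, refs)$rate
  }, numeric(1))
  names(cers) <- as.character(grid)
  best <- which(cers == min(cers))
  if (length(best) > 1) {
    cand <- grid[best]
    best <- best[order(abs(cand), -cand)][1]
  }
  list(penalty = grid[best], cer = cers[best], grid_cer = cers)
}
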