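#' Train a recognizer from a labeled synthetic corpus
#'
#' The standard recipe for context-dependent systems: a context-independent
#' (mono) single-Gaussian system is flat-started and trained first; its
#' models are then cloned to every context-dependent unit seen in the
#' training labels and re-trained; tri systems are state-tied with decision
#' trees and re-trained; finally mixtures are grown along the configured
#' schedule.  The mono models remain in the returned set as context
#' back-offs for units never seen in training (tri systems instead
#' synthesize unseen units through the tying trees).
#'
#' @param corpus List of elements with `motions` and `recording`, as
#'   produced by [generate_corpus()].
#' @param unit_kind `"mono"`, `"bi"`, or `"tri"`.
#' @param features `"six"` (default) for the 6-channel observation vector
#'   or `"two"` for the 2-D projection.
#' @param config An [train_config()]; its `mixture_schedule` governs the
#'   final mixture growth.
#' @param n_states Emitting states per unit; default 4.
#' @param tie Apply decision-tree state tying (default for tri units).
#' @param tie_threshold Likelihood-gain stop threshold for tying, or `NULL`
#'   to auto-calibrate to `target_ratio` (see [tie_states()]).
#' @param target_ratio Tied/seen state ratio for auto-calibration;
#'   default 0.2, of the order of the published tied/seen reduction
#'   (~115 tied from 364 seen states) and small enough that every tied
#'   state pools several context variants at desk-scale data volumes.
#' @param tie_min_occ Minimum frame occupancy on each side of an accepted
#'   tying split; default 100 frames, keeping every tied state estimable.
#' @param smooth_tau Prior weight (frames) for MAP-smoothing every
#'   context-dependent state toward its context-independent parent state
#'   after training, the standard regularizer for sparsely observed
#'   context models; default 100.  Applied to single-component pdfs (the
#'   desk-scale setting); 0 disables.
#' @return A trained `eog_hmm_set` with `$meta` describing the system.
#' @export
train_system <- function(corpus, unit_kind = c("mono", "bi", "tri"),
                         features = c("six", "two"),
                         config = train_config(),
                         n_states = 4, tie = NULL,
                         tie_threshold = NULL, target_ratio = 0.2,
                         tie_min_occ = 100, smooth_tau = 100) {
  unit_kind <- match.arg(unit_kind)
  features <- match.arg(features)
  if (is.null(tie)) tie <- unit_kind == "tri"
  stopifnot(length(corpus) > 0)
  featfun <- if (features == "six") six_channel_features else
    two_channel_features
  items <- lapply(corpus, function(it) {
    list(
      motions = it$motions,
      feats = featfun(it$recording)$vectors,
      has_sil = any(it$recording$labels$motion == sil_label())
    )
  })
  X_all <- do.call(rbind, lapply(items, `[[`, "feats"))
  gm <- colMeans(X_all)
  gv <- apply(X_all, 2, stats::var)

  chains_for <- function(kind) lapply(items, function(it) {
    units <- expand_units(it$motions, kind)
    if (it$has_sil) units <- c(sil_label(), units, sil_label())
    list(units = units, feats = it$feats)
  })

  cfg_single <- train_config(
    n_iterations = config$n_iterations, mixture_schedule = 1,
    convergence_tol = config$convergence_tol,
    min_occupancy = config$min_occupancy)

  mono_chains <- chains_for("mono")
  mono_units <- unique(unlist(lapply(mono_chains, `[[`, "units")))
  set <- make_hmm_set(mono_units, gm, gv, n_states)
  set <- baum_welch(set, mono_chains, cfg_single)

  if (unit_kind != "mono") {
    chains <- chains_for(unit_kind)
    ctx_units <- setdiff(unique(unlist(lapply(chains, `[[`, "units"))),
                         names(set$units))
    set <- clone_units(set, ctx_units)
    set <- baum_welch(set, chains, cfg_single)
    if (tie) {
      stats <- accumulate_state_stats(set, chains)
      tied <- tie_states(set, stats, threshold = tie_threshold,
                         target_ratio = target_ratio, min_occ = tie_min_occ)
      set <- tied$set
    }
    set <- baum_welch(set, chains, config)
    if (smooth_tau > 0)
      set <- smooth_context_models(set, chains, tau = smooth_tau)
  } else {
    set <- baum_welch(set, mono_chains, config)
  }
  set$meta <- list(unit_kind = unit_kind, features = features,
                   n_training_sequences = length(corpus))
  set
}

#' Clone context-free models to context-dependent units
#'
#' Each new unit receives copies of its target motion's pdfs and transition
#' matrix, as the starting point for context-dependent re-estimation.
#'
#' @param set An `eog_hmm_set` containing the target (mono) units.
#' @param new_names Context-dependent unit names to create.
#' @return The augmented model set.
#' @export
clone_units <- function(set, new_names) {
  for (nm in new_names) {
    if (nm %in% names(set$units)) next
    target <- parse_unit_name(nm)$target
    src <- set$units[[target]]
    if (is.null(src))
      stop("no source model '", target, "' to clone for unit '", nm, "'")
    ids <- integer(length(src$pdf_ids))
    for (j in seq_along(src$pdf_ids)) {
      set$pdfs[[length(set$pdfs) + 1]] <- set$pdfs[[src$pdf_ids[j]]]
      ids[j] <- length(set$pdfs)
    }
    set$units[[nm]] <- list(pdf_ids = ids, trans = src$trans)
  }
  set
}

# Features of a recording under a trained system's front-end.
system_features <- function(set, rec) {
  f <- if (!is.null(set$meta) && identical(set$meta$features, "two"))
    two_channel_features(rec) else six_channel_features(rec)
  f$vectors
}

#' Training chains for a corpus under a system's unit kind
#'
#' Convenience wrapper used for adaptation: expands each item's motions to
#' the system's unit inventory (backing off unseen units to their
#' context-stripped models) and extracts features with the system's
#' front-end.
#'
#' @param set A trained `eog_hmm_set`.
#' @param corpus List of elements with `motions` and `recording`.
#' @return List with `set` (possibly augmented with tying-synthesized
#'   units) and `chains` (`units` + `feats` elements for [baum_welch()]).
#' @export
system_chains <- function(set, corpus) {
  kind <- set$meta$unit_kind
  chains <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    it <- corpus[[i]]
    units <- expand_units(it$motions, kind)
    has_sil <- any(it$recording$labels$motion == sil_label())
    resolved <- character(length(units))
    for (j in seq_along(units)) {
      r <- resolve_decoding_unit(set, units[j])
      set <- r$set
      resolved[j] <- r$name
    }
    if (has_sil) resolved <- c(sil_label(), resolved, sil_label())
    chains[[i]] <- list(units = resolved,
                        feats = system_features(set, it$recording))
  }
  list(set = set, chains = chains)
}

#' MAP-smooth context-dependent states toward their mono parents
#'
#' Each context unit's state Gaussian is interpolated with the
#' corresponding state of its target motion's context-independent model,
#' weighted by the state's training occupancy against a prior count
#' `tau`: sparsely observed context states move most of the way back to
#' the robust pooled model, well-observed ones barely move.  Pooled
#' second moments keep the variances consistent.  Only single-component
#' pdfs are smoothed (mixtures are a full-scale setting where data volume
#' replaces the prior).
#'
#' @param set A trained `eog_hmm_set` containing both the context units
#'   and their mono parents.
#' @param chains Training chains (as used by [baum_welch()]) from which
#'   state occupancies are accumulated.
#' @param tau Prior weight in frames (> 0).
#' @return The smoothed model set.
#' @export
smooth_context_models <- function(set, chains, tau = 100) {
  stopifnot(tau > 0)
  stats <- accumulate_state_stats(set, chains)
  done <- rep(FALSE, length(set$pdfs))
  for (u in names(set$units)) {
    pu <- parse_unit_name(u)
    if (pu$kind %in% c("sil", "mono")) next
    mono <- set$units[[pu$target]]
    if (is.null(mono)) next
    for (pos in seq_along(set$units[[u]]$pdf_ids)) {
      pid <- set$units[[u]]$pdf_ids[pos]
      if (done[pid]) next
      done[pid] <- TRUE
      mp <- set$pdfs[[mono$pdf_ids[pos]]]
      cp <- set$pdfs[[pid]]
      if (length(mp$weights) != 1 || length(cp$weights) != 1) next
      occ <- stats[[pid]]$occ
      mu_c <- cp$means[1, ]; mu_m <- mp$means[1, ]
      mu <- (tau * mu_m + occ * mu_c) / (tau + occ)
      v <- (tau * (mp$vars[1, ] + (mu_m - mu)^2) +
            occ * (cp$vars[1, ] + (mu_c - mu)^2)) / (tau + occ)
      set$pdfs[[pid]] <- list(weights = 1, means = matrix(mu, 1),
                              vars = matrix(pmax(v, set$var_floor), 1))
    }
  }
  set
}
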