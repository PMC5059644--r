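#' Threshold-based baseline recognizer
#'
#' The conventional non-probabilistic recognizer used as a point of
#' comparison for the HMM systems.  It works on the 2-D horizontal/vertical
#' EOG vector: per sample, if the vector norm is below a threshold the
#' sample is classified as "center"; otherwise the inner products with the
#' four direction unit vectors (1,0) -> left, (0,1) -> up, (-1,0) -> right,
#' (0,-1) -> down are compared and the largest wins.  A sliding-window
#' majority vote (1000 ms window, 10 ms shift by default) stabilizes the
#' per-sample decisions, and consecutive identical labels are merged into
#' single motion events.
#'
#' @name baseline_threshold
NULL

#' Baseline configuration
#'
#' @param center_threshold Norm threshold in microvolt below which a sample
#'   is classified as "center" (> 0).  A practical default is half the
#'   user's amplitude scale (the projected 2-D deflection of a pure motion
#'   is about twice the per-channel amplitude).
#' @param vote_window Voting window width in ms; default 1000.
#' @param vote_shift Voting window shift in ms; default 10.
#' @return An object of class `eog_threshold_config`.
#' @export
threshold_config <- function(center_threshold, vote_window = 1000,
                             vote_shift = 10) {
  stopifnot(center_threshold > 0, vote_shift > 0, vote_window >= vote_shift)
  structure(
    list(center_threshold = center_threshold, vote_window = vote_window,
         vote_shift = vote_shift),
    class = "eog_threshold_config"
  )
}

#' Per-sample direction classification
#'
#' @param feats 2-D `eog_features` (from [two_channel_features()]).
#' @param config An [threshold_config()].
#' @return Character vector of per-sample motion labels.
#' @export
classify_samples <- function(feats, config) {
  stopifnot(inherits(feats, "eog_features"),
            inherits(config, "eog_threshold_config"))
  v <- feats$vectors
  if (ncol(v) != 2) stop("baseline requires 2-D features, got ", ncol(v))
  # inner products with (1,0), (0,1), (-1,0), (0,-1); ties broken in the
  # fixed order left, up, right, down
  ips <- cbind(left = v[, 1], up = v[, 2], right = -v[, 1], down = -v[, 2])
  lab <- colnames(ips)[max.col(ips, ties.method = "first")]
  lab[sqrt(rowSums(v^2)) < config$center_threshold] <- "center"
  lab
}

#' Sliding-window majority-vote postfilter
#'
#' Votes over a window of `vote_window` ms advanced by `vote_shift` ms; the
#' most frequent label in each window is emitted (one label per shift
#' position).  A signal shorter than one window yields a single vote over
#' the available samples.  Ties go to the label earliest in the fixed order
#' up, down, left, right, center.
#'
#' @param labels Per-sample motion labels.
#' @param config An [threshold_config()].
#' @param sample_rate Sampling rate of `labels` in Hz; default 100.
#' @return Character vector of per-window labels.
#' @export
vote_filter <- function(labels, config, sample_rate = 100) {
  stopifnot(inherits(config, "eog_threshold_config"))
  n <- length(labels)
  if (n == 0) return(character(0))
  win <- max(1L, as.integer(round(config$vote_window / 1000 * sample_rate)))
  shift <- max(1L, as.integer(round(config$vote_shift / 1000 * sample_rate)))
  if (n <= win) starts <- 1L
  else starts <- seq(1L, n - win + 1L, by = shift)
  order_pref <- c(motion_alphabet())
  vapply(starts, function(s) {
    w <- labels[s:min(s + win - 1L, n)]
    tab <- table(factor(w, levels = order_pref))
    names(tab)[which.max(tab)]
  }, character(1))
}

#' Merge consecutive identical labels into motion events
#' @param labels Character vector of (filtered) labels.
#' @return Character vector with runs collapsed (run-length encoding heads).
#' @export
merge_events <- function(labels) {
  if (length(labels) == 0) return(character(0))
  labels[c(TRUE, labels[-1] != labels[-length(labels)])]
}

#' Full baseline pipeline: recording to motion sequence
#'
#' Applies [two_channel_features()], [classify_samples()], [vote_filter()]
#' and [merge_events()], then strips leading/trailing "center" events (the
#' resting gaze around the recording's sil padding).
#'
#' @param rec An `eog_recording`.
#' @param config An [threshold_config()].
#' @return Character vector: the recognized motion sequence.
#' @export
baseline_recognize <- function(rec, config) {
  feats <- two_channel_features(rec)
  lab <- classify_samples(feats, config)
  lab <- vote_filter(lab, config, sample_rate = rec$sample_rate)
  ev <- merge_events(lab)
  # the resting gaze during boundary sil padding is indistinguishable from a
  # "center" motion; drop boundary center events rather than score them
  if (length(ev) > 0 && ev[1] == "center") ev <- ev[-1]
  if (length(ev) > 0 && ev[length(ev)] == "center") ev <- ev[-length(ev)]
  ev
}
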