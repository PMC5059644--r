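#' Observation features from an EOG recording
#'
#' The recognizer consumes the raw channel values frame-by-frame: no
#' windowing, no deltas, so the feature frame rate equals the recording's
#' sample rate.  Two front-ends are provided: the six-dimensional feature
#' (one element per measurement channel) used by the main recognizer, and
#' the two-dimensional horizontal/vertical projection used by the
#' threshold baseline and the 2-channel HMM comparison.
#'
#' @name features
NULL

feature_seq <- function(vectors, frame_rate) {
  structure(list(vectors = vectors, frame_rate = frame_rate),
            class = "eog_features")
}

#' @export
print.eog_features <- function(x, ...) {
  cat(sprintf("EOG features: %d frames x %d dims at %g Hz\n",
              nrow(x$vectors), ncol(x$vectors), x$frame_rate))
  invisible(x)
}

check_six_channels <- function(rec) {
  stopifnot(inherits(rec, "eog_recording"))
  if (ncol(rec$samples) != 6)
    stop("recording has ", ncol(rec$samples), " channels; 6 required")
}

#' Six-dimensional channel features
#'
#' Identity mapping of the six channel values per sample, with optional
#' per-recording mean removal (off by default: the raw channel values are
#' fed to the models).
#'
#' @param rec An `eog_recording` with 6 channels.
#' @param remove_mean If `TRUE`, subtract each channel's recording mean.
#' @return An `eog_features` object with 6-dim vectors.
#' @export
six_channel_features <- function(rec, remove_mean = FALSE) {
  check_six_channels(rec)
  v <- rec$samples
  if (remove_mean) v <- sweep(v, 2, colMeans(v))
  feature_seq(unname(v), rec$sample_rate)
}

#' Two-dimensional horizontal/vertical features
#'
#' Per sample: horizontal = CH2 - CH5 (positive looking left), vertical =
#' mean(CH1, CH6) - mean(CH3, CH4) (positive looking up).  This is the
#' signal used by the threshold baseline and by the 2-channel HMM
#' comparison.
#'
#' @param rec An `eog_recording` with 6 channels.
#' @param remove_mean If `TRUE`, subtract each output dimension's mean.
#' @return An `eog_features` object with 2-dim vectors.
#' @export
two_channel_features <- function(rec, remove_mean = FALSE) {
  check_six_channels(rec)
  s <- rec$samples
  h <- s[, 2] - s[, 5]
  v <- (s[, 1] + s[, 6]) / 2 - (s[, 3] + s[, 4]) / 2
  m <- cbind(h, v, deparse.level = 0)
  if (remove_mean) m <- sweep(m, 2, colMeans(m))
  feature_seq(m, rec$sample_rate)
}

#' Write a feature sequence to CSV (one row per frame)
#' @param feats An `eog_features` object.
#' @param path Output path.
#' @export
write_features_csv <- function(feats, path) {
  stopifnot(inherits(feats, "eog_features"))
  df <- as.data.frame(feats$vectors)
  names(df) <- paste0("f", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
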