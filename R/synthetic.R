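#' User profile for synthetic EOG generation
#'
#' Bundles the user-specific parameters of the synthetic EOG generator.
#' Between-user differences in real recordings are dominated by signal
#' amplitude (the corneoretinal potential projects at roughly 290 to 1100
#' microvolt per radian of gaze deflection, depending on the person and the
#' electrode contact) and by the speed of eye motion; both are explicit here
#' so that user-independent versus user-dependent modeling can be emulated.
#'
#' @param amplitude_scale Signal amplitude in microvolt for a full (unit)
#'   gaze deflection.  Default 600; must lie in `[290, 1100]` unless
#'   `strict = FALSE`.
#' @param motion_duration_mean Mean duration of one motion segment in
#'   seconds (> 0).  Default 0.4.
#' @param motion_duration_std Standard deviation of the segment duration in
#'   seconds (>= 0).  Default 0.1.
#' @param rise_time Duration of the saccade transition ramp in seconds.
#'   Default 0.25: at typical fast-input segment durations (~0.4 s) the
#'   transition spans most of the segment, so the rendered shape of a
#'   motion carries its predecessor's imprint across the whole segment,
#'   matching the persistent context-dependent gradients seen in real
#'   recordings of sequential eye motions.
#' @param noise_std Standard deviation of the band-limited measurement noise
#'   in microvolt (>= 0).  Default 40.
#' @param drift_rate Electrode drift scale in microvolt per square-root
#'   second: the drift is an integrated Gaussian random walk whose standard
#'   deviation after one second equals `drift_rate`.  Default 20:
#'   baseline wander from electrode polarization and skin potential
#'   changes, reaching a visible fraction of the gaze signal over a
#'   recording.
#' @param gaze_jitter Relative standard deviation of the per-motion gaze
#'   deflection amplitude (saccadic endpoint variability); each motion's
#'   target is scaled by `N(1, gaze_jitter)`.  Default 0.15, a typical
#'   saccadic under/overshoot spread.
#' @param rise_jitter Relative standard deviation of the per-motion
#'   transition duration (velocity variability).  Default 0.2.
#' @param sil_pad Duration in seconds of the "sil" (no motion, gaze at
#'   center) padding added at both recording boundaries.  Default 0.5.
#' @param strict If `TRUE` (default), enforce the amplitude range.
#' @return An object of class `eog_profile`.
#' @export
eog_profile <- function(amplitude_scale = 600,
                        motion_duration_mean = 0.4,
                        motion_duration_std = 0.1,
                        rise_time = 0.25,
                        noise_std = 40,
                        drift_rate = 20,
                        gaze_jitter = 0.15,
                        rise_jitter = 0.2,
                        sil_pad = 0.5,
                        strict = TRUE) {
  if (!is.numeric(amplitude_scale) || amplitude_scale <= 0)
    stop("amplitude_scale must be positive")
  if (strict && (amplitude_scale < 290 || amplitude_scale > 1100))
    stop("amplitude_scale must lie in [290, 1100] microvolt")
  if (motion_duration_mean <= 0) stop("motion_duration_mean must be positive")
  if (motion_duration_std < 0) stop("motion_duration_std must be >= 0")
  if (rise_time <= 0) stop("rise_time must be positive")
  if (noise_std < 0) stop("noise_std must be >= 0")
  if (drift_rate < 0) stop("drift_rate must be >= 0")
  if (sil_pad < 0) stop("sil_pad must be >= 0")
  if (gaze_jitter < 0 || rise_jitter < 0) stop("jitters must be >= 0")
  structure(
    list(
      amplitude_scale = amplitude_scale,
      motion_duration_mean = motion_duration_mean,
      motion_duration_std = motion_duration_std,
      rise_time = rise_time,
      noise_std = noise_std,
      drift_rate = drift_rate,
      gaze_jitter = gaze_jitter,
      rise_jitter = rise_jitter,
      sil_pad = sil_pad
    ),
    class = "eog_profile"
  )
}

#' @export
print.eog_profile <- function(x, ...) {
  cat("EOG user profile:\n")
  cat(sprintf("  amplitude        %.0f uV / unit deflection\n", x$amplitude_scale))
  cat(sprintf("  motion duration  %.0f +/- %.0f ms\n",
              1000 * x$motion_duration_mean, 1000 * x$motion_duration_std))
  cat(sprintf("  saccade rise     %.0f ms\n", 1000 * x$rise_time))
  cat(sprintf("  noise sd         %.0f uV, drift %.0f uV/sqrt(s)\n",
              x$noise_std, x$drift_rate))
  invisible(x)
}

# Fixed channel geometry: projection of the 2-D latent gaze state (h, v)
# onto the six measurement channels.  CH1/CH6 sit above the eyes (positive
# for "up"), CH3/CH4 below (positive for "down"), CH2 at the left temple
# (positive for "left"), CH5 at the right temple (positive for "right").
channel_geometry <- function() {
  rbind(
    CH1 = c(0,  1),
    CH2 = c(1,  0),
    CH3 = c(0, -1),
    CH4 = c(0, -1),
    CH5 = c(-1, 0),
    CH6 = c(0,  1)
  )
}

# Brick-wall FFT low-pass: keep components strictly below `cutoff` Hz and
# rescale so the output standard deviation matches the input's target.
lowpass_noise <- function(n, sd, cutoff, sample_rate) {
  if (sd == 0 || n == 0) return(numeric(n))
  x <- stats::rnorm(n, 0, sd)
  if (cutoff >= sample_rate / 2) return(x)
  sp <- stats::fft(x)
  freqs <- (seq_len(n) - 1) * sample_rate / n
  # two-sided spectrum: keep bins whose aliased frequency is below cutoff
  keep <- pmin(freqs, sample_rate - freqs) < cutoff
  sp[!keep] <- 0
  y <- Re(stats::fft(sp, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s > 0) y <- y * (sd / s)
  y
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic labeled EOG recording for a motion sequence
#'
#' Renders each motion as a smooth saccade: the 2-D latent gaze state moves
#' from its current position to the motion's target position along a
#' logistic ramp of duration `profile$rise_time`, then holds for the rest of
#' the segment.  The latent state is projected to the six measurement
#' channels by the fixed channel geometry, and band-limited Gaussian noise
#' (power below 30 Hz) plus an integrated random-walk drift are added.
#' Because every segment starts from wherever the previous motion left the
#' gaze, the rendered shape of a motion depends on its predecessor: the same
#' "center" motion rises after "down" but falls after "up".
#'
#' @param motions Character vector of motion labels (validated).
#' @param profile An [eog_profile()].
#' @param sample_rate Sampling rate in Hz; default 100.
#' @param seed Optional integer seed; with a fixed seed repeated calls are
#'   bit-identical.
#' @return An object of class `eog_recording`: a list with `samples`
#'   (T x 6 matrix, microvolt, columns CH1..CH6), `sample_rate`, and
#'   `labels`, a data frame of half-open sample intervals
#'   (`start`, `end`, `motion`; 0-based, `end` exclusive) covering the whole
#'   signal, including `"sil"` padding segments.
#' @export
generate_recording <- function(motions, profile = eog_profile(),
                               sample_rate = 100, seed = NULL) {
  validate_motion_sequence(motions)
  stopifnot(inherits(profile, "eog_profile"), sample_rate > 0)
  with_seed(seed, {
    tgt <- gaze_targets()
    # segment durations in samples (minimum 2 ramp lengths not enforced;
    # floor at 50 ms so a segment is never empty)
    durs <- stats::rnorm(length(motions), profile$motion_duration_mean,
                         profile$motion_duration_std)
    durs <- pmax(durs, 0.05)
    if (any(durs <= 0)) stop("non-positive motion duration")
    seg_len <- pmax(1L, as.integer(round(durs * sample_rate)))
    pad_len <- as.integer(round(profile$sil_pad * sample_rate))

    lens <- c(if (pad_len > 0) pad_len, seg_len, if (pad_len > 0) pad_len)
    labs <- c(if (pad_len > 0) sil_label(), motions,
              if (pad_len > 0) sil_label())
    total <- sum(lens)

    # latent gaze trajectory: logistic ramp to each segment's target,
    # with per-motion endpoint (gaze_jitter) and velocity (rise_jitter)
    # variability
    pos <- c(h = 0, v = 0)   # gaze starts at center ("sil")
    latent <- matrix(0, nrow = total, ncol = 2)
    at <- 0L
    for (i in seq_along(lens)) {
      target <- if (labs[i] == sil_label()) c(0, 0) else tgt[labs[i], ]
      target <- target * max(0.2, stats::rnorm(1, 1, profile$gaze_jitter))
      rise <- profile$rise_time *
        max(0.3, stats::rnorm(1, 1, profile$rise_jitter))
      k <- 10 / rise                 # ramp ~99% complete within rise
      tt <- (seq_len(lens[i]) - 0.5) / sample_rate
      s <- 1 / (1 + exp(-k * (tt - rise / 2)))
      seg <- outer(1 - s, pos) + outer(s, target)
      latent[at + seq_len(lens[i]), ] <- seg
      pos <- seg[lens[i], ]
      at <- at + lens[i]
    }

    clean <- latent %*% t(channel_geometry()) * profile$amplitude_scale
    noise <- vapply(1:6, function(j)
      lowpass_noise(total, profile$noise_std, 30, sample_rate),
      numeric(total))
    drift <- vapply(1:6, function(j) {
      if (profile$drift_rate == 0) return(numeric(total))
      cumsum(stats::rnorm(total, 0, profile$drift_rate / sqrt(sample_rate)))
    }, numeric(total))
    samples <- clean + noise + drift
    colnames(samples) <- rownames(channel_geometry())

    starts <- cumsum(c(0L, lens[-length(lens)]))
    labels <- data.frame(
      start = starts, end = starts + lens, motion = labs,
      stringsAsFactors = FALSE
    )
    structure(
      list(samples = samples, sample_rate = sample_rate, labels = labels),
      class = "eog_recording"
    )
  })
}

#' @export
print.eog_recording <- function(x, ...) {
  cat(sprintf(
    "EOG recording: %d samples x %d channels at %g Hz (%.2f s)\n",
    nrow(x$samples), ncol(x$samples), x$sample_rate,
    nrow(x$samples) / x$sample_rate
  ))
  if (!is.null(x$labels)) {
    m <- x$labels$motion[x$labels$motion != sil_label()]
    cat("  motions:", paste(m, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Extract the motion sequence from a recording's label track
#' @param rec An `eog_recording` with labels.
#' @return Character vector of motion labels with `"sil"` removed.
#' @export
recording_motions <- function(rec) {
  stopifnot(inherits(rec, "eog_recording"), !is.null(rec$labels))
  m <- rec$labels$motion
  m[m != sil_label()]
}

#' Generate a labeled synthetic EOG corpus
#'
#' Samples `n_sequences` motion sequences uniformly over valid (no adjacent
#' repeat) sequences with lengths uniform over `length_range`, and renders
#' each with [generate_recording()].
#'
#' @param n_sequences Number of sequences (>= 0).
#' @param length_range Integer vector `c(min, max)` of motions per sequence;
#'   default `c(4, 8)`.
#' @param profile An [eog_profile()].
#' @param sample_rate Sampling rate in Hz.
#' @param seed Optional integer seed for reproducibility.
#' @return A list of length `n_sequences`; each element is a list with
#'   `motions` and `recording`.
#' @export
generate_corpus <- function(n_sequences, length_range = c(4, 8),
                            profile = eog_profile(), sample_rate = 100,
                            seed = NULL) {
  stopifnot(n_sequences >= 0, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  with_seed(seed, {
    lapply(seq_len(n_sequences), function(i) {
      len <- sample(seq(length_range[1], length_range[2]), 1)
      motions <- random_motion_sequence(len)
      list(motions = motions,
           recording = generate_recording(motions, profile, sample_rate))
    })
  })
}

#' Motion sequences of one training unit
#'
#' One unit of training data is a set of 22 motion sequences (lengths four
#' to eight, 136 motions in total on average) constructed greedily so that
#' nearly all valid (predecessor, target, successor) context triples occur:
#' each new sequence extends through uncovered triples when possible.
#' This is the designed-coverage recording protocol that makes
#' context-dependent models estimable from few units of data.
#'
#' @param seed Optional integer seed.
#' @return A list of 22 (or slightly more) motion sequences.
#' @export
training_unit_sequences <- function(seed = NULL) {
  with_seed(seed, {
    ab <- motion_alphabet()
    triple_key <- function(p, t, s) paste(p, t, s)
    uncovered <- new.env(parent = emptyenv())
    for (t in ab) for (p in setdiff(ab, t)) for (s in setdiff(ab, t))
      assign(triple_key(p, t, s), TRUE, envir = uncovered)
    n_uncovered <- function() length(ls(uncovered))
    cover <- function(seq) {
      if (length(seq) >= 3)
        for (i in 2:(length(seq) - 1)) {
          k <- triple_key(seq[i - 1], seq[i], seq[i + 1])
          if (exists(k, envir = uncovered)) rm(list = k, envir = uncovered)
        }
    }
    seqs <- list()
    while (n_uncovered() > 0 && length(seqs) < 30) {
      len <- sample(4:8, 1)
      # seed the sequence with an uncovered triple
      k0 <- sample(ls(uncovered), 1)
      seq <- strsplit(k0, " ", fixed = TRUE)[[1]]
      while (length(seq) < len) {
        last <- seq[length(seq)]
        prev <- seq[length(seq) - 1]
        cands <- setdiff(ab, last)
        # prefer a successor that completes an uncovered triple
        good <- cands[vapply(cands, function(s)
          exists(triple_key(prev, last, s), envir = uncovered), logical(1))]
        seq <- c(seq, if (length(good) > 0) sample(good, 1)
                      else sample(cands, 1))
      }
      cover(seq)
      seqs[[length(seqs) + 1]] <- seq
    }
    while (length(seqs) < 22)
      seqs[[length(seqs) + 1]] <- random_motion_sequence(sample(4:8, 1))
    seqs
  })
}

#' Generate one unit of training data
#'
#' Renders the designed-coverage sequences of [training_unit_sequences()]
#' with the given user profile.
#'
#' @param profile An [eog_profile()].
#' @param sample_rate Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return A list of `motions` + `recording` items (one unit of data).
#' @export
generate_training_unit <- function(profile = eog_profile(),
                                   sample_rate = 100, seed = NULL) {
  with_seed(seed, {
    lapply(training_unit_sequences(), function(m)
      list(motions = m,
           recording = generate_recording(m, profile, sample_rate)))
  })
}

#' Sample a population of user profiles
#'
#' Draws user profiles with independent amplitude, speed, and noise levels,
#' emulating the between-user variation (different amplitudes and different
#' speeds of eye motion) that degrades user-independent models.
#'
#' @param n Number of users.
#' @param seed Optional integer seed.
#' @return List of [eog_profile()] objects.
#' @export
sample_user_profiles <- function(n, seed = NULL) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      eog_profile(
        amplitude_scale = stats::runif(1, 350, 1000),
        motion_duration_mean = stats::runif(1, 0.25, 0.40),
        motion_duration_std = 0.08,
        noise_std = stats::runif(1, 25, 60),
        drift_rate = stats::runif(1, 10, 40)
      )
    })
  })
}
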