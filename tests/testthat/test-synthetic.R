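test_that("recording length, labels, and determinism behave as specified", {
  p <- eog_profile(noise_std = 0, drift_rate = 0, motion_duration_std = 0,
                   gaze_jitter = 0, rise_jitter = 0, sil_pad = 0)
  r <- generate_recording("up", p, seed = 5)
  expect_equal(nrow(r$samples), 40)   # 0.4 s at 100 Hz, no padding
  expect_equal(r$labels$start[1], 0)
  expect_equal(r$labels$end[nrow(r$labels)], nrow(r$samples))

  r2 <- generate_recording("up", p, seed = 5)
  expect_identical(r$samples, r2$samples)

  # label/sample conservation with padding and jitter
  p2 <- eog_profile()
  r3 <- generate_recording(c("up", "left", "center"), p2, seed = 1)
  expect_equal(sum(r3$labels$end - r3$labels$start), nrow(r3$samples))
  expect_true(all(r3$labels$start == c(0, head(r3$labels$end, -1))))
  expect_equal(recording_motions(r3), c("up", "left", "center"))
})

test_that("generator rejects invalid input", {
  expect_error(generate_recording(character(0)), "empty")
  expect_error(generate_recording(c("up", "up")), "adjacent")
  expect_error(generate_recording("sideways"), "unknown motion")
  expect_error(eog_profile(motion_duration_mean = -1), "positive")
  expect_error(eog_profile(amplitude_scale = 100), "290")
  expect_error(eog_profile(noise_std = -5), ">= 0")
})

test_that("identical motions have context-dependent shapes", {
  p <- eog_profile(noise_std = 0, drift_rate = 0, motion_duration_std = 0,
                   gaze_jitter = 0, rise_jitter = 0)
  seg <- function(r) {
    i <- which(r$labels$motion == "center")
    r$samples[(r$labels$start[i] + 1):r$labels$end[i], 1]
  }
  s_up <- seg(generate_recording(c("up", "center"), p, seed = 1))
  s_dn <- seg(generate_recording(c("down", "center"), p, seed = 1))
  slope <- function(x) unname(coef(lm(x ~ seq_along(x)))[2])
  # CH1 falls back to baseline after "up" but rises after "down"
  expect_lt(slope(s_up), 0)
  expect_gt(slope(s_dn), 0)

  # context property: same motion, different predecessors, different mean
  # shape (L2 distance bounded away from zero without noise)
  expect_gt(sqrt(mean((s_up - s_dn)^2)), 0.1 * p$amplitude_scale)
})

test_that("pure-motion deflections respect the amplitude scale", {
  p <- eog_profile(noise_std = 0, drift_rate = 0, gaze_jitter = 0,
                   rise_jitter = 0, motion_duration_std = 0,
                   motion_duration_mean = 0.8)
  r <- generate_recording(c("up", "center", "down"), p, seed = 2)
  i <- which(r$labels$motion == "up")
  hold <- r$samples[(r$labels$end[i] - 5):r$labels$end[i], 1]  # CH1 at hold
  expect_true(all(abs(hold - p$amplitude_scale) < 1e-6 * p$amplitude_scale))
  j <- which(r$labels$motion == "down")
  hold_d <- r$samples[(r$labels$end[j] - 5):r$labels$end[j], 3] # CH3 at hold
  expect_true(all(abs(hold_d - p$amplitude_scale) < 0.02 * p$amplitude_scale))
})

test_that("noise is band-limited below 30 Hz", {
  p <- eog_profile(noise_std = 40, drift_rate = 0, gaze_jitter = 0,
                   rise_jitter = 0, sil_pad = 0)
  set.seed(99)
  # a long center-only recording isolates the noise
  r <- generate_recording(rep(c("center", "up"), 10),
                          eog_profile(noise_std = 40, drift_rate = 0,
                                      gaze_jitter = 0, rise_jitter = 0,
                                      motion_duration_mean = 0.3),
                          seed = 99)
  # estimate noise from a sil-padded stretch (constant latent signal)
  sil <- r$samples[2:45, 2]  # CH2 during leading sil, latent is 0
  spec <- stats::spec.pgram(sil - mean(sil), plot = FALSE)
  freq_hz <- spec$freq * r$sample_rate
  p_below <- sum(spec$spec[freq_hz < 30]) / sum(spec$spec)
  expect_gt(p_below, 0.99)
})

test_that("generate_corpus samples valid sequences reproducibly", {
  p <- fixture_profile()
  corpus <- generate_corpus(22, c(4, 8), p, seed = 7)
  expect_length(corpus, 22)
  for (it in corpus) {
    expect_true(all(it$motions %in% motion_alphabet()))
    expect_true(all(it$motions[-1] != head(it$motions, -1)))
    expect_gte(length(it$motions), 4)
    expect_lte(length(it$motions), 8)
  }
  expect_length(generate_corpus(0, profile = p), 0)
  corpus2 <- generate_corpus(22, c(4, 8), p, seed = 7)
  expect_identical(corpus[[5]]$recording$samples,
                   corpus2[[5]]$recording$samples)
})

test_that("training units cover nearly all context triples", {
  seqs <- training_unit_sequences(seed = 3)
  expect_gte(length(seqs), 22)
  triples <- character(0)
  for (s in seqs) {
    validate_motion_sequence(s)
    if (length(s) >= 3)
      for (i in 2:(length(s) - 1))
        triples <- c(triples, paste(s[i - 1], s[i], s[i + 1]))
  }
  # 80 valid (p, t, s) triples over 5 motions with p != t, s != t
  expect_gte(length(unique(triples)), 75)
})
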