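feat2 <- function(m) structure(list(vectors = m, frame_rate = 100),
                               class = "eog_features")

test_that("per-sample classification maps directions and threshold", {
  cfg <- threshold_config(center_threshold = 1)
  f <- feat2(rbind(c(0.1, 0.05),   # sub-threshold -> center
                   c(3, 0.5),      # -> left
                   c(0, -2),       # -> down
                   c(-1.5, 0.2),   # -> right
                   c(0.3, 2)))     # -> up
  cfg02 <- threshold_config(center_threshold = 0.2)
  expect_equal(classify_samples(f, cfg02)[1], "center")
  expect_equal(classify_samples(f, cfg), c("center", "left", "down",
                                           "right", "up"))
  expect_error(classify_samples(
    structure(list(vectors = matrix(0, 3, 6), frame_rate = 100),
              class = "eog_features"), cfg), "2-D")
})

test_that("raising the threshold never decreases center decisions", {
  set.seed(2)
  f <- feat2(matrix(rnorm(400, sd = 2), 200, 2))
  n_center <- sapply(c(0.5, 1, 2, 4), function(th)
    sum(classify_samples(f, threshold_config(th)) == "center"))
  expect_true(all(diff(n_center) >= 0))
})

test_that("vote filter matches an independent windowed recount", {
  cfg <- threshold_config(300, vote_window = 1000, vote_shift = 10)
  # constant stream is unchanged
  expect_true(all(vote_filter(rep("up", 150), cfg, 100) == "up"))
  # 60/40 mixture in every window
  mix <- rep(c("up", "up", "up", "down", "down"), 40)
  expect_true(all(vote_filter(mix, cfg, 100) == "up"))
  # random stream vs oracle
  set.seed(5)
  lab <- sample(motion_alphabet(), 350, TRUE)
  expect_identical(vote_filter(lab, cfg, 100),
                   vote_oracle(lab, 100L, 1L, motion_alphabet()))
  # shorter than one window: single pooled vote
  expect_length(vote_filter(rep("left", 30), cfg, 100), 1)
})

test_that("event merging collapses runs only", {
  expect_equal(merge_events(c("up", "up", "center", "center", "center")),
               c("up", "center"))
  expect_equal(merge_events(character(0)), character(0))
  alt <- rep(c("up", "down"), 5)
  expect_equal(merge_events(alt), alt)
})

test_that("the full baseline recovers slow, clean motion sequences", {
  p <- eog_profile(motion_duration_mean = 1.2, motion_duration_std = 0.05,
                   noise_std = 10, drift_rate = 2, gaze_jitter = 0.02,
                   rise_jitter = 0.05)
  motions <- c("up", "left", "down", "center", "right")
  rec <- generate_recording(motions, p, seed = 1)
  cfg <- threshold_config(0.5 * p$amplitude_scale)
  expect_equal(baseline_recognize(rec, cfg), motions)
})
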