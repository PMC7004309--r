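test_that("beat detection recovers ground-truth onsets on clean recordings", {
  cfg <- sim_config(heart_rate_mean = 60, heart_rate_sd = 0, noise_sd = 0,
                    artifact_beat_rate = 0, rng_seed = 1)
  rec <- generate_recording(cfg, flow_type_library()$I)
  beats <- detect_beats(rec)
  onsets <- vapply(beats, function(b) attr(b, "onset_index"), integer(1))
  gt <- rec$ground_truth$onsets
  expect_lte(abs(length(onsets) - length(gt)), 1)
  err <- vapply(onsets, function(o) min(abs(gt - o)), numeric(1))
  expect_lte(max(err), 3)
})

test_that("a constant signal is flagged unusable rather than erroring", {
  rec <- list(samples = rep(50, 1000), fs = 125)
  beats <- detect_beats(rec)
  expect_length(beats, 0)
  expect_true(attr(beats, "unusable"))
})

test_that("two concatenated noise-free beats are segmented exactly", {
  spec <- flow_type_library()$I
  b <- generate_beat(spec, 1.0, 125, 0)
  rec <- list(samples = c(b, b), fs = 125)
  beats <- detect_beats(rec)
  expect_length(beats, 2)
  onsets <- vapply(beats, function(x) attr(x, "onset_index"), integer(1))
  expect_lte(abs(onsets[1] - 1), 1)
  expect_lte(abs(onsets[2] - 126), 1)
})

test_that("flatline artifact beats are rejected by the correlation comparator", {
  spec <- flow_type_library()$I
  good <- generate_beat(spec, 0.8, 125, 0)
  beats <- c(replicate(19, good, simplify = FALSE),
             list(rep(good[1], length(good))))
  res <- reject_outliers(beats)
  expect_length(res$accepted, 19)
  expect_length(res$rejected, 1)
  expect_true(all(res$rejected[[1]] == good[1]))
})

test_that("identical ensembles reach a fixed point with zero rejections", {
  good <- generate_beat(flow_type_library()$II, 0.8, 125, 0)
  res <- reject_outliers(replicate(20, good, simplify = FALSE))
  expect_length(res$accepted, 20)
  expect_length(res$rejected, 0)
})

test_that("double-length beats are rejected by the length comparator", {
  spec <- flow_type_library()$I
  good <- generate_beat(spec, 0.7, 125, 0)
  long <- generate_beat(spec, 1.4, 125, 0)
  beats <- c(replicate(15, good, simplify = FALSE), list(long))
  res <- reject_outliers(beats)
  expect_length(res$accepted, 15)
  expect_equal(length(res$rejected[[1]]), length(long))
})

test_that("ensembles below three beats are wholly rejected and flagged", {
  good <- generate_beat(flow_type_library()$I, 0.8, 125, 0)
  res <- reject_outliers(list(good, good))
  expect_length(res$accepted, 0)
  expect_length(res$rejected, 2)
  expect_true(attr(res, "flagged"))
})

test_that("averaging identical beats reproduces the beat", {
  good <- generate_beat(flow_type_library()$III, 0.8, 125, 0)
  avg <- average_beats(replicate(7, good, simplify = FALSE))
  expect_equal(avg$samples, good)
  expect_equal(avg$n_beats_used, 7L)
  expect_error(average_beats(list()), "empty")
})

test_that("short beats are end-padded with their final value before averaging", {
  short <- c(seq(0, 1, length.out = 50), seq(1, 0.2, length.out = 50))
  long <- c(seq(0, 1, length.out = 60), seq(1, 0.1, length.out = 60))
  avg <- average_beats(list(short, long))
  expect_length(avg$samples, 120)
  # beyond sample 100 the short beat contributes its final value 0.2
  expect_equal(avg$samples[101:120], (0.2 + long[101:120]) / 2)
  expect_equal(avg$samples[1:100], (short + long[1:100]) / 2)
})

test_that("averaging commutes with velocity scaling", {
  set.seed(1)
  beats <- replicate(6, cumsum(abs(rnorm(90))), simplify = FALSE)
  a1 <- average_beats(lapply(beats, function(b) 3.7 * b))$samples
  a2 <- 3.7 * average_beats(beats)$samples
  expect_equal(a1, a2)
})

test_that("standardized beats have exactly 100 samples spanning [0, 1]", {
  for (fs in c(125, 400)) {
    x <- generate_beat(flow_type_library()$II, 0.9, fs, 0)
    w <- standardize_beat(x, fs)
    expect_length(w, 100)
    expect_identical(min(w), 0)
    expect_identical(max(w), 1)
  }
  expect_error(standardize_beat(rep(1, 100), 125), "constant")
})

test_that("smoothing leaves a broad raised cosine essentially unchanged", {
  n <- 125
  x <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = n))
  w <- standardize_beat(x, 125)
  ref <- norm01(stats::spline(seq_len(n) - 1, norm01(x),
                              xout = seq(0, n - 1, length.out = 100))$y)
  expect_lt(max(abs(w - ref)), 0.02)
})

test_that("standardization is idempotent up to smoothing", {
  w <- standardize_beat(generate_beat(flow_type_library()$I, 0.8, 125, 0), 125)
  w2 <- standardize_beat(w, 125)
  expect_identical(min(w2), 0)
  expect_identical(max(w2), 1)
  expect_lt(max(abs(w2 - w)), 0.08)  # only the repeated 90 ms smoothing acts
})

test_that("normalized beats of one flow type are heart-rate invariant", {
  lib <- flow_type_library()
  for (t in names(lib)) {
    ws <- lapply(c(50, 75, 100), function(hr) {
      standardize_beat(generate_beat(lib[[t]], 60 / hr, 125, 0), 125)
    })
    for (i in 1:2) for (j in (i + 1):3) {
      expect_lt(max(abs(ws[[i]] - ws[[j]])), 0.05)
    }
  }
})

test_that("recordings with too few accepted beats are excluded", {
  cfg <- sim_config(heart_rate_mean = 60, heart_rate_sd = 0, noise_sd = 0,
                    artifact_beat_rate = 0, rng_seed = 2)
  rec <- generate_recording(cfg, flow_type_library()$I)
  rec$samples <- rec$samples[1:(14 * 125)]  # room for ~14 beats
  out <- process_recording(rec)
  expect_s3_class(out, "tcd_excluded")
  expect_match(out$log, "accepted beats")
  # and out-of-range depth is excluded before any signal processing
  rec2 <- generate_recording(cfg, flow_type_library()$I, depth = 62)
  expect_s3_class(process_recording(rec2), "tcd_excluded")
})

test_that("the bilateral-pair exam filter retains only qualifying subjects", {
  W <- matrix(rep(norm01(seq_len(100) * 1.0), 5), nrow = 5, byrow = TRUE)
  info <- data.frame(
    waveform_id = paste0("w", 1:5),
    subject_id = c("A", "A", "B", "B", "C"),
    group = "IHC",
    hemisphere = c("left", "right", "left", "left", "right"),
    depth_mm = c(50, 52, 50, 55, 50),
    n_beats = c(20, 18, 22, 19, 25)
  )
  beats <- tcd_beats(W, info)
  kept <- filter_exams(beats)
  expect_equal(kept$info$subject_id, c("A", "A"))
  expect_match(kept$log, "bilateral", all = FALSE)
  # a qualifying bilateral pair is retained in full
  expect_equal(nrow(kept$waveforms), 2)
  # empty input passes through
  empty <- filter_exams(preprocess_recordings(list()))
  expect_equal(nrow(empty$waveforms), 0)
})
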