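test_that("streaming estimator emits the protocol frame cadence", {
  rec <- eeg_record(signal_segment(
    generate_background(60, 2048, 1, 10, seed = 4)$samples, 2048))
  frames <- stream_theta_power(rec)
  expect_identical(nrow(frames), 473L)        # (60*2048 - 2048)/256 + 1
  hops <- diff(frames$t_s)
  expect_equal(hops, rep(256 / 2048, length(hops)), tolerance = 1e-12)
  expect_equal(1 / hops[1], 8)                # 8 estimates/s
})

test_that("frame-rate law holds across configurations", {
  for (cfg in list(feedback_config(fs = 512, window_samples = 512,
                                   overlap_samples = 448),
                   feedback_config(fs = 1024, window_samples = 1024,
                                   overlap_samples = 512))) {
    rec <- eeg_record(signal_segment(rnorm(cfg$fs * 10), cfg$fs))
    frames <- stream_theta_power(rec, cfg)
    hop <- cfg$window_samples - cfg$overlap_samples
    expect_equal(unique(round(diff(frames$t_s) * cfg$fs)), hop)
    expect_identical(nrow(frames),
                     as.integer((cfg$fs * 10 - cfg$window_samples) / hop + 1))
  }
})

test_that("streamed theta power matches an independent DFT oracle and dB floors at zero", {
  fs <- 2048
  x <- 10 * sin(2 * pi * 6 * (0:(8 * fs - 1)) / fs)
  rec <- eeg_record(signal_segment(x, fs))
  thr <- threshold_state(12)
  frames <- stream_theta_power(rec, threshold = thr)
  # compare a few frames against the direct-DFT single-window oracle
  for (i in c(1, 20, 57)) {
    s <- round(frames$t_s[i] * fs) - 2048 + 1
    expect_equal(frames$theta_power[i],
                 oracle_band_mean(x[s:(s + 2047)], fs), tolerance = 1e-6)
  }
  zero <- stream_theta_power(eeg_record(signal_segment(rep(0, 3 * fs), fs)),
                             threshold = thr)
  expect_true(all(zero$theta_power == 0))
  expect_true(all(zero$db == -60))

  expect_warning(short <- stream_theta_power(
    eeg_record(signal_segment(rep(0, 100), fs))), "shorter")
  expect_identical(nrow(short), 0L)
})

test_that("artifact gating holds the last clean value and conserves frames", {
  fs <- 512
  cfg <- feedback_config(fs = fs, window_samples = fs,
                         overlap_samples = round(0.875 * fs))
  bg <- generate_background(30, fs, 1, 5, seed = 6)
  clean <- eeg_record(add_narrowband_noise(bg, c(4, 7), 20, seed = 1))
  frames <- stream_theta_power(clean, cfg, threshold = threshold_state(20))
  expect_identical(artifact_gate(frames, clean, cfg), frames)

  inj <- inject_artifacts(clean$segment, 10, peak_uV = 150, dur_s = 0.05)
  dirty <- eeg_record(inj$segment)
  fr2 <- stream_theta_power(dirty, cfg, threshold = threshold_state(20))
  gated <- artifact_gate(fr2, dirty, cfg, threshold = threshold_state(20))
  expect_identical(nrow(gated), nrow(fr2))
  # frames whose 1-s window intersects [10, 10.05] are exactly the gated ones
  win_start <- gated$t_s - 1
  intersects <- win_start < 10.05 & gated$t_s > 10
  expect_identical(gated$gated, intersects)
  last_clean <- max(which(!intersects & gated$t_s <= 10))
  held <- which(gated$gated)
  expect_true(all(gated$theta_power[held] == gated$theta_power[last_clean]))
  expect_true(all(gated$db[held] == gated$db[last_clean]))
  # non-gated frames untouched, live values resume after the artifact
  expect_identical(gated$theta_power[!gated$gated],
                   fr2$theta_power[!gated$gated])

  # artifact spanning the first window: start-of-stream hold is 0 dB
  inj0 <- inject_artifacts(clean$segment, 0.2, peak_uV = 150, dur_s = 0.05)
  rec0 <- eeg_record(inj0$segment)
  fr0 <- stream_theta_power(rec0, cfg, threshold = threshold_state(20))
  g0 <- artifact_gate(fr0, rec0, cfg, threshold = threshold_state(20))
  expect_true(g0$gated[1])
  expect_identical(g0$db[1], 0)
})

test_that("dB conversion has the closed-form values and the -60 dB floor", {
  thr <- threshold_state(10)
  expect_equal(to_db(10, thr), 0)
  expect_equal(to_db(20, thr), 10 * log10(2), tolerance = 1e-12)
  expect_equal(round(to_db(20, thr), 4), 3.0103)
  expect_identical(to_db(0, thr), -60)
  expect_error(to_db(5, threshold_state(0)), "> 0")
  expect_error(threshold_state(-1), "> 0")
})

test_that("block achievement counts goal-consistent non-gated frames", {
  fr <- data.frame(t_s = 1:4, theta_power = 1, db = c(1, 1, 1, 1),
                   gated = FALSE, achieved = NA)
  expect_equal(block_achievement(fr, "Up"), 100)
  expect_equal(block_achievement(fr, "Down"), 0)
  fr$db <- c(1, 1, -1, -1)
  expect_equal(block_achievement(fr, "Up"), 50)
  expect_equal(block_achievement(fr, "Up") + block_achievement(fr, "Down"),
               100)
  # exact 0 dB counts for neither goal
  fr$db <- c(0, 0, 1, -1)
  expect_equal(block_achievement(fr, "Up"), 25)
  expect_equal(block_achievement(fr, "Down"), 25)
  # gated frames are excluded; all-gated is missing
  fr$gated <- c(TRUE, TRUE, TRUE, FALSE)
  expect_equal(block_achievement(fr, "Down"), 100)
  fr$gated <- TRUE
  expect_warning(res <- block_achievement(fr, "Up"), "gated")
  expect_true(is.na(res))
})

test_that("threshold updates follow the session rule", {
  t1 <- update_threshold(1, resting_theta = 12)
  expect_equal(t1$value, 12)
  expect_identical(t1$source, "resting_baseline")
  t2 <- update_threshold(2, previous_session_block_means = rep(10, 6))
  expect_equal(t2$value, 10)
  expect_identical(t2$source, "previous_session_mean")
  t3 <- update_threshold(3,
                         previous_session_block_means = c(8, 10, 12, 9, 11, 10))
  expect_equal(t3$value, 10)
  expect_error(update_threshold(1), "resting_theta")
  expect_error(update_threshold(2), "previous_session")
})

test_that("streaming estimator equals offline Welch with identical window/overlap", {
  fs <- 2048
  rec <- eeg_record(signal_segment(
    generate_background(20, fs, 1, 10, seed = 12)$samples, fs))
  frames <- stream_theta_power(rec)
  w <- welch_band_power(rec$segment$samples, fs, win_s = 1,
                        overlap = 1792 / 2048, band = c(4, 7))
  expect_identical(w$n_windows, nrow(frames))
  expect_lt(abs(mean(frames$theta_power) - w$power) / w$power, 1e-6)
})

test_that("feedback config and frames round-trip through JSON/CSV", {
  cfg <- feedback_config(fs = 512, window_samples = 512,
                         overlap_samples = 448)
  path <- withr::local_tempfile(fileext = ".json")
  write_feedback_config(cfg, path)
  expect_equal(unclass(read_feedback_config(path)), unclass(cfg))
  expect_error(feedback_config(overlap_samples = 2048), "overlap")
  expect_error(feedback_config(band_lo = 7, band_hi = 4), "band")

  rec <- eeg_record(signal_segment(rnorm(2048 * 3), 2048))
  frames <- stream_theta_power(rec)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_frames_csv(frames, csv)
  back <- utils::read.csv(csv)
  expect_equal(back$theta_power, frames$theta_power)
})
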