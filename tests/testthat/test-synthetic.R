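test_that("1/f background has the requested spectral slope and is deterministic", {
  seg <- generate_background(60, 2048, spectral_exponent = 1, scale = 10,
                             seed = 7)
  expect_equal(mean(seg$samples), 0, tolerance = 1e-8)
  expect_equal(sd(seg$samples), 10, tolerance = 1e-6)
  pg <- periodogram_psd(seg$samples, 2048,
                        window = rep(1, length(seg$samples)))
  sel <- pg$freq >= 1 & pg$freq <= 100
  slope <- unname(coef(lm(log(pg$psd[sel]) ~ log(pg$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.15)

  again <- generate_background(60, 2048, spectral_exponent = 1, scale = 10,
                               seed = 7)
  expect_identical(seg$samples, again$samples)
  other <- generate_background(60, 2048, spectral_exponent = 1, scale = 10,
                               seed = 8)
  expect_false(identical(seg$samples, other$samples))

  expect_true(all(generate_background(2, 256, 1, scale = 0, seed = 1)$samples == 0))
  expect_error(generate_background(0, 256), "duration")
  expect_error(generate_background(2, -1), "fs")
})

test_that("sinusoidal oscillation obeys the quadratic power law", {
  fs <- 2048
  z <- signal_segment(rep(0, fs), fs)
  # amplitude 0 is the identity
  expect_identical(add_band_oscillation(z, 6, 0)$samples, z$samples)
  a <- 5
  s1 <- add_band_oscillation(z, 6, a)
  p1 <- welch_band_power(s1$samples, fs, 1, 0.5, c(4, 7),
                         stat = "integral")$power
  expect_lt(abs(p1 - a^2 / 2) / (a^2 / 2), 0.05)
  s2 <- add_band_oscillation(z, 6, 2 * a)
  p2 <- welch_band_power(s2$samples, fs, 1, 0.5, c(4, 7),
                         stat = "integral")$power
  expect_lt(abs(p2 / p1 - 4), 0.05)
  # input segment unchanged
  expect_true(all(z$samples == 0))
  expect_error(add_band_oscillation(z, fs / 2, 1), "f_hz")
})

test_that("narrowband noise power scales with the squared envelope", {
  fs <- 256
  z <- signal_segment(rep(0, 240 * fs), fs)
  s1 <- add_narrowband_noise(z, c(4, 7), 20, seed = 3)
  s2 <- add_narrowband_noise(z, c(4, 7), 20, envelope = 2, seed = 3)
  p1 <- welch_band_power(s1$samples, fs, 1, 0.5, c(4, 7))$power
  p2 <- welch_band_power(s2$samples, fs, 1, 0.5, c(4, 7))$power
  expect_equal(p2 / p1, 4, tolerance = 1e-10)
})

test_that("injected artifacts are flagged by a +/-75 uV scan exactly inside their intervals", {
  fs <- 256
  bg <- generate_background(20, fs, 1, scale = 5, seed = 2)

  none <- inject_artifacts(bg, numeric(0))
  expect_identical(none$segment$samples, bg$samples)
  expect_identical(nrow(none$intervals), 0L)

  one <- inject_artifacts(bg, 8, peak_uV = 150, dur_s = 0.4)
  x <- one$segment$samples
  t <- (seq_along(x) - 1) / fs
  inside <- t >= 8 & t <= 8.4
  expect_gte(sum(abs(x[inside]) > 75), 1)
  expect_identical(sum(abs(x[!inside]) > 75), 0L)
  expect_gte(max(abs(x[inside])), 150)

  two <- inject_artifacts(bg, c(12, 3), peak_uV = 150, dur_s = 0.4)
  expect_equal(two$intervals$start_s, c(3, 12))
  expect_true(all(two$intervals$end_s[-nrow(two$intervals)] <=
                    two$intervals$start_s[-1]))

  expect_warning(mrg <- inject_artifacts(bg, c(5, 5.2), 150, 0.4),
                 "merged")
  expect_identical(nrow(mrg$intervals), 1L)
  expect_error(inject_artifacts(bg, 1, peak_uV = 50), "75")
})

test_that("simulated training sessions hit the commanded modulation power", {
  fs <- 256
  null_p <- subject_params("N", "ALT", up_gain = 1, down_gain = 1,
                           artifact_rate = 0)
  sess <- build_session_timeline(1, assign_block_goals("ALT", seed = 3))
  tl <- sess$timeline
  rec0 <- simulate_nf_session(null_p, sess, seed = 21, fs = fs)
  db0 <- 10 * log10(interval_band_power(rec0, tl[tl$phase == "mod", ]) /
                      interval_band_power(rec0, tl[tl$phase == "rest", ]))
  expect_lt(abs(db0), 0.5)

  up_p <- subject_params("U", "INC", up_gain = 2, artifact_rate = 0)
  sessU <- build_session_timeline(1, rep("Up", 6))
  recU <- simulate_nf_session(up_p, sessU, seed = 22, fs = fs)
  tlU <- sessU$timeline
  dbU <- 10 * log10(interval_band_power(recU, tlU[tlU$phase == "mod", ]) /
                      interval_band_power(recU, tlU[tlU$phase == "rest", ]))
  expect_lt(abs(dbU - 10 * log10(2)), 0.5)

  # determinism of the full session record
  expect_identical(recU$segment$samples,
                   simulate_nf_session(up_p, sessU, seed = 22,
                                       fs = fs)$segment$samples)
})

test_that("ALT up-blocks always outrank down-blocks in measured theta power", {
  fs <- 256
  p <- subject_params("A", "ALT", up_gain = 2, down_gain = 0.5,
                      artifact_rate = 0)
  for (seed in 1:30) {
    sess <- build_session_timeline(1, assign_block_goals("ALT", seed = seed))
    rec <- simulate_nf_session(p, sess, seed = seed, fs = fs)
    tl <- sess$timeline
    blocks <- unique(tl$block)
    means <- vapply(blocks, function(b) {
      interval_band_power(rec, tl[tl$block == b & tl$phase == "mod", ])
    }, numeric(1))
    goals <- tl$goal[match(blocks, tl$block)]
    expect_gt(min(means[goals == "Up"]), max(means[goals == "Down"]))
  }
})

test_that("modulation-to-rest power ratio calibrates to the commanded gain", {
  fs <- 256
  for (gain in c(0.5, 2)) {
    p <- subject_params("C", "INC", up_gain = gain, artifact_rate = 0)
    sess <- build_session_timeline(1, rep("Up", 6))
    tl <- sess$timeline
    ratios <- vapply(1:5, function(seed) {
      rec <- simulate_nf_session(p, sess, seed = seed, fs = fs)
      interval_band_power(rec, tl[tl$phase == "mod", ]) /
        interval_band_power(rec, tl[tl$phase == "rest", ])
    }, numeric(1))
    expect_lt(abs(mean(ratios) - gain) / gain, 0.05)
  }
})

test_that("virtual shooter follows its psychometric and commission parameters", {
  p <- subject_params("S", "INC", tet50_ms = 750, tet90_ms = 1100,
                      commission_prob = 0)
  # commission_prob = 0: no commissions ever
  fr <- simulate_shooter(p, make_schedule(200, "friendly", 900), seed = 1)
  expect_identical(sum(fr$outcome == "commission"), 0L)
  expect_true(all(fr$outcome == "correct_withhold"))

  # commission_prob = 1: every friendly trial is a commission
  p1 <- subject_params("S", "INC", commission_prob = 1)
  fr1 <- simulate_shooter(p1, make_schedule(200, "friendly", 500), seed = 2)
  expect_true(all(fr1$outcome == "commission"))
  expect_true(all(fr1$shot_time_ms <= 500))

  # hit rate at TET = tet50 is 50% within 3 binomial SE (n = 1000)
  tr <- simulate_shooter(p, make_schedule(1000, "enemy", 750), seed = 3)
  se <- sqrt(0.5 * 0.5 / 1000)
  expect_lt(abs(mean(tr$hit) - 0.5), 3 * se)
  # outcomes are consistent with shots
  expect_true(all(is.na(tr$rt_ms[tr$outcome == "omission"])))
  expect_true(all(!is.na(tr$rt_ms[tr$outcome %in% c("hit", "miss")])))
})

test_that("cohort parameter draws respect group structure and constraints", {
  params <- draw_cohort_params(n_inc = 4, n_alt = 6, seed = 9)
  expect_length(params, 10)
  groups <- vapply(params, function(p) p$group, character(1))
  expect_identical(groups, c(rep("INC", 4), rep("ALT", 6)))
  for (p in params) {
    expect_lt(p$tet50_ms, p$tet90_ms)
    expect_gte(p$commission_prob, 0)
    expect_lte(p$commission_prob, 1)
    expect_gt(p$baseline_theta_power, 0)
  }
  again <- draw_cohort_params(n_inc = 4, n_alt = 6, seed = 9)
  expect_identical(vapply(params, function(p) p$tet50_ms, numeric(1)),
                   vapply(again, function(p) p$tet50_ms, numeric(1)))
})

test_that("subject parameters survive a JSON round trip", {
  p <- subject_params("S07", "ALT", session_trend = 0.3)
  path <- withr::local_tempfile(fileext = ".json")
  write_subject_params(p, path)
  q <- read_subject_params(path)
  expect_equal(unclass(q), unclass(p))
  expect_error(subject_params("X", "ALT", tet50_ms = 1200, tet90_ms = 900),
               "tet50")
  expect_error(subject_params("X", "ALT", commission_prob = 1.2),
               "commission_prob")
})
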