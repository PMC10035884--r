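#' Simulate the EEG of one neurofeedback training session
#'
#' Assembles a single-channel FCz-like record for the full session timeline:
#' 1/f background, a goal-responsive theta (4-7 Hz) component, a constant
#' alpha (8-13 Hz) component, and artifact transients at the subject's
#' artifact rate. During the 30-s modulation interval of block `b` in session
#' `s`, theta band power is
#' `baseline * gain(goal) * 10^((session_trend*(s-1) + block_trend*(b-1))/10)`;
#' rest intervals stay at baseline. Gains act on power, so the amplitude
#' envelope is the square root of the power ratio.
#'
#' Theta is synthesized as narrowband filtered noise by default; set
#' `pure_tone = TRUE` for a 6 Hz sinusoid (used by closed-form spectral
#' checks).
#'
#' @param params a [subject_params()].
#' @param session an `nf_session` from [build_session_timeline()].
#' @param seed integer seed; the record is a pure function of
#'   (params, session, seed).
#' @param fs sampling rate in Hz (default 2048, the acquisition rate).
#' @param background_scale RMS of the 1/f background (uV).
#' @param spectral_exponent background spectral exponent.
#' @param pure_tone synthesize theta as a 6 Hz sinusoid instead of narrowband
#'   noise.
#' @param artifact_peak_uV,artifact_dur_s artifact pulse parameters.
#' @return an [eeg_record()] with events `"rest"`, `"mod_up"`/`"mod_down"`
#'   (one per trial interval) and `"artifact"` (one per injected pulse).
#' @export
simulate_nf_session <- function(params, session, seed = 1, fs = 2048,
                                background_scale = 5, spectral_exponent = 1,
                                pure_tone = FALSE, artifact_peak_uV = 150,
                                artifact_dur_s = 0.4) {
  stopifnot(inherits(params, "subject_params"), inherits(session, "nf_session"))
  tl <- session$timeline
  dur_s <- max(tl$end_s)
  n <- as.integer(round(dur_s * fs))
  s_idx <- session$session_index

  seg <- generate_background(dur_s, fs, spectral_exponent, background_scale,
                             seed = derive_seed(seed, 1))

  # per-sample amplitude envelope of the theta component (sqrt of power ratio)
  env <- rep(1, n)
  for (r in which(tl$phase == "mod")) {
    gain <- if (tl$goal[r] == "Up") params$up_gain else params$down_gain
    trend_db <- params$session_trend * (s_idx - 1) +
      params$block_trend * (tl$block[r] - 1)
    rel_power <- gain * 10^(trend_db / 10)
    i0 <- as.integer(floor(tl$start_s[r] * fs)) + 1L
    i1 <- min(as.integer(floor(tl$end_s[r] * fs)), n)
    env[i0:i1] <- sqrt(rel_power)
  }

  if (pure_tone) {
    # amplitude such that the 1-s-window band-mean PSD over the four 4-7 Hz
    # bins equals baseline_theta_power: band mean = (a^2/2) / 4 per Hz
    a <- sqrt(8 * params$baseline_theta_power)
    seg <- add_band_oscillation(seg, 6, a, envelope = env)
  } else {
    seg <- add_narrowband_noise(seg, c(4, 7), params$baseline_theta_power,
                                envelope = env, seed = derive_seed(seed, 2))
  }
  if (params$alpha_power > 0) {
    seg <- add_narrowband_noise(seg, c(8, 13), params$alpha_power,
                                envelope = 1, seed = derive_seed(seed, 3))
  }

  # artifact transients: count from the per-minute rate, onsets uniform,
  # overlapping draws thinned so injected intervals are disjoint
  intervals <- data.frame(start_s = numeric(), end_s = numeric())
  n_art <- as.integer(round(params$artifact_rate * dur_s / 60))
  if (n_art > 0) {
    onsets <- with_seed(derive_seed(seed, 4), {
      sort(stats::runif(n_art, 0, dur_s - artifact_dur_s))
    })
    if (length(onsets) > 1) {
      keep <- c(TRUE, diff(onsets) > artifact_dur_s)
      onsets <- onsets[keep]
    }
    inj <- inject_artifacts(seg, onsets, artifact_peak_uV, artifact_dur_s)
    seg <- inj$segment
    intervals <- inj$intervals
  }

  ev_tl <- data.frame(
    onset = as.integer(floor(tl$start_s * fs)),
    duration = as.integer(round((tl$end_s - tl$start_s) * fs)),
    code = ifelse(tl$phase == "rest", "rest",
                  ifelse(tl$goal == "Up", "mod_up", "mod_down")),
    stringsAsFactors = FALSE)
  ev_art <- if (nrow(intervals)) {
    data.frame(onset = as.integer(floor(intervals$start_s * fs)),
               duration = as.integer(round((intervals$end_s -
                                              intervals$start_s) * fs)),
               code = "artifact", stringsAsFactors = FALSE)
  } else NULL
  events <- rbind(ev_tl, ev_art)
  events <- events[order(events$onset), ]
  rownames(events) <- NULL
  eeg_record(seg, events)
}
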