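#' Online feedback configuration
#'
#' Parameters of the closed-loop theta-power estimator. Defaults reproduce the
#' study protocol: 2048 Hz acquisition, 1-s analysis windows (2048 samples)
#' with 875 ms overlap (1792 samples) giving 8 estimates/s, 4-7 Hz band, and a
#' +/-75 uV online artifact threshold.
#'
#' @param fs sampling rate (Hz).
#' @param window_samples analysis window length in samples.
#' @param overlap_samples overlap between consecutive windows in samples;
#'   must satisfy `0 <= overlap_samples < window_samples`.
#' @param band_lo,band_hi band edges in Hz (inclusive); `band_hi` must be
#'   below Nyquist.
#' @param artifact_limit_uV online amplitude threshold (uV).
#' @return an object of class `feedback_config`.
#' @export
feedback_config <- function(fs = 2048, window_samples = 2048,
                            overlap_samples = 1792, band_lo = 4, band_hi = 7,
                            artifact_limit_uV = 75) {
  if (overlap_samples < 0 || overlap_samples >= window_samples) {
    stopf("need 0 <= overlap_samples < window_samples")
  }
  if (!(band_lo < band_hi && band_hi < fs / 2)) {
    stopf("need band_lo < band_hi < fs/2")
  }
  structure(list(fs = fs, window_samples = as.integer(window_samples),
                 overlap_samples = as.integer(overlap_samples),
                 band_lo = band_lo, band_hi = band_hi,
                 artifact_limit_uV = artifact_limit_uV),
            class = "feedback_config")
}

#' @export
print.feedback_config <- function(x, ...) {
  hop <- x$window_samples - x$overlap_samples
  cat(sprintf(
    "<feedback_config> fs %g Hz, window %d, overlap %d (%.3g frames/s), band %g-%g Hz, |limit| %g uV\n",
    x$fs, x$window_samples, x$overlap_samples, x$fs / hop, x$band_lo,
    x$band_hi, x$artifact_limit_uV))
  invisible(x)
}

#' Read / write a feedback configuration as JSON
#' @param cfg a [feedback_config()].
#' @param path JSON path.
#' @return `path` (write) or a `feedback_config` (read).
#' @export
write_feedback_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_feedback_config
#' @export
read_feedback_config <- function(path) {
  do.call(feedback_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Streaming theta-power estimation
#'
#' Slides the analysis window across the record in hops of
#' `window_samples - overlap_samples` samples and computes, per window, the
#' mean Hann-tapered PSD over the bins with `band_lo <= f <= band_hi` — the
#' online feedback signal. With the defaults this emits exactly 8 frames/s in
#' steady state and the per-frame values average to the offline Welch
#' band power computed with the same window/overlap.
#'
#' @param record an [eeg_record()] whose sampling rate matches `cfg$fs`.
#' @param cfg a [feedback_config()].
#' @param threshold optional [threshold_state()]; when given, each frame also
#'   carries `db`, the power in dB relative to the threshold (see [to_db()]).
#' @return data.frame of class `feedback_frames` with one row per frame:
#'   `t_s` (window end time, s), `theta_power` (uV^2 band-mean PSD), `db`,
#'   `gated` (all `FALSE`; see [artifact_gate()]), `achieved` (`NA` until a
#'   goal is applied).
#' @export
stream_theta_power <- function(record, cfg = feedback_config(),
                               threshold = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  if (abs(record$segment$fs - cfg$fs) > 1e-9) {
    stopf("record sampling rate (%g) does not match cfg$fs (%g)",
          record$segment$fs, cfg$fs)
  }
  x <- record$segment$samples
  win <- cfg$window_samples
  hop <- win - cfg$overlap_samples
  n <- length(x)
  if (n < win) {
    warnf("record (%d samples) shorter than one analysis window (%d)", n, win)
    return(empty_frames())
  }
  starts <- seq(1L, n - win + 1L, by = hop)
  w <- hann_window(win)
  # precompute band bin selection once: bins are identical for every window
  freq <- (seq_len(win %/% 2 + 1) - 1) * cfg$fs / win
  sel <- freq >= cfg$band_lo & freq <= cfg$band_hi
  power <- vapply(starts, function(s) {
    pg <- periodogram_psd(x[s:(s + win - 1L)], cfg$fs, w)
    mean(pg$psd[sel])
  }, numeric(1))
  db <- if (is.null(threshold)) rep(NA_real_, length(power)) else {
    vapply(power, to_db, numeric(1), threshold = threshold)
  }
  frames <- data.frame(t_s = (starts - 1 + win) / cfg$fs,
                       theta_power = power, db = db,
                       gated = FALSE, achieved = NA)
  class(frames) <- c("feedback_frames", "data.frame")
  frames
}

empty_frames <- function() {
  f <- data.frame(t_s = numeric(), theta_power = numeric(), db = numeric(),
                  gated = logical(), achieved = logical())
  class(f) <- c("feedback_frames", "data.frame")
  f
}

#' Online artifact gating (flat-line hold)
#'
#' A frame is gated iff any sample inside its analysis window exceeds the
#' +/- amplitude limit. Gated frames are displayed as a flat line: they carry
#' the last non-gated `theta_power`/`db` (hold-last). If the stream starts
#' gated, held frames carry `db = 0` (the threshold level) and, when the
#' threshold value is known, `theta_power` equal to it. The first clean window
#' after an artifact resumes live values. Frame count is conserved and
#' non-gated frames are never altered.
#'
#' @param frames output of [stream_theta_power()] for `record` under `cfg`.
#' @param record the [eeg_record()] the frames were derived from.
#' @param cfg the [feedback_config()] used.
#' @param threshold optional [threshold_state()] supplying the hold power when
#'   the stream starts gated.
#' @return the frames with `gated`, `theta_power`, `db` updated.
#' @export
artifact_gate <- function(frames, record, cfg = feedback_config(),
                          threshold = NULL) {
  if (!nrow(frames)) return(frames)
  x <- record$segment$samples
  win <- cfg$window_samples
  hop <- win - cfg$overlap_samples
  starts <- as.integer(round(frames$t_s * cfg$fs)) - win + 1L
  bad <- abs(x) > cfg$artifact_limit_uV
  cbad <- c(0, cumsum(bad))
  hold_power <- if (is.null(threshold)) NA_real_ else threshold$value
  hold_db <- 0
  for (i in seq_len(nrow(frames))) {
    s <- starts[i]
    n_bad <- cbad[s + win] - cbad[s]
    if (n_bad > 0) {
      frames$gated[i] <- TRUE
      frames$theta_power[i] <- hold_power
      frames$db[i] <- hold_db
    } else {
      hold_power <- frames$theta_power[i]
      hold_db <- frames$db[i]
    }
  }
  frames
}

#' Threshold state for dB conversion
#'
#' The adaptive per-session reference against which online power is expressed
#' in dB: the pre-training resting theta power in session 1, the mean of the
#' previous session's block means afterwards.
#'
#' @param value threshold power (uV^2 band-mean, > 0).
#' @param session_index 1-based session count.
#' @param source `"resting_baseline"` or `"previous_session_mean"`.
#' @return an object of class `threshold_state`.
#' @export
threshold_state <- function(value, session_index = 1L,
                            source = c("resting_baseline",
                                       "previous_session_mean")) {
  source <- match.arg(source)
  if (!is.finite(value) || value <= 0) stopf("threshold value must be > 0")
  structure(list(value = value, session_index = as.integer(session_index),
                 source = source), class = "threshold_state")
}

#' @export
print.threshold_state <- function(x, ...) {
  cat(sprintf("<threshold_state> session %d: %.4g uV^2 (%s)\n",
              x$session_index, x$value, x$source))
  invisible(x)
}

#' Power in dB relative to the modulation threshold
#'
#' `10 * log10(power / threshold)`, floored at -60 dB so that zero or
#' near-zero power stays finite while preserving ordering.
#'
#' @param power band-mean power (uV^2, >= 0).
#' @param threshold a [threshold_state()] (or a positive number).
#' @param floor_db lower clamp, default -60.
#' @return dB value.
#' @export
to_db <- function(power, threshold, floor_db = -60) {
  thr <- if (inherits(threshold, "threshold_state")) threshold$value else threshold
  if (!is.finite(thr) || thr <= 0) stopf("threshold value must be > 0")
  if (!is.finite(power) || power < 0) stopf("power must be finite and >= 0")
  if (power <= 0) return(floor_db)
  max(10 * log10(power / thr), floor_db)
}

#' Block goal-achievement percentage
#'
#' Percentage of non-gated frames on the goal-consistent side of 0 dB:
#' `db > 0` for an Up goal, `db < 0` for Down. Frames at exactly 0 dB count
#' as not achieved for either goal. With no frame exactly at 0 dB,
#' achievement(Up) + achievement(Down) = 100.
#'
#' @param frames [stream_theta_power()] output with `db` populated.
#' @param goal `"Up"` or `"Down"`.
#' @return percentage in `[0, 100]`, or `NA` (with a warning) if every frame
#'   is gated.
#' @export
block_achievement <- function(frames, goal = c("Up", "Down")) {
  goal <- match.arg(goal)
  live <- frames[!frames$gated, , drop = FALSE]
  if (!nrow(live)) {
    warnf("all frames gated; achievement undefined")
    return(NA_real_)
  }
  if (any(!is.finite(live$db))) stopf("frames carry no dB values; supply a threshold")
  ok <- if (goal == "Up") live$db > 0 else live$db < 0
  100 * sum(ok) / nrow(live)
}

#' Update the modulation threshold between sessions
#'
#' Session 1 uses pre-training resting theta power; every later session uses
#' the arithmetic mean of the previous session's six block mean powers.
#'
#' @param session_index 1-based session number.
#' @param resting_theta resting theta power (uV^2); required for session 1.
#' @param previous_session_block_means numeric vector of the previous
#'   session's block mean powers; required for sessions > 1.
#' @return a [threshold_state()].
#' @export
update_threshold <- function(session_index, resting_theta = NULL,
                             previous_session_block_means = NULL) {
  if (session_index < 1) stopf("session_index must be >= 1")
  if (session_index == 1) {
    if (is.null(resting_theta)) {
      stopf("session 1 requires `resting_theta`")
    }
    threshold_state(resting_theta, 1L, "resting_baseline")
  } else {
    if (is.null(previous_session_block_means) ||
        !length(previous_session_block_means)) {
      stopf("session %d requires `previous_session_block_means`", session_index)
    }
    threshold_state(mean(previous_session_block_means), session_index,
                    "previous_session_mean")
  }
}

#' Write feedback frames to CSV
#' @param frames [stream_theta_power()] output.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_frames_csv <- function(frames, path) {
  utils::write.csv(as.data.frame(frames), path, row.names = FALSE)
  invisible(path)
}
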