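#' Generate 1/f background EEG
#'
#' Spectrally shaped Gaussian noise standing in for resting EEG: white noise
#' is shaped in the frequency domain so its power spectrum follows
#' 1/f^exponent, then standardized to zero mean and the requested RMS
#' amplitude.
#'
#' @param duration_s duration in seconds (> 0).
#' @param fs sampling rate in Hz (> 0).
#' @param spectral_exponent exponent of the 1/f^a spectrum, in `[0, 3]`.
#' @param scale output RMS amplitude in uV; `scale = 0` gives an all-zero
#'   segment.
#' @param seed integer seed; identical arguments and seed give bit-identical
#'   output.
#' @return a [signal_segment()].
#' @export
generate_background <- function(duration_s, fs, spectral_exponent = 1,
                                scale = 10, seed = NULL) {
  if (duration_s <= 0) stopf("duration_s must be > 0")
  if (fs <= 0) stopf("fs must be > 0")
  if (spectral_exponent < 0 || spectral_exponent > 3) {
    stopf("spectral_exponent must be in [0, 3]")
  }
  n <- as.integer(round(duration_s * fs))
  with_seed(seed, {
    w <- stats::rnorm(n)
    if (spectral_exponent > 0) {
      X <- stats::fft(w)
      k <- 0:(n - 1)
      f <- pmin(k, n - k) * fs / n
      g <- ifelse(f > 0, f^(-spectral_exponent / 2), 0)
      x <- Re(stats::fft(X * g, inverse = TRUE)) / n
    } else {
      x <- w
    }
    x <- x - mean(x)
    s <- stats::sd(x)
    x <- if (s > 0) x * (scale / s) else x * 0
    signal_segment(x, fs)
  })
}

#' Add a band-limited sinusoidal oscillation
#'
#' Adds `amplitude * envelope * sin(2*pi*f_hz*t + phase)` to a segment. The
#' envelope is either a constant or a per-sample gain sequence, which is how
#' goal-responsive power modulation is imposed on the theta component. The
#' input segment is not modified.
#'
#' @param segment a [signal_segment()].
#' @param f_hz oscillation frequency, `0 < f_hz < fs/2`.
#' @param amplitude peak amplitude in uV.
#' @param envelope scalar or numeric vector of the segment length.
#' @param phase initial phase in radians.
#' @return a new [signal_segment()].
#' @export
add_band_oscillation <- function(segment, f_hz, amplitude, envelope = 1,
                                 phase = 0) {
  stopifnot(inherits(segment, "signal_segment"))
  fs <- segment$fs
  if (f_hz <= 0 || f_hz >= fs / 2) {
    stopf("f_hz must satisfy 0 < f_hz < fs/2 = %g", fs / 2)
  }
  n <- length(segment$samples)
  if (!(length(envelope) %in% c(1L, n))) {
    stopf("envelope must be a scalar or have the segment length (%d)", n)
  }
  t <- (0:(n - 1)) / fs
  signal_segment(segment$samples +
                   amplitude * envelope * sin(2 * pi * f_hz * t + phase), fs)
}

#' Add band-limited Gaussian noise (narrowband oscillation)
#'
#' The default realistic theta/alpha component: white Gaussian noise masked to
#' a frequency band, scaled so its band-mean power spectral density equals
#' `band_mean_power`, then multiplied by the (amplitude) envelope. Local band
#' power scales with `envelope^2`.
#'
#' @param segment a [signal_segment()].
#' @param band numeric length-2, band edges in Hz.
#' @param band_mean_power target band-mean PSD (uV^2/Hz-bin mean) of the added
#'   component.
#' @param envelope scalar or per-sample amplitude gain.
#' @param seed integer seed for the noise stream.
#' @return a new [signal_segment()].
#' @export
add_narrowband_noise <- function(segment, band, band_mean_power, envelope = 1,
                                 seed = NULL) {
  stopifnot(inherits(segment, "signal_segment"), length(band) == 2)
  fs <- segment$fs
  if (band[2] >= fs / 2 || band[1] <= 0 || band[1] >= band[2]) {
    stopf("band must satisfy 0 < lo < hi < fs/2")
  }
  n <- length(segment$samples)
  if (!(length(envelope) %in% c(1L, n))) {
    stopf("envelope must be a scalar or have the segment length (%d)", n)
  }
  x <- with_seed(seed, {
    w <- stats::rnorm(n)
    X <- stats::fft(w)
    k <- 0:(n - 1)
    f <- pmin(k, n - k) * fs / n
    mask <- as.numeric(f >= band[1] & f <= band[2])
    Re(stats::fft(X * mask, inverse = TRUE)) / n
  })
  # unit-variance white noise has one-sided PSD 2/fs; masking preserves the
  # in-band density, so scaling by sqrt(P * fs / 2) sets it to P
  x <- x * sqrt(band_mean_power * fs / 2)
  signal_segment(segment$samples + envelope * x, fs)
}

#' Inject artifact transients
#'
#' Adds raised-cosine pulses (band-limited, deterministic peak) at the given
#' onsets. Pulse amplitude is adjusted for the underlying sample so that the
#' absolute peak inside each injected interval is at least `peak_uV`, i.e. a
#' +/-75 uV threshold scan is guaranteed to flag every injected interval.
#' Overlapping requested intervals are merged with a warning.
#'
#' @param segment a [signal_segment()].
#' @param onsets_s numeric vector of pulse onset times (s).
#' @param peak_uV pulse peak amplitude (uV, must exceed 75).
#' @param dur_s pulse duration (s).
#' @return list with `segment` (new [signal_segment()]) and `intervals`
#'   (data.frame `start_s`, `end_s`, ascending, disjoint).
#' @export
inject_artifacts <- function(segment, onsets_s, peak_uV = 150, dur_s = 0.4) {
  stopifnot(inherits(segment, "signal_segment"))
  if (peak_uV <= 75) stopf("peak_uV must exceed the 75 uV online threshold")
  if (!length(onsets_s)) {
    return(list(segment = segment, intervals = data.frame(start_s = numeric(),
                                                          end_s = numeric())))
  }
  fs <- segment$fs
  n <- length(segment$samples)
  onsets_s <- sort(onsets_s)
  if (any(onsets_s < 0) || any(onsets_s + dur_s > n / fs)) {
    stopf("artifact intervals must lie within the segment")
  }
  # merge overlaps
  starts <- onsets_s
  ends <- onsets_s + dur_s
  keep_start <- starts[1]
  merged <- list()
  cur_end <- ends[1]
  for (i in seq_along(starts)[-1]) {
    if (starts[i] < cur_end) {
      warnf("overlapping artifact intervals merged")
      cur_end <- max(cur_end, ends[i])
    } else {
      merged[[length(merged) + 1]] <- c(keep_start, cur_end)
      keep_start <- starts[i]
      cur_end <- ends[i]
    }
  }
  merged[[length(merged) + 1]] <- c(keep_start, cur_end)
  iv <- do.call(rbind, merged)
  x <- segment$samples
  for (r in seq_len(nrow(iv))) {
    i0 <- as.integer(floor(iv[r, 1] * fs)) + 1L
    i1 <- min(as.integer(ceiling(iv[r, 2] * fs)), n)
    m <- i1 - i0 + 1L
    pulse <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = m))
    apex <- i0 + which.max(pulse) - 1L
    amp <- peak_uV + abs(x[apex])
    x[i0:i1] <- x[i0:i1] + amp * pulse
  }
  list(segment = signal_segment(x, fs),
       intervals = data.frame(start_s = iv[, 1], end_s = iv[, 2]))
}
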