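# Zero-phase FIR filtering: FFT-based (overlap-add) convolution with a
# linear-phase FIR kernel, group delay compensated by shifting, which is an
# exact zero-phase filter for odd-length symmetric kernels.
fir_zerophase <- function(x, b) {
  d <- (length(b) - 1L) %/% 2L
  y <- signal::fftfilt(b, c(x, rep(0, d)))
  y[(d + 1L):(d + length(x))]
}

#' Offline preprocessing: zero-phase highpass and downsampling
#'
#' 1 Hz zero-phase FIR highpass followed by anti-aliased decimation from the
#' acquisition rate to the analysis rate (2048 -> 512 Hz by default). Event
#' onsets/durations are remapped to the new rate.
#'
#' @param record an [eeg_record()].
#' @param highpass_hz highpass cutoff (Hz); 0 disables the highpass.
#' @param target_fs output sampling rate; the input rate must be an integer
#'   multiple.
#' @param transition_hz highpass transition bandwidth (sets the FIR length,
#'   `~3.3 * fs / transition_hz` taps).
#' @return a preprocessed [eeg_record()] at `target_fs`.
#' @export
preprocess_record <- function(record, highpass_hz = 1, target_fs = 512,
                              transition_hz = 1) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$segment$fs
  factor <- fs / target_fs
  if (abs(factor - round(factor)) > 1e-9 || factor < 1) {
    stopf("fs (%g) must be an integer multiple of target_fs (%g)", fs,
          target_fs)
  }
  factor <- as.integer(round(factor))
  x <- record$segment$samples

  if (highpass_hz > 0) {
    ntaps <- as.integer(ceiling(3.3 * fs / transition_hz))
    if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
    b <- signal::fir1(ntaps - 1L, highpass_hz / (fs / 2), type = "high")
    x <- fir_zerophase(x, b)
  }
  if (factor > 1L) {
    # anti-alias lowpass at 80% of the new Nyquist, then pick every factor-th
    lp_taps <- 255L
    bl <- signal::fir1(lp_taps - 1L, 0.8 * (target_fs / 2) / (fs / 2),
                       type = "low")
    x <- fir_zerophase(x, bl)
    x <- x[seq(1L, length(x), by = factor)]
  }
  events <- record$events
  if (nrow(events)) {
    events$onset <- events$onset %/% factor
    events$duration <- as.integer(round(events$duration / factor))
  }
  eeg_record(signal_segment(x, target_fs), events, record$channel_label)
}

#' Epoch a record around events
#'
#' One epoch per event matching `event_code`, spanning the half-open sample
#' window `[onset + t_min*fs, onset + t_max*fs)` (onsets are 0-based sample
#' indices). Events whose window does not fit inside the record are dropped
#' and counted.
#'
#' @param record an [eeg_record()].
#' @param event_code event code to epoch around (exact match).
#' @param t_min_s,t_max_s window relative to event onset, seconds.
#' @return list of class `epoch_list`; each element has `samples`, `fs`,
#'   `t0_s` (= `t_min_s`) and `label`. Attribute `dropped` counts events whose
#'   window fell outside the record.
#' @export
epoch_records <- function(record, event_code, t_min_s, t_max_s) {
  stopifnot(inherits(record, "eeg_record"), t_max_s > t_min_s)
  fs <- record$segment$fs
  x <- record$segment$samples
  ev <- record$events[record$events$code %in% event_code, , drop = FALSE]
  if (!nrow(ev)) {
    warnf("no events with code %s", paste(event_code, collapse = "/"))
    out <- list()
    class(out) <- "epoch_list"
    attr(out, "dropped") <- 0L
    return(out)
  }
  i0 <- ev$onset + as.integer(round(t_min_s * fs)) # 0-based start
  i1 <- ev$onset + as.integer(round(t_max_s * fs)) # 0-based, exclusive
  ok <- i0 >= 0 & i1 <= length(x)
  dropped <- sum(!ok)
  out <- lapply(which(ok), function(j) {
    list(samples = x[(i0[j] + 1L):i1[j]], fs = fs, t0_s = t_min_s,
         label = ev$code[j])
  })
  class(out) <- "epoch_list"
  attr(out, "dropped") <- as.integer(dropped)
  out
}

#' @export
print.epoch_list <- function(x, ...) {
  n <- length(x)
  cat(sprintf("<epoch_list> %d epochs%s%s\n", n,
              if (n) sprintf(" of %.3g s @ %g Hz",
                             length(x[[1]]$samples) / x[[1]]$fs, x[[1]]$fs)
              else "",
              if (attr(x, "dropped") > 0)
                sprintf(" (%d dropped at edges)", attr(x, "dropped")) else ""))
  invisible(x)
}

#' Split epochs into non-overlapping sub-epochs
#'
#' E.g. a 33-s modulation epoch into 33 1-s windows for artifact screening.
#'
#' @param epochs an `epoch_list` (or a single epoch).
#' @param win_s sub-epoch length in seconds.
#' @return an `epoch_list` of sub-epochs; each carries `parent` (index of the
#'   source epoch) in addition to the epoch fields.
#' @export
sub_epoch <- function(epochs, win_s = 1) {
  if (!inherits(epochs, "epoch_list")) epochs <- structure(list(epochs),
                                                           class = "epoch_list")
  out <- list()
  for (i in seq_along(epochs)) {
    e <- epochs[[i]]
    w <- as.integer(round(win_s * e$fs))
    k <- length(e$samples) %/% w
    for (j in seq_len(k)) {
      out[[length(out) + 1]] <- list(
        samples = e$samples[((j - 1L) * w + 1L):(j * w)], fs = e$fs,
        t0_s = e$t0_s + (j - 1) * win_s, label = e$label, parent = i)
    }
  }
  class(out) <- "epoch_list"
  attr(out, "dropped") <- 0L
  out
}

#' Rejection criteria for epoch screening
#'
#' Defaults follow the standard automatic rejection battery: amplitude
#' threshold +/-100 uV; joint probability > 5 SD; abnormal linear trend (max
#' slope 75 uV per 1-s epoch AND fit R-squared > 0.3, conjunctive); kurtosis
#' > 5 SD.
#'
#' @param amp_limit_uV absolute amplitude limit (uV).
#' @param jointprob_sd joint-probability threshold in SD units.
#' @param slope_limit_uV_per_epoch absolute least-squares slope limit, uV over
#'   the epoch.
#' @param slope_r2_limit minimum R-squared for the trend criterion.
#' @param kurtosis_sd kurtosis z-score threshold in SD units.
#' @return an object of class `rejection_criteria`.
#' @export
rejection_criteria <- function(amp_limit_uV = 100, jointprob_sd = 5,
                               slope_limit_uV_per_epoch = 75,
                               slope_r2_limit = 0.3, kurtosis_sd = 5) {
  vals <- c(amp_limit_uV, jointprob_sd, slope_limit_uV_per_epoch,
            slope_r2_limit, kurtosis_sd)
  if (any(vals <= 0)) stopf("all rejection criteria must be positive")
  structure(list(amp_limit_uV = amp_limit_uV, jointprob_sd = jointprob_sd,
                 slope_limit_uV_per_epoch = slope_limit_uV_per_epoch,
                 slope_r2_limit = slope_r2_limit, kurtosis_sd = kurtosis_sd),
            class = "rejection_criteria")
}

#' Four-criterion automatic epoch rejection
#'
#' Flags an epoch if (a) any sample exceeds the amplitude limit; (b) its mean
#' negative log-probability under a Gaussian fit to the pooled amplitude
#' distribution exceeds the across-epoch mean by more than `jointprob_sd` SD;
#' (c) the absolute least-squares linear trend exceeds
#' `slope_limit_uV_per_epoch` uV over the epoch AND the trend fit R-squared
#' exceeds `slope_r2_limit`; (d) the z-scored sample kurtosis exceeds
#' `kurtosis_sd`. Distribution-based criteria (b) and (d) need at least 8
#' epochs and nonzero across-epoch variance, otherwise they are skipped with
#' a warning.
#'
#' @param epochs an `epoch_list` (or list of numeric vectors).
#' @param criteria a [rejection_criteria()].
#' @return list with `keep` (logical mask, TRUE = retained), `counts` (named
#'   vector of per-criterion flag counts) and `flags` (epoch x criterion
#'   logical matrix).
#' @export
reject_epochs <- function(epochs, criteria = rejection_criteria()) {
  xs <- lapply(epochs, function(e) if (is.list(e)) e$samples else e)
  n <- length(xs)
  if (!n) stopf("no epochs supplied")
  flags <- matrix(FALSE, n, 4,
                  dimnames = list(NULL, c("amplitude", "jointprob", "trend",
                                          "kurtosis")))
  # (a) amplitude
  flags[, "amplitude"] <- vapply(xs, function(x) {
    any(abs(x) > criteria$amp_limit_uV)
  }, logical(1))

  # (c) abnormal trend: slope expressed as uV change over the epoch
  flags[, "trend"] <- vapply(xs, function(x) {
    m <- length(x)
    t01 <- seq(0, 1, length.out = m)
    fit <- stats::lm.fit(cbind(1, t01), x)
    slope <- fit$coefficients[2]
    ssr <- sum(fit$residuals^2)
    sst <- sum((x - mean(x))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else 0
    abs(slope) > criteria$slope_limit_uV_per_epoch &&
      r2 > criteria$slope_r2_limit
  }, logical(1))

  distribution_ok <- n >= 8
  if (distribution_ok) {
    pooled <- unlist(xs, use.names = FALSE)
    mu <- mean(pooled)
    sdev <- stats::sd(pooled)
    if (!is.finite(sdev) || sdev <= 0) {
      warnf("zero pooled variance: joint-probability and kurtosis criteria skipped")
    } else {
      # (b) joint probability
      nlp <- vapply(xs, function(x) {
        -mean(stats::dnorm(x, mu, sdev, log = TRUE))
      }, numeric(1))
      s_nlp <- stats::sd(nlp)
      if (is.finite(s_nlp) && s_nlp > 0) {
        flags[, "jointprob"] <- (nlp - mean(nlp)) / s_nlp > criteria$jointprob_sd
      }
      # (d) kurtosis
      ku <- vapply(xs, sample_kurtosis, numeric(1))
      s_ku <- stats::sd(ku)
      if (is.finite(s_ku) && s_ku > 0) {
        flags[, "kurtosis"] <- (ku - mean(ku)) / s_ku > criteria$kurtosis_sd
      }
    }
  } else {
    warnf("fewer than 8 epochs: distribution-based criteria skipped")
  }
  keep <- !apply(flags, 1, any)
  list(keep = keep, counts = colSums(flags), flags = flags)
}

#' Welch band power
#'
#' Welch power spectral density (Hann taper, PSD scaling) from overlapping
#' windows, summarized over a frequency band. `stat = "mean"` averages the
#' PSD bins inside the band (the feedback-signal convention);
#' `stat = "integral"` integrates them (uV^2; equals a^2/2 for a sinusoid of
#' amplitude a inside the band).
#'
#' @param samples numeric samples (uV).
#' @param fs sampling rate (Hz).
#' @param win_s window length in seconds.
#' @param overlap fractional window overlap in `[0, 1)`.
#' @param band numeric length-2 band edges (Hz, inclusive).
#' @param stat `"mean"` or `"integral"`.
#' @return list of class `band_power`: `power`, `band`, `stat`, `n_windows`.
#' @export
welch_band_power <- function(samples, fs, win_s = 1, overlap = 0.5,
                             band = c(4, 7), stat = c("mean", "integral")) {
  stat <- match.arg(stat)
  win <- as.integer(round(win_s * fs))
  if (length(samples) < win) {
    stopf("signal (%d samples) shorter than one window (%d)", length(samples),
          win)
  }
  hop <- max(1L, as.integer(round(win * (1 - overlap))))
  starts <- seq(1L, length(samples) - win + 1L, by = hop)
  w <- hann_window(win)
  acc <- NULL
  for (s in starts) {
    pg <- periodogram_psd(samples[s:(s + win - 1L)], fs, w)
    acc <- if (is.null(acc)) pg$psd else acc + pg$psd
  }
  psd <- acc / length(starts)
  freq <- (seq_len(win %/% 2 + 1) - 1) * fs / win
  structure(list(power = band_stat(freq, psd, band, stat), band = band,
                 stat = stat, n_windows = length(starts),
                 freq = freq, psd = psd),
            class = "band_power")
}

#' @export
print.band_power <- function(x, ...) {
  cat(sprintf("<band_power> %.4g uV^2 (%s over %g-%g Hz, %d windows)\n",
              x$power, x$stat, x$band[1], x$band[2], x$n_windows))
  invisible(x)
}

#' Band power in dB relative to a reference period
#'
#' `10*log10(task/reference)`. The reference is typically the pre-trial
#' baseline period mean power (modulation trials: -3 to 0 s; shooting trials:
#' -1 to 0 s). Antisymmetric under ratio inversion.
#'
#' @param task_power task-period band power (uV^2, >= 0).
#' @param reference_power baseline band power (uV^2, > 0).
#' @return dB value.
#' @export
band_power_db <- function(task_power, reference_power) {
  if (!is.finite(reference_power) || reference_power <= 0) {
    stopf("reference power must be > 0")
  }
  tp <- if (inherits(task_power, "band_power")) task_power$power else task_power
  rp <- if (inherits(reference_power, "band_power")) reference_power$power else reference_power
  10 * log10(tp / rp)
}

#' Retention accounting
#'
#' Percentage of analysis units retained after artifact rejection, rounded
#' half-up to two decimals.
#'
#' @param kept_units units retained (`0 <= kept <= total`).
#' @param total_units total units (> 0).
#' @return list with `kept`, `total`, `percentage`.
#' @export
retention_stats <- function(kept_units, total_units) {
  if (total_units <= 0) stopf("total_units must be > 0")
  if (kept_units < 0 || kept_units > total_units) {
    stopf("need 0 <= kept_units <= total_units")
  }
  list(kept = kept_units, total = total_units,
       percentage = round_half_up(100 * kept_units / total_units, 2))
}
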