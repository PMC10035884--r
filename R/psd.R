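# Shared spectral core: a single Hann-tapered one-sided periodogram with
# power-spectral-density scaling underlies both the streaming (online)
# estimator and the offline Welch estimator, so the two agree exactly on the
# same window/overlap settings.

#' Periodic Hann window
#' @param n window length in samples.
#' @return numeric vector of length `n`.
#' @export
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (seq_len(n) - 1) / n)

#' One-sided periodogram PSD of a single window
#'
#' Hann-tapered, scaled to power spectral density (uV^2/Hz): the PSD integral
#' over frequency estimates the signal variance (and equals a^2/2 for a
#' sinusoid of amplitude a at a bin frequency).
#'
#' @param x numeric samples (one window).
#' @param fs sampling rate in Hz.
#' @param window taper; defaults to a periodic Hann window.
#' @return list with `freq` (Hz) and `psd` (uV^2/Hz).
#' @export
periodogram_psd <- function(x, fs, window = hann_window(length(x))) {
  n <- length(x)
  stopifnot(length(window) == n, n >= 2)
  X <- stats::fft(x * window)
  nf <- n %/% 2 + 1
  p <- Mod(X[seq_len(nf)])^2 / (fs * sum(window^2))
  one_sided <- rep(2, nf)
  one_sided[1] <- 1
  if (n %% 2 == 0) one_sided[nf] <- 1
  list(freq = (seq_len(nf) - 1) * fs / n, psd = p * one_sided)
}

# Band summary of a PSD: `mean` = average of PSD bins with band[1] <= f <=
# band[2] (inclusive; the feedback signal convention), `integral` = sum of
# bins times bin width (uV^2; closed-form a^2/2 oracle convention).
band_stat <- function(freq, psd, band, stat = c("mean", "integral")) {
  stat <- match.arg(stat)
  sel <- freq >= band[1] & freq <= band[2]
  if (!any(sel)) stopf("no PSD bins inside band [%g, %g] Hz", band[1], band[2])
  if (stat == "mean") mean(psd[sel]) else sum(psd[sel]) * (freq[2] - freq[1])
}
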