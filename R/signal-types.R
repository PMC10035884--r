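#' Sampled signal segment
#'
#' A single-channel sampled signal in microvolts at a fixed sampling rate: the
#' basic carrier for both synthetic and file-read EEG.
#'
#' @param samples numeric vector of samples (uV).
#' @param fs sampling rate in Hz (> 0).
#' @return an object of class `signal_segment` with fields `samples` and `fs`.
#' @export
signal_segment <- function(samples, fs) {
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) {
    stopf("`fs` must be a single positive number, got %s", format(fs))
  }
  samples <- as.numeric(samples)
  if (any(!is.finite(samples))) stopf("`samples` must be finite")
  structure(list(samples = samples, fs = fs), class = "signal_segment")
}

#' @export
print.signal_segment <- function(x, ...) {
  cat(sprintf("<signal_segment> %d samples @ %g Hz (%.2f s)\n",
              length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.signal_segment <- function(x) length(x$samples)

#' Duration of a signal segment in seconds
#' @param segment a [signal_segment()].
#' @return seconds.
#' @export
segment_duration <- function(segment) length(segment$samples) / segment$fs

#' Single-channel EEG record with typed events
#'
#' Couples a [signal_segment()] with an event table. Event onsets are
#' *0-based* sample indices (epoch windows downstream are half-open and
#' 0-based in samples), durations are in samples, and `code` is a free-form
#' label such as `"mod_up"`, `"rest"` or `"artifact"`.
#'
#' @param segment a [signal_segment()].
#' @param events data.frame with columns `onset` (0-based sample index),
#'   `duration` (samples, >= 0), `code` (character). May have zero rows.
#' @param channel_label channel name; default `"FCz"`.
#' @return an object of class `eeg_record`.
#' @export
eeg_record <- function(segment, events = empty_events(), channel_label = "FCz") {
  stopifnot(inherits(segment, "signal_segment"))
  events <- as.data.frame(events)
  required <- c("onset", "duration", "code")
  if (!all(required %in% names(events))) {
    stopf("`events` must have columns %s", paste(required, collapse = ", "))
  }
  n <- length(segment$samples)
  if (nrow(events)) {
    if (any(events$onset < 0 | events$onset >= n)) {
      stopf("event onsets must lie within [0, %d)", n)
    }
    if (any(events$duration < 0)) stopf("event durations must be >= 0")
  }
  structure(list(segment = segment, events = events,
                 channel_label = channel_label),
            class = "eeg_record")
}

#' @rdname eeg_record
#' @export
empty_events <- function() {
  data.frame(onset = integer(), duration = integer(), code = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> channel %s, %d samples @ %g Hz, %d events\n",
              x$channel_label, length(x$segment$samples), x$segment$fs,
              nrow(x$events)))
  if (nrow(x$events)) {
    tab <- table(x$events$code)
    cat("  events:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Write / read an event table as TSV
#'
#' Events are serialized in seconds (`onset_s`, `duration_s`, `code`), the
#' rate-independent interchange form consumed by the protocol and feedback
#' stages.
#'
#' @param record an [eeg_record()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(record, path) {
  ev <- record$events
  out <- data.frame(onset_s = ev$onset / record$segment$fs,
                    duration_s = ev$duration / record$segment$fs,
                    code = ev$code)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events_tsv
#' @param fs sampling rate used to map seconds back to sample indices.
#' @export
read_events_tsv <- function(path, fs) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(onset = as.integer(round(tab$onset_s * fs)),
             duration = as.integer(round(tab$duration_s * fs)),
             code = tab$code, stringsAsFactors = FALSE)
}

#' Export a record's samples to CSV
#'
#' Plain-text interchange (column `t_s`, `uV`); pairs with
#' [write_events_tsv()] for a complete text serialization of a record.
#'
#' @param record an [eeg_record()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(record, path) {
  n <- length(record$segment$samples)
  utils::write.csv(data.frame(t_s = (seq_len(n) - 1) / record$segment$fs,
                              uV = record$segment$samples),
                   path, row.names = FALSE)
  invisible(path)
}
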