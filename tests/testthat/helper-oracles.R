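# Independent single-window band-power oracle: direct DFT sums (no shared
# code with the package's FFT-based periodogram).
oracle_band_mean <- function(x, fs, band = c(4, 7)) {
  n <- length(x)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)
  xw <- x * w
  bins <- 0:(n %/% 2)
  freqs <- bins * fs / n
  sel <- bins[freqs >= band[1] & freqs <= band[2]]
  t <- 0:(n - 1)
  psd <- vapply(sel, function(k) {
    re <- sum(xw * cos(2 * pi * k * t / n))
    im <- -sum(xw * sin(2 * pi * k * t / n))
    scale <- if (k == 0 || (n %% 2 == 0 && k == n / 2)) 1 else 2
    scale * (re^2 + im^2) / (fs * sum(w^2))
  }, numeric(1))
  mean(psd)
}

# Brute-force enumeration of valid ALT goal arrangements: all C(6,3) = 20
# placements of three Up among six blocks, filtered for runs >= 3.
enumerate_valid_alt <- function() {
  combs <- utils::combn(6, 3)
  seqs <- apply(combs, 2, function(up) {
    g <- rep("Down", 6)
    g[up] <- "Up"
    g
  })
  valid <- apply(seqs, 2, function(g) max(rle(g)$lengths) <= 2)
  apply(seqs[, valid, drop = FALSE], 2, paste, collapse = "")
}

# Build a target_schedule by hand (constant exposure-time test rigs).
make_schedule <- function(n, identity = "enemy", tet_ms = 750,
                          condition = "High") {
  ev <- data.frame(index = seq_len(n), block = 1L, lane = "center",
                   distance = "mid", identity = identity,
                   onset_ms = seq_len(n) * 2000, tet_ms = tet_ms,
                   stringsAsFactors = FALSE)
  structure(list(condition = condition, events = ev),
            class = "target_schedule")
}

# Mean measured theta band power over timeline intervals of a session record.
interval_band_power <- function(record, rows, band = c(4, 7)) {
  fs <- record$segment$fs
  vals <- vapply(seq_len(nrow(rows)), function(r) {
    i0 <- floor(rows$start_s[r] * fs) + 1
    i1 <- floor(rows$end_s[r] * fs)
    welch_band_power(record$segment$samples[i0:i1], fs, win_s = 1,
                     overlap = 0.5, band = band)$power
  }, numeric(1))
  mean(vals)
}
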