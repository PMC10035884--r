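# Sample from a Gaussian discretized onto a lattice of values (weights
# proportional to the normal density at each lattice point, i.e. a truncated
# discrete Gaussian).
sample_discrete_gaussian <- function(n, lattice, center, sd) {
  w <- stats::dnorm(lattice, center, sd)
  sample(lattice, n, replace = TRUE, prob = w / sum(w))
}

SH_LANES <- c("left", "center", "right")
SH_DISTANCES <- c("near", "mid", "far")

#' Generate a Go/No-Go shooting-task target schedule
#'
#' One time-stress condition: 360 pop-up targets, exactly 40 at each of the 9
#' range locations (3 lanes x 3 distances), with an exact 324:36
#' enemy:friendly composition (4 friendly per location cell), split into 4
#' blocks of 90 trials. Inter-target intervals are drawn from a truncated
#' discrete Gaussian on the 500-1500 ms lattice in 100 ms steps (center
#' 1000 ms, sigma 250 ms). Per-target exposure times are drawn from a normal
#' distribution centered on the subject's individualized threshold —
#' `tet50_ms` under High time stress, `tet90_ms` under Low — with sigma
#' 100 ms, rounded to 1 ms and clipped to [400, 1500] ms.
#'
#' @param condition `"Low"` or `"High"` time stress.
#' @param tet50_ms,tet90_ms the subject's individualized exposure thresholds.
#' @param seed integer seed.
#' @param tet_sd_ms spread of the exposure-time distribution (ms).
#' @return an object of class `target_schedule`: `condition` and `events`, a
#'   data.frame with `index`, `block`, `lane`, `distance`, `identity`,
#'   `onset_ms` (from block start, strictly increasing within block),
#'   `tet_ms`.
#' @export
generate_target_schedule <- function(condition = c("Low", "High"),
                                     tet50_ms = 750, tet90_ms = 1100,
                                     seed = NULL, tet_sd_ms = 100) {
  condition <- match.arg(condition)
  if (tet50_ms <= 0 || tet90_ms <= 0) stopf("TETs must be > 0")
  center <- if (condition == "High") tet50_ms else tet90_ms
  with_seed(seed, {
    cells <- expand.grid(lane = SH_LANES, distance = SH_DISTANCES,
                         stringsAsFactors = FALSE)
    ev <- do.call(rbind, lapply(seq_len(nrow(cells)), function(ci) {
      data.frame(lane = cells$lane[ci], distance = cells$distance[ci],
                 identity = c(rep("enemy", 36), rep("friendly", 4)),
                 stringsAsFactors = FALSE)
    }))
    ev <- ev[sample.int(nrow(ev)), ]
    ev$index <- seq_len(nrow(ev))
    ev$block <- rep(1:4, each = 90)
    ev$tet_ms <- pmin(1500, pmax(400, round(
      stats::rnorm(nrow(ev), center, tet_sd_ms))))
    iti <- sample_discrete_gaussian(nrow(ev), seq(500, 1500, by = 100),
                                    1000, 250)
    onset <- numeric(nrow(ev))
    for (b in 1:4) {
      sel <- which(ev$block == b)
      t <- 0
      for (j in sel) {
        t <- t + iti[j]
        onset[j] <- t
        t <- t + ev$tet_ms[j]
      }
    }
    ev$onset_ms <- onset
    rownames(ev) <- NULL
    structure(list(condition = condition,
                   events = ev[, c("index", "block", "lane", "distance",
                                   "identity", "onset_ms", "tet_ms")]),
              class = "target_schedule")
  })
}

#' Generate the familiarization (FTP) schedule
#'
#' 100 all-enemy targets across the nine locations, inter-target intervals
#' from a truncated discrete Gaussian on the 1000-3000 ms lattice in 100 ms
#' steps (center 2000 ms, sigma 500 ms), exposure times uniform over the 12
#' values 400, 500, ..., 1500 ms in randomized order.
#'
#' @param seed integer seed.
#' @return a `target_schedule` with `condition = "FTP"` and 100 events in one
#'   block.
#' @export
generate_ftp_schedule <- function(seed = NULL) {
  with_seed(seed, {
    n <- 100L
    lanes <- sample(SH_LANES, n, replace = TRUE)
    dists <- sample(SH_DISTANCES, n, replace = TRUE)
    tet <- sample(seq(400, 1500, by = 100), n, replace = TRUE)
    iti <- sample_discrete_gaussian(n, seq(1000, 3000, by = 100), 2000, 500)
    onset <- cumsum(iti + c(0, tet[-n]))
    ev <- data.frame(index = seq_len(n), block = 1L, lane = lanes,
                     distance = dists, identity = "enemy", onset_ms = onset,
                     tet_ms = tet, stringsAsFactors = FALSE)
    structure(list(condition = "FTP", events = ev), class = "target_schedule")
  })
}

#' @export
print.target_schedule <- function(x, ...) {
  ev <- x$events
  cat(sprintf("<target_schedule> %s: %d targets in %d block(s), %d enemy / %d friendly\n",
              x$condition, nrow(ev), length(unique(ev$block)),
              sum(ev$identity == "enemy"), sum(ev$identity == "friendly")))
  invisible(x)
}

#' Write a schedule or trial table to TSV
#' @param x a `target_schedule` or a behavioral trial data.frame.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_schedule_tsv <- function(x, path) {
  tab <- if (inherits(x, "target_schedule")) x$events else as.data.frame(x)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
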