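#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All generators in the package route through this so
# a generator is a pure function of (arguments, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stream-specific seed from a master seed
#'
#' Counter-based split of a master seed so that independent random streams
#' (per subject, session, block, stage) are reproducible regardless of the
#' order in which they are consumed. Exact integer arithmetic below 2^31.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer counters (subject, session, ...).
#' @return an integer in [1, 2^31 - 2] usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  for (k in c(...)) {
    # multiply-with-carry style mix; doubles are exact well below 2^53
    h <- (h * 48271 + (as.numeric(k) + 1) * 16807) %% m
    h <- (h * 69621) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

# Round half away from zero to `digits` decimals (base round() rounds half to
# even, which would misreport e.g. printed retention percentages).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Moment-based sample skewness and excess kurtosis (the usual g1 / g2
# definitions used by EEG rejection tools).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^3) / s2^1.5
}

sample_kurtosis <- function(x) {
  x <- x[is.finite(x)]
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 <= 0) return(0)
  mean((x - m)^4) / s2^2 - 3
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
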