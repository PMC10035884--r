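#' Run the individual performance thresholding procedure (IPTP)
#'
#' Method-of-limits data collection: 10 alternating ascending/descending
#' series over 11 exposure-time levels, one simulated trial per level per
#' series, using the virtual shooter's psychometric function.
#'
#' @param params a [subject_params()].
#' @param levels_ms the 11 exposure-time levels (ms).
#' @param n_series number of alternating series (default 10, so 10 trials per
#'   level).
#' @param seed integer seed.
#' @return data.frame with `series`, `direction`, `tet_ms`, `hit` (0/1).
#' @export
run_iptp <- function(params, levels_ms = seq(500, 1500, by = 100),
                     n_series = 10, seed = NULL) {
  stopifnot(inherits(params, "subject_params"))
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_series), function(s) {
      asc <- s %% 2 == 1
      lv <- if (asc) sort(levels_ms) else sort(levels_ms, decreasing = TRUE)
      data.frame(series = s, direction = if (asc) "ascending" else "descending",
                 tet_ms = lv,
                 hit = as.integer(stats::runif(length(lv)) <
                                    hit_probability(lv, params)))
    }))
  })
}

#' Fit psychometric thresholds from method-of-limits responses
#'
#' Pools ascending and descending series and fits a two-parameter logistic
#' hit-rate curve by maximum likelihood (binomial GLM with logit link); the
#' 50% and 90% exposure-time thresholds are its inverses at 0.5 and 0.9.
#'
#' @param responses data.frame with columns `tet_ms` and `hit` (0/1 per
#'   trial), e.g. from [run_iptp()]; aggregated tables with columns `tet_ms`,
#'   `hits`, `n` are also accepted.
#' @return an object of class `threshold_result`: list with `tet50_ms`,
#'   `tet90_ms`, `slope` (1/ms) and the fitted `glm`.
#' @export
method_of_limits <- function(responses) {
  responses <- as.data.frame(responses)
  if (all(c("hits", "n") %in% names(responses))) {
    agg <- responses[, c("tet_ms", "hits", "n")]
  } else {
    if (!all(c("tet_ms", "hit") %in% names(responses))) {
      stopf("responses need columns (tet_ms, hit) or (tet_ms, hits, n)")
    }
    agg <- stats::aggregate(hit ~ tet_ms, responses,
                            function(h) c(sum(h), length(h)))
    agg <- data.frame(tet_ms = agg$tet_ms, hits = agg$hit[, 1],
                      n = agg$hit[, 2])
  }
  if (nrow(agg) < 2) stopf("need responses at >= 2 exposure-time levels")
  if (sum(agg$hits) == 0 || sum(agg$hits) == sum(agg$n)) {
    stopf("degenerate data (all hits or all misses): no threshold estimable")
  }
  fit <- suppressWarnings(
    stats::glm(cbind(hits, n - hits) ~ tet_ms, family = stats::binomial(),
               data = agg))
  b <- stats::coef(fit)
  if (!is.finite(b[2]) || b[2] <= 0) {
    stopf("hit rate is not increasing in exposure time; no threshold")
  }
  tet50 <- unname(-b[1] / b[2])
  tet90 <- unname((stats::qlogis(0.9) - b[1]) / b[2])
  structure(list(tet50_ms = tet50, tet90_ms = tet90, slope = unname(b[2]),
                 fit = fit), class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> TET50 %.1f ms, TET90 %.1f ms (slope %.4g /ms)\n",
              x$tet50_ms, x$tet90_ms, x$slope))
  invisible(x)
}
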