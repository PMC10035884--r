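#' Virtual-subject parameters
#'
#' All tunables of a synthetic participant: the EEG side (baseline theta
#' power, multiplicative up/down modulation gains, additive dB trends per
#' session and per block, alpha power, artifact rate) and the behavioral side
#' (psychometric target-exposure thresholds, commission tendency, reaction
#' time distribution).
#'
#' Gains act multiplicatively on band power; trends act additively in dB,
#' matching the dB scale of the analysis stage. `tet50_ms < tet90_ms` must
#' hold because the hit rate is increasing in exposure time.
#'
#' @param subject_id identifier (character or integer).
#' @param group `"INC"` (up-modulation only) or `"ALT"` (alternating).
#' @param baseline_theta_power resting theta band-mean power (uV^2, > 0).
#' @param up_gain,down_gain multiplicative band-power gains during up/down
#'   modulation (>= 0).
#' @param session_trend,block_trend additive dB change per session / block of
#'   modulation power.
#' @param alpha_power alpha (8-13 Hz) band-mean power (uV^2, >= 0).
#' @param artifact_rate artifact transients per minute (>= 0).
#' @param tet50_ms,tet90_ms target exposure times (ms) at which the enemy hit
#'   rate is 50% / 90%; `tet50_ms < tet90_ms`.
#' @param commission_prob probability of firing at a friendly target, `[0,1]`.
#' @param rt_median_ms median of the log-normal shot-latency distribution (ms).
#' @param rt_spread log-scale SD of the latency distribution (> 0).
#' @return an object of class `subject_params`.
#' @export
subject_params <- function(subject_id, group = c("INC", "ALT"),
                           baseline_theta_power = 20, up_gain = 2,
                           down_gain = 0.5, session_trend = 0,
                           block_trend = 0, alpha_power = 15,
                           artifact_rate = 8, tet50_ms = 750,
                           tet90_ms = 1100, commission_prob = 0.26,
                           rt_median_ms = 450, rt_spread = 0.2) {
  group <- match.arg(group)
  if (baseline_theta_power <= 0) stopf("baseline_theta_power must be > 0")
  if (up_gain < 0 || down_gain < 0) stopf("gains must be >= 0")
  if (alpha_power < 0) stopf("alpha_power must be >= 0")
  if (artifact_rate < 0) stopf("artifact_rate must be >= 0")
  if (!(tet50_ms > 0 && tet90_ms > 0)) stopf("TETs must be > 0")
  if (tet50_ms >= tet90_ms) {
    stopf("tet50_ms must be < tet90_ms (hit rate increases with exposure)")
  }
  if (commission_prob < 0 || commission_prob > 1) {
    stopf("commission_prob must be in [0, 1]")
  }
  if (rt_median_ms <= 0 || rt_spread <= 0) stopf("RT parameters must be > 0")
  structure(list(subject_id = subject_id, group = group,
                 baseline_theta_power = baseline_theta_power,
                 up_gain = up_gain, down_gain = down_gain,
                 session_trend = session_trend, block_trend = block_trend,
                 alpha_power = alpha_power, artifact_rate = artifact_rate,
                 tet50_ms = tet50_ms, tet90_ms = tet90_ms,
                 commission_prob = commission_prob,
                 rt_median_ms = rt_median_ms, rt_spread = rt_spread),
            class = "subject_params")
}

#' @export
print.subject_params <- function(x, ...) {
  cat(sprintf("<subject_params> %s (%s): theta %.3g uV^2, gains %.3g/%.3g, trends %+.3g dB/session %+.3g dB/block\n",
              x$subject_id, x$group, x$baseline_theta_power, x$up_gain,
              x$down_gain, x$session_trend, x$block_trend))
  cat(sprintf("  shooter: TET50 %.0f ms, TET90 %.0f ms, commission %.2f, RT median %.0f ms\n",
              x$tet50_ms, x$tet90_ms, x$commission_prob, x$rt_median_ms))
  invisible(x)
}

#' Write / read subject parameters as JSON
#' @param params a [subject_params()] or list of them.
#' @param path JSON path.
#' @return `path` (write) or the parsed object(s) (read).
#' @export
write_subject_params <- function(params, path) {
  payload <- if (inherits(params, "subject_params")) unclass(params) else {
    lapply(params, unclass)
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_subject_params
#' @export
read_subject_params <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(raw$subject_id)) return(do.call(subject_params, as.list(raw)))
  lapply(raw, function(p) do.call(subject_params, as.list(p)))
}

#' Draw a cohort of virtual subjects
#'
#' Samples per-subject parameters around realistic population values. Group
#' assignments and sizes default to the study design (12 INC, 18 ALT). ALT
#' subjects carry a positive session trend (population mean 0.32 dB/session)
#' and block trend (0.06 dB/block) while INC trends center on zero — the
#' qualitative group-by-session pattern the analysis stage is meant to
#' detect. Artifact rate defaults to 8/min so that roughly a quarter of 1-s
#' windows are artifact-contaminated.
#'
#' @param n_inc,n_alt group sizes.
#' @param seed integer seed.
#' @param alt_session_trend,inc_session_trend population mean session trends
#'   (dB/session).
#' @param alt_block_trend population mean block trend for ALT (dB/block).
#' @return list of [subject_params()], INC subjects first.
#' @export
draw_cohort_params <- function(n_inc = 12, n_alt = 18, seed = 1,
                               alt_session_trend = 0.32,
                               inc_session_trend = 0,
                               alt_block_trend = 0.06) {
  groups <- c(rep("INC", n_inc), rep("ALT", n_alt))
  lapply(seq_along(groups), function(i) {
    with_seed(derive_seed(seed, 101, i), {
      g <- groups[i]
      tet50 <- stats::rnorm(1, 750, 50)
      subject_params(
        subject_id = sprintf("S%02d", i), group = g,
        baseline_theta_power = stats::rlnorm(1, log(20), 0.3),
        up_gain = stats::rlnorm(1, log(2), 0.15),
        down_gain = if (g == "ALT") stats::rlnorm(1, log(0.5), 0.15) else 1,
        session_trend = stats::rnorm(
          1, if (g == "ALT") alt_session_trend else inc_session_trend, 0.15),
        block_trend = stats::rnorm(
          1, if (g == "ALT") alt_block_trend else 0, 0.03),
        alpha_power = stats::rlnorm(1, log(15), 0.3),
        artifact_rate = stats::runif(1, 5, 11),
        tet50_ms = tet50,
        tet90_ms = tet50 + stats::rnorm(1, 350, 40),
        commission_prob = min(0.95, max(0.02, stats::rnorm(1, 0.26, 0.08))),
        rt_median_ms = stats::rnorm(1, 450, 40),
        rt_spread = 0.2)
    })
  })
}
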