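#' Simulate a cohort's theta long table at the band-power level
#'
#' Generates the training-stage long table (one row per subject x session x
#' block, with the block's modulation code) directly from the generative
#' model in dB units, without waveform synthesis:
#'
#' `y = mu + u_i + (trend_i + v_i) * (session - 1) + block_trend_i * (block - 1)
#'    + mod_effect * modulation + e`
#'
#' with subject intercepts `u_i ~ N(0, tau)`, subject session-slope deviations
#' `v_i ~ N(0, tau_slope)` and residuals `e ~ N(0, sigma2)`. Defaults anchor
#' the marginal distribution to the study-scale values (grand mean -0.18 dB,
#' between-subject variance 6.25, residual variance 1.76, i.e. SD 2.83 and
#' ICC 0.78) with the group-specific mean session trends of the cohort
#' parameters (ALT 0.32 dB/session, INC 0). Block goals respect the protocol
#' randomization.
#'
#' @param n_inc,n_alt group sizes.
#' @param n_sessions,n_blocks table dimensions (defaults: 5 sessions, 6
#'   blocks).
#' @param seed integer seed.
#' @param mu grand mean (dB).
#' @param tau between-subject intercept variance.
#' @param tau_slope between-subject session-slope variance
#'   (default `0.15^2`).
#' @param sigma2 residual variance.
#' @param alt_session_trend,inc_session_trend mean session trends (dB/session).
#' @param alt_block_trend,inc_block_trend mean block trends (dB/block).
#' @param mod_effect additive effect of up- vs down-modulation (dB).
#' @return long data.frame with columns `subject`, `group`, `session`,
#'   `block`, `modulation`, `y`.
#' @export
simulate_cohort_fm_theta <- function(n_inc = 12, n_alt = 18, n_sessions = 5,
                                     n_blocks = 6, seed = 1, mu = -0.18,
                                     tau = 6.25, tau_slope = 0.15^2,
                                     sigma2 = 1.76, alt_session_trend = 0.32,
                                     inc_session_trend = 0,
                                     alt_block_trend = 0.06,
                                     inc_block_trend = 0, mod_effect = 0.10) {
  groups <- c(rep("INC", n_inc), rep("ALT", n_alt))
  n_sub <- length(groups)
  with_seed(seed, {
    u <- stats::rnorm(n_sub, 0, sqrt(tau))
    v <- stats::rnorm(n_sub, 0, sqrt(tau_slope))
    rows <- vector("list", n_sub)
    for (i in seq_len(n_sub)) {
      g <- groups[i]
      trend <- if (g == "ALT") alt_session_trend else inc_session_trend
      btrend <- if (g == "ALT") alt_block_trend else inc_block_trend
      per_sess <- lapply(seq_len(n_sessions), function(s) {
        goals <- if (g == "ALT") {
          assign_block_goals("ALT", seed = derive_seed(seed, i, s))
        } else rep("Up", n_blocks)
        goals <- rep_len(goals, n_blocks)
        data.frame(subject = sprintf("S%02d", i), group = g, session = s,
                   block = seq_len(n_blocks), modulation = goals,
                   stringsAsFactors = FALSE)
      })
      d <- do.call(rbind, per_sess)
      d$y <- mu + u[i] + (trend + v[i]) * (d$session - 1) +
        btrend * (d$block - 1) +
        mod_effect * as.numeric(d$modulation == "Up") +
        stats::rnorm(nrow(d), 0, sqrt(sigma2))
      rows[[i]] <- d
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Run the four-step model ladder on a long table
#'
#' Intercepts-only; level-1 predictors; level-1 plus session (with its
#' interactions with the level-1 predictors); and the full model adding group
#' and its interactions. The session rung and the full model carry a random
#' session slope.
#'
#' @param table long data.frame with `subject`, `y` and the predictors.
#' @param level1 character vector of level-1 predictor names present in the
#'   table (e.g. `c("block", "modulation")` for training,
#'   `"condition"` for the shooting task).
#' @param p_method passed to [fit_mlm()].
#' @return named list of `mlm_result`s: `intercepts_only`, `level1`,
#'   `session`, `full`.
#' @export
fit_model_ladder <- function(table, level1 = c("block", "modulation"),
                             p_method = "wald") {
  level1 <- intersect(level1, names(table))
  # session interacts with the trend-bearing level-1 predictor (block for the
  # training table, condition for the shooting table), not the modulation code
  trend1 <- setdiff(level1, "modulation")
  sess_terms <- c(level1, "session",
                  if (length(trend1)) paste0(trend1, ":session"))
  full_core <- if (length(trend1)) {
    paste0(paste(trend1, collapse = " * "), " * session * group")
  } else "session * group"
  full_terms <- c(setdiff(level1, trend1), full_core)
  list(
    intercepts_only = fit_mlm(table, model_spec(), p_method = p_method),
    level1 = fit_mlm(table, model_spec(fixed = level1), p_method = p_method),
    session = fit_mlm(table, model_spec(fixed = sess_terms,
                                        random_slope = "session"),
                      p_method = p_method),
    full = fit_mlm(table, model_spec(fixed = full_terms,
                                     random_slope = "session"),
                   p_method = p_method))
}
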