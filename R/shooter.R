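# Psychometric slope (1/ms) of the two-parameter logistic constrained through
# (tet50, 0.5) and (tet90, 0.9): P(hit | TET) = plogis((TET - tet50) * k).
psychometric_slope <- function(tet50_ms, tet90_ms) {
  stats::qlogis(0.9) / (tet90_ms - tet50_ms)
}

#' Enemy hit probability of a virtual shooter
#' @param tet_ms exposure time(s), ms.
#' @param params a [subject_params()].
#' @return probability of a registered hit.
#' @export
hit_probability <- function(tet_ms, params) {
  stats::plogis((tet_ms - params$tet50_ms) *
                  psychometric_slope(params$tet50_ms, params$tet90_ms))
}

#' Simulate shooter responses to a target schedule
#'
#' For enemy targets the probability of a registered hit follows the logistic
#' psychometric through (`tet50_ms`, 0.5) and (`tet90_ms`, 0.9) exactly. Shot
#' latency is log-normal with median `rt_median_ms`; a shot registers only if
#' the latency does not exceed the exposure time (otherwise the trial is an
#' omission), and the hit probability is apportioned conditionally on firing
#' (clipped at 1 when the latency distribution makes the marginal target
#' unreachable). Friendly targets draw a commission with probability
#' `commission_prob`; commission shot latency is truncated at the exposure
#' time, and a commission shot hits with the same psychometric accuracy.
#'
#' @param params a [subject_params()].
#' @param schedule a `target_schedule`.
#' @param seed integer seed.
#' @return data.frame of behavioral trials: the target fields plus
#'   `shot_time_ms` (NA if no shot), `hit`, `outcome` (one of `hit`, `miss`,
#'   `omission`, `commission`, `correct_withhold`) and `rt_ms`.
#' @export
simulate_shooter <- function(params, schedule, seed = NULL) {
  stopifnot(inherits(params, "subject_params"),
            inherits(schedule, "target_schedule"))
  ev <- schedule$events
  n <- nrow(ev)
  with_seed(seed, {
    lat <- stats::rlnorm(n, log(params$rt_median_ms), params$rt_spread)
    u_hit <- stats::runif(n)
    u_comm <- stats::runif(n)

    enemy <- ev$identity == "enemy"
    p_marginal <- hit_probability(ev$tet_ms, params)
    p_fire <- stats::plnorm(ev$tet_ms, log(params$rt_median_ms),
                            params$rt_spread)
    fired <- rep(FALSE, n)
    hit <- rep(FALSE, n)
    shot_time <- rep(NA_real_, n)

    # enemy: fire iff latency beats the exposure; conditional hit probability
    fired[enemy] <- lat[enemy] <= ev$tet_ms[enemy]
    q <- ifelse(p_fire > 0, pmin(1, p_marginal / p_fire), 0)
    hit[enemy] <- fired[enemy] & (u_hit[enemy] < q[enemy])
    shot_time[enemy & fired] <- lat[enemy & fired]

    # friendly: commission decision, latency squeezed before target drop
    fr <- !enemy
    fired[fr] <- u_comm[fr] < params$commission_prob
    shot_time[fr & fired] <- pmin(lat[fr & fired], ev$tet_ms[fr & fired])
    hit[fr] <- fired[fr] & (u_hit[fr] < p_marginal[fr])

    outcome <- ifelse(enemy,
                      ifelse(hit, "hit", ifelse(fired, "miss", "omission")),
                      ifelse(fired, "commission", "correct_withhold"))
    out <- cbind(ev,
                 data.frame(shot_time_ms = shot_time, hit = hit,
                            outcome = outcome,
                            rt_ms = shot_time, stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out
  })
}
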