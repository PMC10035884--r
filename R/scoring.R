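#' Score a set of behavioral trials
#'
#' The scoreboard rules: shot fired at an enemy target +1, enemy target hit
#' +1, shot withheld at a friendly target +1; shot fired at a friendly target
#' -1, friendly target hit -1, fail-to-fire at an enemy target (omission) -1,
#' enemy target fired at but missed -1. So an enemy fired-and-hit trial is
#' worth +2, an enemy fired-and-missed 0, a friendly fired-and-hit -2.
#'
#' @param trials data.frame from [simulate_shooter()] (needs `identity`,
#'   `outcome`, `hit`).
#' @return integer total score.
#' @export
score_events <- function(trials) {
  trials <- as.data.frame(trials)
  enemy <- trials$identity == "enemy"
  fired <- trials$outcome %in% c("hit", "miss", "commission")
  score <- sum(enemy & fired) +                 # shot fired at enemy
    sum(enemy & trials$hit) -                   # enemy hit
    sum(enemy & fired & !trials$hit) -          # enemy fired but missed
    sum(enemy & trials$outcome == "omission") + # fail to fire at enemy
    sum(!enemy & trials$outcome == "correct_withhold") - # withheld at friendly
    sum(!enemy & fired) -                       # fired at friendly
    sum(!enemy & trials$hit)                    # friendly hit
  as.integer(score)
}

#' Behavioral performance metrics
#'
#' Commission percentage (friendly targets fired at, over friendly targets),
#' hit percentage (enemy targets hit, over enemy targets; a target counts as
#' hit if any shot hit it), and mean reaction time to enemy targets. Per the
#' scoring convention, a hit target's RT is the trigger time of the shot that
#' hit it; a missed (but fired-at) target's RT is the time of the first
#' trigger pull; omissions contribute no RT.
#'
#' @param trials data.frame from [simulate_shooter()]. Multiple shots per
#'   target are supported when `shot_time_ms` is a list column or
#'   `rt_ms` is pre-resolved per the rules above.
#' @return list with `commission_pct`, `hit_pct`, `mean_rt_ms`, `n_enemy`,
#'   `n_friendly`. Missing classes yield `NA` with a warning.
#' @export
compute_behavioral_metrics <- function(trials) {
  trials <- as.data.frame(trials)
  enemy <- trials[trials$identity == "enemy", , drop = FALSE]
  friendly <- trials[trials$identity == "friendly", , drop = FALSE]
  commission_pct <- if (nrow(friendly)) {
    100 * sum(friendly$outcome == "commission") / nrow(friendly)
  } else {
    warnf("no friendly trials; commission percentage undefined")
    NA_real_
  }
  hit_pct <- if (nrow(enemy)) {
    100 * sum(enemy$hit) / nrow(enemy)
  } else {
    warnf("no enemy trials; hit percentage undefined")
    NA_real_
  }
  rts <- enemy$rt_ms[!is.na(enemy$rt_ms)]
  mean_rt <- if (length(rts)) mean(rts) else NA_real_
  list(commission_pct = commission_pct, hit_pct = hit_pct,
       mean_rt_ms = mean_rt, n_enemy = nrow(enemy),
       n_friendly = nrow(friendly))
}

#' Resolve the per-target reaction time from multiple shot times
#'
#' Helper implementing the RT rule for multi-shot targets: if the target was
#' hit, the time of the hitting shot; if fired at but missed, the time of the
#' first shot; `NA` if no shot was fired.
#'
#' @param shot_times_ms numeric vector of trigger-pull times (ms from target
#'   onset).
#' @param hit_index index of the hitting shot within `shot_times_ms`, or `NA`
#'   if the target was not hit.
#' @return RT in ms or `NA`.
#' @export
resolve_rt <- function(shot_times_ms, hit_index = NA) {
  if (!length(shot_times_ms)) return(NA_real_)
  if (!is.na(hit_index)) shot_times_ms[hit_index] else min(shot_times_ms)
}
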