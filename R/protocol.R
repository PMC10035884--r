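# Protocol constants: six blocks of six trials per session, each trial a 10-s
# rest followed by a 30-s active modulation period; five training sessions.
NF_TRIALS_PER_BLOCK <- 6L
NF_BLOCKS_PER_SESSION <- 6L
NF_REST_S <- 10
NF_MOD_S <- 30
NF_SESSIONS <- 5L

#' Assign modulation goals to the six blocks of a session
#'
#' INC subjects up-modulate in every block. ALT subjects get a uniform draw
#' from the valid arrangements of three Up and three Down blocks with no three
#' consecutive equal goals (14 of the 20 arrangements are valid); sampling is
#' by rejection from uniform permutations, so it is uniform over the valid
#' set.
#'
#' @param group `"INC"` or `"ALT"`.
#' @param seed integer seed.
#' @return character vector of 6 goals (`"Up"` / `"Down"`).
#' @export
assign_block_goals <- function(group = c("INC", "ALT"), seed = NULL) {
  group <- match.arg(group)
  if (group == "INC") return(rep("Up", NF_BLOCKS_PER_SESSION))
  with_seed(seed, {
    repeat {
      g <- sample(c(rep("Up", 3), rep("Down", 3)))
      if (max(rle(g)$lengths) <= 2) return(g)
    }
  })
}

#' Build the timed structure of one neurofeedback session
#'
#' Lays out six blocks of six trials, each trial a 10-s rest followed by a
#' 30-s modulation interval: 180 s of active modulation and 60 s of rest per
#' block, 1080 s active per session. Intervals are contiguous and
#' non-overlapping.
#'
#' @param session_index 1-based session number (1-5).
#' @param goals character vector of 6 block goals from [assign_block_goals()].
#' @return an object of class `nf_session`: list with `session_index`,
#'   `goals`, `threshold` (`NULL` until assigned) and `timeline`, a data.frame
#'   with one row per interval (`block`, `trial`, `phase` = rest/mod, `goal`,
#'   `start_s`, `end_s`).
#' @export
build_session_timeline <- function(session_index, goals) {
  if (length(goals) != NF_BLOCKS_PER_SESSION) {
    stopf("exactly %d block goals required, got %d", NF_BLOCKS_PER_SESSION,
          length(goals))
  }
  if (!all(goals %in% c("Up", "Down"))) stopf("goals must be 'Up' or 'Down'")
  rows <- list()
  t <- 0
  for (b in seq_len(NF_BLOCKS_PER_SESSION)) {
    for (tr in seq_len(NF_TRIALS_PER_BLOCK)) {
      rows[[length(rows) + 1]] <- data.frame(
        block = b, trial = tr, phase = c("rest", "mod"), goal = goals[b],
        start_s = c(t, t + NF_REST_S),
        end_s = c(t + NF_REST_S, t + NF_REST_S + NF_MOD_S))
      t <- t + NF_REST_S + NF_MOD_S
    }
  }
  structure(list(session_index = as.integer(session_index), goals = goals,
                 threshold = NULL, timeline = do.call(rbind, rows)),
            class = "nf_session")
}

#' @export
print.nf_session <- function(x, ...) {
  cat(sprintf("<nf_session> session %d: goals %s; %.0f s total (%.0f s active)\n",
              x$session_index, paste(substr(x$goals, 1, 1), collapse = ""),
              max(x$timeline$end_s), session_active_seconds(x)))
  invisible(x)
}

#' Timing summaries of a session
#'
#' @param session an `nf_session`.
#' @return total active-modulation seconds in the session
#'   ([session_active_seconds()]) or per block ([block_active_seconds()],
#'   [block_rest_seconds()]).
#' @export
session_active_seconds <- function(session) {
  tl <- session$timeline
  sum(tl$end_s[tl$phase == "mod"] - tl$start_s[tl$phase == "mod"])
}

#' @rdname session_active_seconds
#' @export
block_active_seconds <- function(session) {
  tl <- session$timeline
  m <- tl[tl$phase == "mod", ]
  as.numeric(tapply(m$end_s - m$start_s, m$block, sum))
}

#' @rdname session_active_seconds
#' @export
block_rest_seconds <- function(session) {
  tl <- session$timeline
  r <- tl[tl$phase == "rest", ]
  as.numeric(tapply(r$end_s - r$start_s, r$block, sum))
}

#' Build the full study plan for a cohort
#'
#' One orientation session, five combined neurofeedback + shooting-task
#' sessions and one final shooting-task-only session. In session 1 the
#' shooting task precedes training; in sessions 2-5 training comes first.
#' Block goals are re-randomized independently per subject and session.
#'
#' @param n_inc,n_alt group sizes (>= 1).
#' @param master_seed integer master seed; the whole plan is a pure function
#'   of it.
#' @return an object of class `study_plan`: `subjects` (data.frame
#'   `subject_id`, `group`), `schedule` (data.frame of the seven study visits
#'   with `has_nf`, `has_sh`, `sh_before_nf`), and `nf_sessions`, a list (per
#'   subject) of lists of 5 [build_session_timeline()] objects.
#' @export
build_study_plan <- function(n_inc = 12, n_alt = 18, master_seed = 1) {
  if (n_inc < 1 || n_alt < 1) stopf("group sizes must be >= 1")
  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_inc + n_alt)),
    group = c(rep("INC", n_inc), rep("ALT", n_alt)),
    stringsAsFactors = FALSE)
  schedule <- data.frame(
    visit = 0:6,
    label = c("orientation", paste0("session", 1:6)),
    has_nf = c(FALSE, rep(TRUE, NF_SESSIONS), FALSE),
    has_sh = c(FALSE, rep(TRUE, 6)),
    sh_before_nf = c(FALSE, TRUE, rep(FALSE, 5)))
  nf_sessions <- lapply(seq_len(nrow(subjects)), function(i) {
    lapply(seq_len(NF_SESSIONS), function(s) {
      goals <- assign_block_goals(subjects$group[i],
                                  seed = derive_seed(master_seed, i, s))
      build_session_timeline(s, goals)
    })
  })
  names(nf_sessions) <- subjects$subject_id
  structure(list(subjects = subjects, schedule = schedule,
                 nf_sessions = nf_sessions, master_seed = master_seed),
            class = "study_plan")
}

#' @export
print.study_plan <- function(x, ...) {
  cat(sprintf("<study_plan> %d subjects (%d INC, %d ALT), %d NF sessions each; master seed %d\n",
              nrow(x$subjects), sum(x$subjects$group == "INC"),
              sum(x$subjects$group == "ALT"), NF_SESSIONS, x$master_seed))
  invisible(x)
}

#' Serialize a study plan to JSON
#' @param plan a [build_study_plan()] result.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_study_plan <- function(plan, path) {
  payload <- list(
    master_seed = plan$master_seed,
    subjects = plan$subjects,
    schedule = plan$schedule,
    goals = lapply(plan$nf_sessions, function(sess) {
      lapply(sess, function(s) s$goals)
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
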