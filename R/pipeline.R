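default_study_config <- function() {
  list(
    master_seed = NULL,
    n_inc = 12L,
    n_alt = 18L,
    engine = "power",
    fs = 2048,
    background_scale = 5,
    out_dir = NULL,
    feedback = list(window_s = 1, overlap_frac = 0.875, band_lo = 4,
                    band_hi = 7, artifact_limit_uV = 75),
    cohort = list(alt_session_trend = 0.32, inc_session_trend = 0,
                  alt_block_trend = 0.06),
    theta_model = list(mu = -0.18, tau = 6.25, tau_slope = 0.15^2,
                       sigma2 = 1.76, mod_effect = 0.10, sh_mu = 0.85,
                       sh_sigma2 = 1.6, sh_condition_effect = 0.14),
    subject_overrides = list())
}

check_unknown <- function(given, allowed, where) {
  unknown <- setdiff(names(given), allowed)
  if (length(unknown)) {
    stopf("unknown config key(s) in %s: %s", where,
          paste(unknown, collapse = ", "))
  }
}

#' Validate and normalize a study configuration
#'
#' Accepts a config list or a JSON file path, fills defaults, checks
#' cross-field invariants (positive sizes, gains, probabilities, rates) and
#' rejects unknown keys with their field path. Normalization is idempotent.
#'
#' @param config named list or path to a JSON config file. `master_seed` is
#'   required.
#' @return normalized config list of class `study_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  config <- unclass(config)
  def <- default_study_config()
  check_unknown(config, names(def), "config")
  for (sub in c("feedback", "cohort", "theta_model", "subject_overrides")) {
    if (!is.null(config[[sub]])) {
      allowed <- if (sub == "subject_overrides") {
        setdiff(names(formals(subject_params)), c("subject_id", "group"))
      } else names(def[[sub]])
      check_unknown(config[[sub]], allowed, sub)
      def[[sub]] <- utils::modifyList(def[[sub]], as.list(config[[sub]]))
    }
  }
  for (key in setdiff(names(def), c("feedback", "cohort", "theta_model",
                                    "subject_overrides"))) {
    if (!is.null(config[[key]])) def[[key]] <- config[[key]]
  }
  if (is.null(def$master_seed)) stopf("config requires `master_seed`")
  def$master_seed <- as.integer(def$master_seed)
  if (def$n_inc < 1 || def$n_alt < 1) stopf("group sizes must be >= 1")
  if (!def$engine %in% c("power", "eeg")) {
    stopf("engine must be 'power' or 'eeg'")
  }
  ov <- def$subject_overrides
  for (gn in c("up_gain", "down_gain")) {
    if (!is.null(ov[[gn]]) && ov[[gn]] < 0) {
      stopf("subject_overrides$%s must be >= 0", gn)
    }
  }
  if (!is.null(ov$commission_prob) &&
      (ov$commission_prob < 0 || ov$commission_prob > 1)) {
    stopf("subject_overrides$commission_prob must be in [0, 1]")
  }
  if (!is.null(ov$artifact_rate) && ov$artifact_rate < 0) {
    stopf("subject_overrides$artifact_rate must be >= 0")
  }
  structure(def, class = "study_config")
}

# Shooting-task theta long table at the band-power level (6 sessions x 2
# conditions per subject); group-null by default, matching the corresponding
# human-scale pattern.
simulate_cohort_sh_theta <- function(n_inc, n_alt, seed, mu = 0.85,
                                     tau = 6.25, sigma2 = 1.6,
                                     condition_effect = 0.14) {
  groups <- c(rep("INC", n_inc), rep("ALT", n_alt))
  with_seed(seed, {
    u <- stats::rnorm(length(groups), 0, sqrt(tau))
    grid <- expand.grid(session = 1:6, condition = c("Low", "High"),
                        stringsAsFactors = FALSE)
    out <- do.call(rbind, lapply(seq_along(groups), function(i) {
      d <- grid
      d$subject <- sprintf("S%02d", i)
      d$group <- groups[i]
      d$y <- mu + u[i] + condition_effect * (d$condition == "High") +
        stats::rnorm(nrow(d), 0, sqrt(sigma2))
      d
    }))
    out[, c("subject", "group", "session", "condition", "y")]
  })
}

# Offline analysis of one simulated training session record: per-trial
# modulation-vs-baseline dB after 1-s sub-epoch artifact screening,
# aggregated per block, plus retention accounting in seconds.
analyze_nf_record <- function(record, session, band = c(4, 7),
                              criteria = rejection_criteria()) {
  rec <- preprocess_record(record, highpass_hz = 1,
                           target_fs = record$segment$fs / 4)
  epochs <- epoch_records(rec, c("mod_up", "mod_down"), -3, 30)
  subs <- sub_epoch(epochs, 1)
  rej <- reject_epochs(subs, criteria)
  parents <- vapply(subs, function(e) e$parent, integer(1))
  t0 <- vapply(subs, function(e) e$t0_s, numeric(1))
  power1s <- vapply(seq_along(subs), function(j) {
    if (!rej$keep[j]) return(NA_real_)
    welch_band_power(subs[[j]]$samples, rec$segment$fs, win_s = 1,
                     overlap = 0.5, band = band)$power
  }, numeric(1))
  tl <- session$timeline
  mod_rows <- tl[tl$phase == "mod", ]
  per_trial <- do.call(rbind, lapply(seq_along(epochs), function(i) {
    sel <- parents == i & rej$keep
    base <- power1s[sel & t0 < 0]
    task <- power1s[sel & t0 >= 0]
    db <- if (length(base) && length(task) && mean(base) > 0) {
      band_power_db(mean(task), mean(base))
    } else NA_real_
    data.frame(trial = i, block = mod_rows$block[i], goal = mod_rows$goal[i],
               db = db, kept_s = sum(sel), total_s = sum(parents == i))
  }))
  by_block <- stats::aggregate(db ~ block + goal, per_trial, mean,
                               na.action = stats::na.omit)
  list(per_trial = per_trial, by_block = by_block[order(by_block$block), ],
       kept_s = sum(rej$keep), total_s = length(subs))
}

# Closed-loop feedback pass over one session record: streaming frames, gating,
# per-block achievement and block mean powers (for the next session's
# threshold).
run_nf_feedback <- function(record, session, threshold, fs) {
  cfg <- feedback_config(fs = fs, window_samples = as.integer(fs),
                         overlap_samples = as.integer(round(0.875 * fs)))
  frames <- stream_theta_power(record, cfg, threshold = threshold)
  frames <- artifact_gate(frames, record, cfg, threshold = threshold)
  tl <- session$timeline
  out <- do.call(rbind, lapply(unique(tl$block), function(b) {
    rows <- tl[tl$block == b & tl$phase == "mod", ]
    in_block <- frames$t_s > min(rows$start_s) & frames$t_s <= max(rows$end_s)
    fb <- frames[in_block, , drop = FALSE]
    live <- fb[!fb$gated, , drop = FALSE]
    data.frame(block = b, goal = rows$goal[1],
               achievement_pct = if (nrow(live)) {
                 block_achievement(fb, rows$goal[1])
               } else NA_real_,
               mean_power = if (nrow(live)) mean(live$theta_power) else NA_real_)
  }))
  out
}

#' Run the full simulated study
#'
#' Builds the study plan, draws the virtual cohort, simulates training and
#' shooting-task data, runs the offline analysis and the four-step model
#' ladder for each outcome, and (optionally) writes all tables and reports to
#' `out_dir`. Deterministic given `master_seed`.
#'
#' Two engines: `"power"` generates the theta long tables directly at the
#' band-power level (fast; the default), while `"eeg"` synthesizes full
#' waveforms per subject and session and pushes them through the closed-loop
#' feedback pass and the offline spectral pipeline (slow; intended for small
#' cohorts and for validating the signal path end to end). The behavioral
#' tables always come from the mechanistic virtual shooter.
#'
#' @param config a config list or JSON path accepted by [validate_config()].
#' @return an object of class `study_outputs`: `config`, `plan`, `params`,
#'   `nf_table`, `sh_theta_table`, `behavior_table`, `ladders` (per outcome),
#'   `retention` (eeg engine), `achievement` (eeg engine), `log`, and `paths`
#'   (when `out_dir` was set).
#' @export
run_study <- function(config) {
  cfg <- validate_config(config)
  seed <- cfg$master_seed
  log <- list()
  tick <- function(stage, n) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, seed = seed, n = n,
                                          time = format(Sys.time()))
  }

  plan <- build_study_plan(cfg$n_inc, cfg$n_alt, master_seed = seed)
  params <- draw_cohort_params(cfg$n_inc, cfg$n_alt,
                               seed = derive_seed(seed, 7),
                               alt_session_trend = cfg$cohort$alt_session_trend,
                               inc_session_trend = cfg$cohort$inc_session_trend,
                               alt_block_trend = cfg$cohort$alt_block_trend)
  if (length(cfg$subject_overrides)) {
    params <- lapply(params, function(p) {
      do.call(subject_params, utils::modifyList(unclass(p),
                                                cfg$subject_overrides))
    })
  }
  tick("plan+cohort", nrow(plan$subjects))

  retention <- NULL
  achievement <- NULL
  if (cfg$engine == "power") {
    tm <- cfg$theta_model
    nf_table <- simulate_cohort_fm_theta(
      cfg$n_inc, cfg$n_alt, seed = seed, mu = tm$mu, tau = tm$tau,
      tau_slope = tm$tau_slope, sigma2 = tm$sigma2,
      alt_session_trend = cfg$cohort$alt_session_trend,
      inc_session_trend = cfg$cohort$inc_session_trend,
      alt_block_trend = cfg$cohort$alt_block_trend, mod_effect = tm$mod_effect)
    sh_theta <- simulate_cohort_sh_theta(
      cfg$n_inc, cfg$n_alt, seed = derive_seed(seed, 13), mu = tm$sh_mu,
      tau = tm$tau, sigma2 = tm$sh_sigma2,
      condition_effect = tm$sh_condition_effect)
  } else {
    nf_rows <- list()
    ret_rows <- list()
    ach_rows <- list()
    for (i in seq_len(nrow(plan$subjects))) {
      p <- params[[i]]
      threshold <- update_threshold(1, resting_theta = p$baseline_theta_power)
      for (s in seq_len(NF_SESSIONS)) {
        session <- plan$nf_sessions[[i]][[s]]
        record <- simulate_nf_session(p, session,
                                      seed = derive_seed(seed, i, s, 2),
                                      fs = cfg$fs,
                                      background_scale = cfg$background_scale)
        fb <- run_nf_feedback(record, session, threshold, cfg$fs)
        ach_rows[[length(ach_rows) + 1]] <-
          cbind(subject = plan$subjects$subject_id[i],
                group = plan$subjects$group[i], session = s, fb)
        if (s < NF_SESSIONS) {
          bm <- fb$mean_power[!is.na(fb$mean_power)]
          threshold <- update_threshold(s + 1,
                                        previous_session_block_means = bm)
        }
        an <- analyze_nf_record(record, session)
        nf_rows[[length(nf_rows) + 1]] <- data.frame(
          subject = plan$subjects$subject_id[i],
          group = plan$subjects$group[i], session = s,
          block = an$by_block$block, modulation = an$by_block$goal,
          y = an$by_block$db, stringsAsFactors = FALSE)
        ret_rows[[length(ret_rows) + 1]] <- data.frame(
          subject = plan$subjects$subject_id[i], session = s,
          kept_s = an$kept_s, total_s = an$total_s)
      }
    }
    nf_table <- do.call(rbind, nf_rows)
    retention <- do.call(rbind, ret_rows)
    achievement <- do.call(rbind, ach_rows)
    tm <- cfg$theta_model
    sh_theta <- simulate_cohort_sh_theta(
      cfg$n_inc, cfg$n_alt, seed = derive_seed(seed, 13), mu = tm$sh_mu,
      tau = tm$tau, sigma2 = tm$sh_sigma2,
      condition_effect = tm$sh_condition_effect)
  }
  tick("nf_table", nrow(nf_table))

  # shooting task: shared target sequence per session (individualized TETs),
  # reshuffled between sessions; behavioral metrics per subject x session x
  # condition
  beh_rows <- list()
  for (s in 1:6) {
    for (ci in 1:2) {
      cond <- c("Low", "High")[ci]
      sched_seed <- derive_seed(seed, 900, s, ci)
      for (i in seq_len(nrow(plan$subjects))) {
        p <- params[[i]]
        schedule <- generate_target_schedule(cond, p$tet50_ms, p$tet90_ms,
                                             seed = sched_seed)
        trials <- simulate_shooter(p, schedule,
                                   seed = derive_seed(seed, i, s, ci, 3))
        m <- compute_behavioral_metrics(trials)
        beh_rows[[length(beh_rows) + 1]] <- data.frame(
          subject = plan$subjects$subject_id[i],
          group = plan$subjects$group[i], session = s, condition = cond,
          commission_pct = m$commission_pct, hit_pct = m$hit_pct,
          mean_rt_ms = m$mean_rt_ms, score = score_events(trials),
          stringsAsFactors = FALSE)
      }
    }
  }
  behavior <- do.call(rbind, beh_rows)
  behavior <- behavior[order(behavior$subject, behavior$session,
                             behavior$condition), ]
  rownames(behavior) <- NULL
  tick("behavior", nrow(behavior))

  ladders <- list(
    fm_theta_nf = fit_model_ladder(nf_table,
                                   level1 = c("block", "modulation")),
    fm_theta_sh = fit_model_ladder(sh_theta, level1 = "condition"),
    commission = fit_model_ladder(
      transform(behavior, y = commission_pct), level1 = "condition"),
    accuracy = fit_model_ladder(
      transform(behavior, y = hit_pct), level1 = "condition"),
    rt = fit_model_ladder(
      transform(behavior, y = mean_rt_ms), level1 = "condition"))
  tick("stats", length(ladders))

  paths <- NULL
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      nf_table = file.path(cfg$out_dir, "nf_long_table.csv"),
      sh_theta_table = file.path(cfg$out_dir, "sh_theta_table.csv"),
      behavior_table = file.path(cfg$out_dir, "behavior_table.csv"),
      log = file.path(cfg$out_dir, "run_log.csv"))
    utils::write.csv(nf_table, paths$nf_table, row.names = FALSE)
    utils::write.csv(sh_theta, paths$sh_theta_table, row.names = FALSE)
    utils::write.csv(behavior, paths$behavior_table, row.names = FALSE)
    for (nm in names(ladders)) {
      fp <- file.path(cfg$out_dir, sprintf("model_%s_full.json", nm))
      write_model_report(ladders[[nm]]$full, fp)
      paths[[paste0("model_", nm)]] <- fp
    }
    if (!is.null(retention)) {
      paths$retention <- file.path(cfg$out_dir, "retention.csv")
      utils::write.csv(retention, paths$retention, row.names = FALSE)
    }
    logdf <- do.call(rbind, log)
    utils::write.csv(logdf, paths$log, row.names = FALSE)
  }

  structure(list(config = cfg, plan = plan, params = params,
                 nf_table = nf_table, sh_theta_table = sh_theta,
                 behavior_table = behavior, ladders = ladders,
                 retention = retention, achievement = achievement,
                 log = do.call(rbind, log), paths = paths),
            class = "study_outputs")
}

#' @export
print.study_outputs <- function(x, ...) {
  cat(sprintf("<study_outputs> engine '%s', %d subjects; NF table %d rows, behavior %d rows\n",
              x$config$engine, nrow(x$plan$subjects), nrow(x$nf_table),
              nrow(x$behavior_table)))
  full <- x$ladders$fm_theta_nf$full
  gs <- full$fixed[full$fixed$term == "session:group", ]
  if (nrow(gs)) {
    cat(sprintf("  training Group x Session: b = %.3f (SE %.3f), p = %.3g\n",
                gs$estimate, gs$se, gs$p))
  }
  invisible(x)
}
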