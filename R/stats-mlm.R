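# Numeric coding used throughout the modeling stage: Group INC = 0 / ALT = 1,
# Modulation Down = 0 / Up = 1, Condition Low = 0 / High = 1; session and
# block enter uncentered at their printed 1-based values.
code_long_table <- function(table) {
  tab <- as.data.frame(table)
  if (!all(c("subject", "y") %in% names(tab))) {
    stopf("long table needs at least columns `subject` and `y`")
  }
  recode <- function(x, zero, one, what) {
    if (is.numeric(x)) return(x)
    x <- as.character(x)
    bad <- !(x %in% c(zero, one))
    if (any(bad)) stopf("%s must be %s/%s", what, zero, one)
    as.numeric(x == one)
  }
  if ("group" %in% names(tab)) tab$group <- recode(tab$group, "INC", "ALT", "group")
  if ("modulation" %in% names(tab)) {
    tab$modulation <- recode(tab$modulation, "Down", "Up", "modulation")
  }
  if ("condition" %in% names(tab)) {
    tab$condition <- recode(tab$condition, "Low", "High", "condition")
  }
  tab$subject <- factor(tab$subject)
  tab
}

#' Specify a multilevel model
#'
#' @param outcome outcome column name (default `"y"`).
#' @param fixed character vector of fixed-effect terms (R formula syntax,
#'   e.g. `c("modulation", "block * session * group")`); empty for an
#'   intercepts-only model.
#' @param random_slope optional predictor with a per-subject random slope
#'   (e.g. `"session"`); the random intercept is always present.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(outcome = "y", fixed = character(),
                       random_slope = NULL) {
  structure(list(outcome = outcome, fixed = fixed,
                 random_slope = random_slope), class = "model_spec")
}

spec_formula <- function(spec) {
  fe <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  re <- if (is.null(spec$random_slope)) "(1 | subject)" else {
    sprintf("(1 + %s | subject)", spec$random_slope)
  }
  stats::as.formula(paste(spec$outcome, "~", fe, "+", re))
}

#' Fit a multilevel (mixed) linear model by REML
#'
#' Random-intercept (optionally random-slope) model estimated with
#' `lme4::lmer` under REML. Reporting is owned here: fixed effects with Wald-z
#' p-values (or Satterthwaite via lmerTest), variance components, ICC
#' (intercept variance over intercept + residual variance), AIC/BIC on the
#' REML criterion, and the fixed-effects pseudo R-squared (variance of the
#' fixed-effects-predicted values over the outcome variance). Singular fits
#' are flagged, with variance components floored at zero rather than refused.
#'
#' @param table long-format data.frame with columns `subject`, `y` and the
#'   predictors named in `spec` (`group`, `session`, `block`, `modulation`,
#'   `condition`); factor-like columns are recoded 0/1 (INC/ALT, Down/Up,
#'   Low/High).
#' @param spec a [model_spec()].
#' @param p_method `"wald"` (z reference) or `"satterthwaite"` (requires
#'   lmerTest).
#' @return an object of class `mlm_result`: `fixed` (data.frame estimate, se,
#'   z, p), `tau_intercept`, `tau_slope`, `sigma2`, `icc`, `aic`, `bic`,
#'   `pseudo_r2`, `converged`, `singular`, `n_obs`, `n_subjects`, and `fit`
#'   (the lmer object).
#' @export
fit_mlm <- function(table, spec = model_spec(), p_method = c("wald",
                                                             "satterthwaite")) {
  p_method <- match.arg(p_method)
  tab <- code_long_table(table)
  if (nlevels(tab$subject) < 2) stopf("need >= 2 subjects")
  form <- spec_formula(spec)
  # convergence and singularity are reported through the flags below, so
  # lme4's boundary-fit messages and optimizer warnings are captured rather
  # than emitted
  conv_notes <- character()
  fit <- withCallingHandlers(
    suppressMessages(
      if (p_method == "satterthwaite") {
        if (!requireNamespace("lmerTest", quietly = TRUE)) {
          stopf("p_method = 'satterthwaite' requires the lmerTest package")
        }
        lmerTest::lmer(form, data = tab, REML = TRUE)
      } else {
        lme4::lmer(form, data = tab, REML = TRUE)
      }),
    warning = function(w) {
      if (grepl("converge|gradient|Hessian", conditionMessage(w))) {
        conv_notes <<- c(conv_notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    })
  singular <- lme4::isSingular(fit, tol = 1e-5)
  converged <- length(fit@optinfo$conv$lme4$messages) == 0 &&
    length(conv_notes) == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  tau_int <- max(0, vc$vcov[vc$grp == "subject" & vc$var1 == "(Intercept)" &
                              is.na(vc$var2)][1])
  tau_slope <- if (!is.null(spec$random_slope)) {
    max(0, vc$vcov[vc$grp == "subject" & vc$var1 == spec$random_slope &
                     is.na(vc$var2)][1])
  } else NA_real_
  sigma2 <- vc$vcov[vc$grp == "Residual"][1]
  icc <- tau_int / (tau_int + sigma2)

  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (p_method == "satterthwaite") {
    sm <- stats::coef(summary(fit))
    p <- sm[, "Pr(>|t|)"]
    z <- sm[, "t value"]
  } else {
    z <- cf / se
    p <- 2 * stats::pnorm(-abs(z))
  }
  fixed <- data.frame(term = names(cf), estimate = unname(cf),
                      se = unname(se), z = unname(z), p = unname(p),
                      stringsAsFactors = FALSE)

  y <- tab[[spec$outcome]]
  yhat_fixed <- as.numeric(stats::model.matrix(fit) %*% cf)
  pseudo_r2 <- if (stats::var(y) > 0) stats::var(yhat_fixed) / stats::var(y) else NA_real_

  structure(list(fixed = fixed, tau_intercept = tau_int,
                 tau_slope = tau_slope, sigma2 = sigma2, icc = icc,
                 aic = stats::AIC(fit), bic = stats::BIC(fit),
                 pseudo_r2 = pseudo_r2, converged = converged,
                 singular = singular, n_obs = nrow(tab),
                 n_subjects = nlevels(tab$subject), spec = spec, fit = fit),
            class = "mlm_result")
}

#' @export
print.mlm_result <- function(x, ...) {
  cat(sprintf("<mlm_result> %d obs, %d subjects%s\n", x$n_obs, x$n_subjects,
              if (x$singular) " [singular fit]" else ""))
  cat(sprintf("  ICC = %.3f | tau_int = %.3g | sigma2 = %.3g%s\n", x$icc,
              x$tau_intercept, x$sigma2,
              if (!is.na(x$tau_slope)) sprintf(" | tau_slope = %.3g",
                                               x$tau_slope) else ""))
  cat(sprintf("  AIC = %.2f, BIC = %.2f, fixed pseudo-R2 = %.3f\n", x$aic,
              x$bic, x$pseudo_r2))
  print(x$fixed, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Intercepts-only multilevel model
#'
#' Random-intercept REML model with no predictors; the starting rung of the
#' model ladder, from which the ICC and design effect are read.
#'
#' @inheritParams fit_mlm
#' @return an `mlm_result`.
#' @export
fit_intercepts_only <- function(table, p_method = "wald") {
  fit_mlm(table, model_spec(), p_method = p_method)
}

#' Design effect of clustered sampling
#'
#' `1 + (n - 1) * ICC`: the variance inflation of cluster sampling relative
#' to independent observations. Values above 2 are conventional evidence for
#' multilevel structure. The cluster size defaults downstream to the number
#' of observations per subject (30 for the training table: 6 blocks x 5
#' sessions).
#'
#' @param icc intraclass correlation in `[0, 1]`.
#' @param n_per_cluster observations per cluster (>= 1).
#' @return the design effect (unitless).
#' @export
design_effect <- function(icc, n_per_cluster) {
  if (any(icc < 0 | icc > 1)) stopf("icc must be in [0, 1]")
  if (any(n_per_cluster < 1)) stopf("n_per_cluster must be >= 1")
  1 + (n_per_cluster - 1) * icc
}

#' Fixed-effects pseudo R-squared
#'
#' Variance of the fixed-effects-predicted values over the variance of the
#' observed outcome.
#'
#' @param result an `mlm_result`.
#' @param table the long table the model was fit to (defaults to the model
#'   frame stored in the fit).
#' @return unitless proportion.
#' @export
pseudo_r2_fixed <- function(result, table = NULL) {
  stopifnot(inherits(result, "mlm_result"))
  if (is.null(table)) return(result$pseudo_r2)
  tab <- code_long_table(table)
  y <- tab[[result$spec$outcome]]
  if (stats::var(y) <= 0) stopf("outcome has zero variance")
  X <- stats::model.matrix(stats::terms(result$fit), tab)
  yhat <- as.numeric(X %*% lme4::fixef(result$fit))
  stats::var(yhat) / stats::var(y)
}

#' Simple slopes of a cross-level interaction
#'
#' The conditional slope of the focal predictor at each level of the
#' moderator: `b(g) = beta_focal + beta_interaction * g`, with delta-method
#' standard errors from the coefficient covariance matrix.
#'
#' @param result an `mlm_result` whose model contains the focal x moderator
#'   interaction.
#' @param focal focal predictor name (e.g. `"session"`).
#' @param moderator moderator name (e.g. `"group"`).
#' @param levels numeric moderator levels at which to evaluate (default 0/1,
#'   i.e. INC/ALT under the coding convention).
#' @return data.frame with `level`, `slope`, `se`, `z`, `p`.
#' @export
simple_slopes <- function(result, focal = "session", moderator = "group",
                          levels = c(0, 1)) {
  stopifnot(inherits(result, "mlm_result"))
  cf <- lme4::fixef(result$fit)
  V <- as.matrix(stats::vcov(result$fit))
  nm <- names(cf)
  int_name <- intersect(c(paste(focal, moderator, sep = ":"),
                          paste(moderator, focal, sep = ":")), nm)
  if (!length(int_name)) {
    stopf("no %s x %s interaction in the model", focal, moderator)
  }
  if (!(focal %in% nm)) stopf("focal predictor %s not in the model", focal)
  int_name <- int_name[1]
  out <- do.call(rbind, lapply(levels, function(g) {
    b <- cf[focal] + g * cf[int_name]
    v <- V[focal, focal] + g^2 * V[int_name, int_name] +
      2 * g * V[focal, int_name]
    se <- sqrt(v)
    z <- b / se
    data.frame(level = g, slope = unname(b), se = se, z = unname(z),
               p = unname(2 * stats::pnorm(-abs(z))))
  }))
  rownames(out) <- NULL
  out
}

#' Model assumption checks
#'
#' Outlier screening on subject-level outcome means (|z| > 2 SD), skewness
#' and excess kurtosis of the outcome with +/-3 flags, variance inflation
#' factors for the fixed-effect predictors, and residual summaries for QQ /
#' homoscedasticity export.
#'
#' @param table the long table.
#' @param result an `mlm_result` fit to it.
#' @return list with `subject_means` (data.frame subject, mean, z, outlier),
#'   `skewness`, `kurtosis`, `skewness_flag`, `kurtosis_flag`, `vif` (named
#'   vector; NA for an intercepts-only model), and `residuals` (data.frame
#'   fitted, residual).
#' @export
assumption_checks <- function(table, result) {
  stopifnot(inherits(result, "mlm_result"))
  tab <- code_long_table(table)
  y <- tab[[result$spec$outcome]]

  sm <- stats::aggregate(y, list(subject = tab$subject), mean)
  names(sm)[2] <- "mean"
  sdev <- stats::sd(sm$mean)
  sm$z <- if (is.finite(sdev) && sdev > 0) (sm$mean - mean(sm$mean)) / sdev else 0
  sm$outlier <- abs(sm$z) > 2

  skew <- sample_skewness(y)
  kurt <- sample_kurtosis(y)

  X <- stats::model.matrix(stats::terms(result$fit), tab)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  vif <- if (ncol(X) >= 2) {
    R <- stats::cor(X)
    v <- diag(solve(R))
    names(v) <- colnames(X)
    v
  } else if (ncol(X) == 1) {
    stats::setNames(1, colnames(X))
  } else NA
  list(subject_means = sm, skewness = skew, kurtosis = kurt,
       skewness_flag = abs(skew) > 3, kurtosis_flag = abs(kurt) > 3,
       vif = vif,
       residuals = data.frame(fitted = stats::fitted(result$fit),
                              residual = stats::residuals(result$fit)))
}

#' Classify neurofeedback responders
#'
#' A subject is a responder if a univariate regression of their theta outcome
#' on session, or on modulation code, is significant at the two-sided alpha
#' level. Subjects with a constant outcome are non-responders.
#'
#' @param table long table with columns `subject`, `y`, `session` and
#'   (optionally) `modulation`.
#' @param alpha two-sided significance level for each univariate screen.
#' @return data.frame with `subject`, `p_session`, `p_modulation`,
#'   `responder`.
#' @export
classify_responders <- function(table, alpha = 0.05) {
  tab <- code_long_table(table)
  uni_p <- function(d, predictor) {
    if (!(predictor %in% names(d))) return(NA_real_)
    x <- d[[predictor]]
    if (stats::var(d$y) == 0 || stats::var(x) == 0) return(NA_real_)
    fit <- stats::lm(d$y ~ x)
    stats::coef(summary(fit))[2, 4]
  }
  subjects <- levels(tab$subject)
  out <- do.call(rbind, lapply(subjects, function(s) {
    d <- tab[tab$subject == s, , drop = FALSE]
    ps <- uni_p(d, "session")
    pm <- uni_p(d, "modulation")
    data.frame(subject = s, p_session = ps, p_modulation = pm,
               responder = isTRUE(ps < alpha) || isTRUE(pm < alpha),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a model result as a JSON report
#' @param result an `mlm_result`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_model_report <- function(result, path) {
  payload <- result[c("fixed", "tau_intercept", "tau_slope", "sigma2", "icc",
                      "aic", "bic", "pseudo_r2", "converged", "singular",
                      "n_obs", "n_subjects")]
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
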