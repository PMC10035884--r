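test_that("design effect has its closed form and boundary behavior", {
  expect_equal(design_effect(0, 30), 1)
  expect_equal(design_effect(1, 30), 30)
  expect_equal(design_effect(0.5, 1), 1)
  # monotone in both arguments
  expect_true(all(diff(design_effect(seq(0, 1, 0.1), 30)) > 0))
  expect_true(all(diff(design_effect(0.4, c(2, 10, 30))) > 0))
  expect_error(design_effect(1.2, 30), "icc")
  expect_error(design_effect(0.5, 0), "n_per_cluster")
})

test_that("intercepts-only model reads near-zero ICC from unclustered data", {
  set.seed(101)
  tab <- data.frame(subject = rep(1:30, each = 30), y = rnorm(900))
  m <- fit_intercepts_only(tab)
  expect_lt(m$icc, 0.05)
  expect_identical(m$n_subjects, 30L)
  expect_identical(m$n_obs, 900L)
})

test_that("ICC is invariant under affine rescaling of the outcome", {
  set.seed(11)
  u <- rnorm(20, 0, 2)
  tab <- data.frame(subject = rep(1:20, each = 15),
                    y = rep(u, each = 15) + rnorm(300))
  m1 <- fit_intercepts_only(tab)
  tab$y <- 5 * tab$y - 100
  m2 <- fit_intercepts_only(tab)
  expect_equal(m2$icc, m1$icc, tolerance = 1e-4)
})

test_that("REML components match the balanced-design method-of-moments oracle", {
  set.seed(202)
  n_sub <- 40; n_obs <- 25
  u <- rnorm(n_sub, 0, sqrt(3))
  tab <- data.frame(subject = rep(seq_len(n_sub), each = n_obs),
                    y = rep(u, each = n_obs) + rnorm(n_sub * n_obs))
  m <- fit_intercepts_only(tab)
  # one-way ANOVA estimator: sigma2 = MSW, tau = (MSB - MSW) / n
  fit <- aov(y ~ factor(subject), tab)
  ms <- summary(fit)[[1]]$`Mean Sq`
  tau_mom <- (ms[1] - ms[2]) / n_obs
  expect_lt(abs(m$sigma2 - ms[2]) / ms[2], 0.02)
  expect_lt(abs(m$tau_intercept - tau_mom) / tau_mom, 0.02)
})

test_that("random-slope fit degenerates gracefully on zero-slope-variance data", {
  set.seed(303)
  u <- rnorm(25, 0, 2)
  tab <- expand.grid(subject = 1:25, session = 1:5, rep = 1:4)
  tab$y <- 10 + u[tab$subject] + rnorm(nrow(tab))
  m_slope <- fit_mlm(tab, model_spec(random_slope = "session"))
  m_int <- fit_intercepts_only(tab)
  expect_lt(m_slope$tau_slope, 0.02)
  expect_true(m_slope$singular || m_slope$tau_slope < 0.02)
  expect_lt(abs(m_slope$fixed$estimate[1] - m_int$fixed$estimate[1]) /
              abs(m_int$fixed$estimate[1]), 0.01)
})

test_that("fixed-effects pseudo R-squared behaves at its extremes and under noise predictors", {
  set.seed(404)
  u <- rnorm(30, 0, 1.5)
  tab <- expand.grid(subject = 1:30, session = 1:5, rep = 1:6)
  tab$y <- u[tab$subject] + 0.5 * tab$session + rnorm(nrow(tab), 0, 0.8)
  m0 <- fit_intercepts_only(tab)
  expect_equal(m0$pseudo_r2, 0, tolerance = 1e-10)

  # near-deterministic fixed effect
  tab2 <- tab
  tab2$y <- 2 * tab2$session + rnorm(nrow(tab2), 0, 0.01)
  m2 <- fit_mlm(tab2, model_spec(fixed = "session"))
  expect_gt(m2$pseudo_r2, 0.99)

  # a pure-noise predictor barely moves the statistic
  m_base <- fit_mlm(tab, model_spec(fixed = "session"))
  tab$noise <- rnorm(nrow(tab))
  m_noise <- fit_mlm(tab, model_spec(fixed = c("session", "noise")))
  expect_lt(abs(m_noise$pseudo_r2 - m_base$pseudo_r2), 0.01)

  # recomputation from the table matches the stored value
  expect_equal(pseudo_r2_fixed(m_base, tab), m_base$pseudo_r2,
               tolerance = 1e-10)
})

test_that("known fixed-effects pseudo R-squared is recovered from simulation", {
  # y = b*x + e scaled for var(bx)/var(y) = 0.3
  set.seed(505)
  tab <- expand.grid(subject = 1:30, session = 1:5, rep = 1:6)
  u <- rnorm(30, 0, 0.3)
  signal <- sqrt(0.3) * scale(tab$session)[, 1]
  noise_sd <- sqrt(1 - 0.3 - 0.09)
  tab$y <- signal + u[tab$subject] + rnorm(nrow(tab), 0, noise_sd)
  m <- fit_mlm(tab, model_spec(fixed = "session"))
  expect_lt(abs(m$pseudo_r2 - 0.3), 0.05)
})

test_that("simple slopes obey the interaction algebra and factor coding", {
  tab <- simulate_cohort_fm_theta(seed = 606)
  m <- fit_mlm(tab, model_spec(fixed = c("modulation", "block",
                                         "session * group"),
                               random_slope = "session"))
  ss <- simple_slopes(m, "session", "group")
  b <- m$fixed
  b_s <- b$estimate[b$term == "session"]
  b_int <- b$estimate[b$term == "session:group"]
  expect_equal(ss$slope[ss$level == 0], b_s, tolerance = 1e-12)
  expect_equal(ss$slope[ss$level == 1] - ss$slope[ss$level == 0], b_int,
               tolerance = 1e-12)
  expect_error(simple_slopes(m, "block", "group"), "interaction")

  # zero interaction -> identical slopes at both levels
  set.seed(607)
  tab0 <- expand.grid(subject = 1:20, session = 1:5, rep = 1:4)
  tab0$group <- rep(c(0, 1), length.out = 20)[tab0$subject]
  u <- rnorm(20)
  tab0$y <- u[tab0$subject] + 0.4 * tab0$session + rnorm(nrow(tab0))
  m0 <- fit_mlm(tab0, model_spec(fixed = "session * group"))
  b0 <- m0$fixed$estimate[m0$fixed$term == "session:group"]
  ss0 <- simple_slopes(m0, "session", "group")
  expect_equal(diff(ss0$slope), b0, tolerance = 1e-12)
})

test_that("group-specific slopes are recovered within 2 SE in >= 93% of replicates", {
  hits <- vapply(1:100, function(r) {
    set.seed(derive_seed(3000, r))
    d <- expand.grid(subject = 1:30, session = 1:5, rep = 1:6)
    g <- c(rep(0, 12), rep(1, 18))
    d$group <- g[d$subject]
    u <- rnorm(30, 0, sqrt(3))
    d$y <- u[d$subject] + 0.4 * d$session * d$group + rnorm(nrow(d))
    fit <- fit_mlm(d, model_spec(fixed = "session * group"))
    gs <- fit$fixed[fit$fixed$term == "session:group", ]
    abs(gs$estimate - 0.4) < 2 * gs$se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("assumption checks flag outliers, moments and collinearity as specified", {
  set.seed(707)
  tab <- simulate_cohort_fm_theta(n_inc = 6, n_alt = 9, seed = 707)
  m <- fit_mlm(tab, model_spec(fixed = c("session", "block")))
  chk <- assumption_checks(tab, m)
  expect_false(chk$skewness_flag)
  expect_false(chk$kurtosis_flag)
  # session and block are crossed -> orthogonal -> VIF 1
  expect_true(all(abs(chk$vif - 1) < 1e-8))
  expect_identical(nrow(chk$residuals), nrow(tab))

  # a subject sitting 3 SD out is flagged
  tab2 <- tab
  mu <- aggregate(y ~ subject, tab2, mean)
  shift <- mean(mu$y) + 3 * sd(mu$y) - mu$y[1]
  tab2$y[tab2$subject == mu$subject[1]] <-
    tab2$y[tab2$subject == mu$subject[1]] + shift
  m2 <- fit_mlm(tab2, model_spec(fixed = "session"))
  chk2 <- assumption_checks(tab2, m2)
  expect_true(chk2$subject_means$outlier[chk2$subject_means$subject ==
                                           mu$subject[1]])
})

test_that("responder classification matches its univariate screens", {
  set.seed(808)
  # strong session slope -> responder; modulation-locked -> responder
  strong <- data.frame(subject = "A", session = rep(1:5, each = 6),
                       modulation = "Up",
                       y = rep(1:5, each = 6) + rnorm(30, 0, 0.1))
  modlock <- data.frame(subject = "B", session = rep(1:5, each = 6),
                        modulation = rep(c("Up", "Down"), 15),
                        y = 3 * rep(c(1, 0), 15) + rnorm(30, 0, 0.1))
  flat <- data.frame(subject = "C", session = rep(1:5, each = 6),
                     modulation = rep(c("Up", "Down"), 15), y = 1)
  tab <- rbind(strong, modlock, flat)
  res <- classify_responders(tab)
  expect_true(res$responder[res$subject == "A"])
  expect_true(res$responder[res$subject == "B"])
  expect_false(res$responder[res$subject == "C"])

  # under pure noise the responder fraction stays near the union type-I level
  noise <- do.call(rbind, lapply(1:100, function(i) {
    data.frame(subject = sprintf("N%03d", i), session = rep(1:5, each = 6),
               modulation = rep(c("Up", "Down"), 15), y = rnorm(30))
  }))
  resn <- classify_responders(noise)
  expect_lte(mean(resn$responder), 0.12)
})

test_that("model reports serialize to JSON", {
  tab <- simulate_cohort_fm_theta(n_inc = 4, n_alt = 4, seed = 9)
  m <- fit_mlm(tab, model_spec(fixed = "session"))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_report(m, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$icc, m$icc, tolerance = 1e-12)
  expect_identical(nrow(back$fixed), nrow(m$fixed))
})
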