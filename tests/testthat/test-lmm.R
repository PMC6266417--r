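test_that("the scaled design row matches direct arithmetic", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 6),
                  cycle_day = rep(c(2, 7, 14, 20, 25, 28), 2),
                  Y = rnorm(12))
  des <- build_design(d, "Y")
  row <- des$X[d$cycle_day == 14, ][1, ]
  ts <- (14 - 14.5) / 13.5
  expect_equal(unname(row), ts^(0:4), tolerance = 1e-12)
  expect_equal(unname(row), c(1, -0.037037, 0.00137174, -5.0805e-05, 1.88167e-06),
               tolerance = 1e-4)
})

test_that("a single-day design is rejected as rank deficient", {
  d <- data.frame(subject_id = rep(c("a", "b"), each = 3),
                  cycle_day = 14, Y = rnorm(6))
  expect_error(build_design(d, "Y"), "distinct days")
})

test_that("raw-scale coefficients reproduce the fitted values exactly", {
  d <- null_study(31)
  fit <- fit_reml(build_design(d, "Y"))
  des <- fit$design
  fitted_scaled <- as.numeric(des$X %*% fit$beta)
  fitted_raw <- as.numeric(outer(des$t_raw, 0:4, `^`) %*% fit$beta_raw)
  expect_equal(fitted_raw, fitted_scaled, tolerance = 1e-9)
})

test_that("an exact quartic is interpolated to at least 6 significant digits", {
  beta_true <- c(2, -0.5, 0.03, -0.001, 1.5e-5)  # raw day scale
  d <- expand.grid(subject_id = sprintf("S%d", 1:4),
                   cycle_day = c(1, 4, 8, 11, 15, 18, 22, 25, 28))
  d$Y <- as.numeric(outer(d$cycle_day, 0:4, `^`) %*% beta_true)
  fit <- fit_reml(build_design(d, "Y", re_orders = integer(0)))
  expect_equal(fit$beta_raw, beta_true, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_lt(fit$sigma2_resid / stats::var(d$Y), 1e-8)
})

test_that("with no random effects the fit equals pooled OLS to 8+ digits", {
  d <- null_study(33)
  fit <- fit_reml(build_design(d, "Y", re_orders = integer(0)))
  ts <- (d$cycle_day - 14.5) / 13.5
  ols <- stats::lm(d$Y ~ ts + I(ts^2) + I(ts^3) + I(ts^4))
  expect_equal(unname(fit$beta), unname(stats::coef(ols)), tolerance = 1e-9)
})

test_that("REML on a balanced one-way layout equals the ANOVA closed form", {
  set.seed(41)
  a <- 8; m <- 6
  b <- rnorm(a, 0, 2)
  d <- data.frame(subject_id = rep(sprintf("S%d", 1:a), each = m),
                  cycle_day = rep(seq(2, 27, length.out = m), a))
  d$Y <- 20 + b[rep(1:a, each = m)] + rnorm(a * m, 0, 0.7)
  fit <- fit_reml(build_design(d, "Y", fixed_orders = 0, re_orders = 0))
  fm <- stats::aov(Y ~ Error(factor(subject_id)), data = d)
  msb <- summary(fm)[[1]][[1]]["Residuals", "Mean Sq"]
  msw <- summary(fm)[[2]][[1]]["Residuals", "Mean Sq"]
  expect_equal(unname(fit$varcomp["sigma2_b0"]), (msb - msw) / m,
               tolerance = 1e-5)
  expect_equal(fit$sigma2_resid, msw, tolerance = 1e-5)
})

test_that("the REML optimum is a local maximum of the restricted likelihood", {
  d <- null_study(35)
  des <- build_design(d, "Y")
  fit <- fit_reml(des)
  stats_list <- cyclemetrics:::subject_stats(des)
  re_idx <- match(des$re_orders, des$fixed_orders)
  th_hat <- log(c(fit$varcomp, fit$sigma2_resid))
  m2l_hat <- cyclemetrics:::reml_pieces(th_hat, stats_list, re_idx,
                                        ncol(des$X))$m2l
  set.seed(99)
  for (k in 1:20) {
    th <- th_hat + rnorm(length(th_hat), 0, 0.35)
    m2l <- cyclemetrics:::reml_pieces(th, stats_list, re_idx, ncol(des$X))$m2l
    expect_gte(m2l, m2l_hat - 1e-6)
  }
})

test_that("the fit agrees with an independent REML implementation (lme4)", {
  library(lme4)
  set.seed(19)
  d <- null_study(45, subject_sd = 2, noise_cv = 0)
  ts <- (d$cycle_day - 14.5) / 13.5
  d$Y <- d$Y + 1.2 * ts + 0.8 * ts^2 + rnorm(nrow(d), 0, 0.5)
  fit <- fit_reml(build_design(d, "Y"))
  d$ts <- ts; d$ts2 <- ts^2; d$ts3 <- ts^3; d$ts4 <- ts^4
  ref <- lmer(Y ~ ts + ts2 + ts3 + ts4 + (1 | subject_id) +
                (0 + ts | subject_id) + (0 + ts2 | subject_id) +
                (0 + ts3 | subject_id) + (0 + ts4 | subject_id),
              data = d, REML = TRUE,
              control = lmerControl(check.conv.singular = "ignore"))
  expect_equal(unname(fit$beta), unname(fixef(ref)), tolerance = 1e-4)
  expect_equal(-2 * fit$logLik_REML, REMLcrit(ref), tolerance = 1e-4)
  expect_equal(unname(sqrt(diag(fit$cov_beta))),
               unname(sqrt(diag(as.matrix(vcov(ref))))), tolerance = 1e-3)
})

test_that("constant data give a numerically null combined test", {
  d <- data.frame(subject_id = rep(sprintf("S%d", 1:5), each = 8),
                  cycle_day = rep(c(1, 5, 9, 13, 17, 21, 25, 28), 5),
                  Y = 7.5)
  res <- fit_cycle_lmm(d, "Y")
  expect_lt(res$test$F, 1e-6)
  expect_equal(res$test$verdict, "constant-model")
  expect_equal(res$test$df1, 4)
  expect_equal(res$test$df2, nrow(d) - 5)
})

test_that("the verdict switches exactly at the significance level", {
  d <- null_study(61, cycle = cycle_linear(0.3))
  res <- fit_cycle_lmm(d, "Y")
  expect_identical(res$test$verdict,
                   if (res$test$p_value <= 0.05) "time-dependent" else "constant-model")
  expect_true(res$test$p_value >= 0 && res$test$p_value <= 1)
  expect_equal(nrow(res$test$coefficients), 5)
})

test_that("outcome rescaling scales coefficients but not F, p or deviation %", {
  d <- null_study(55, cycle = cycle_linear(0.05))
  d2 <- d; d2$Y <- d2$Y * 1000
  r1 <- fit_cycle_lmm(d, "Y"); r2 <- fit_cycle_lmm(d2, "Y")
  expect_equal(unname(r2$fit$beta_raw), unname(r1$fit$beta_raw) * 1000,
               tolerance = 1e-5)
  expect_equal(r2$test$F, r1$test$F, tolerance = 1e-5)
  expect_equal(r2$test$p_value, r1$test$p_value, tolerance = 1e-5)
  dv1 <- deviation_stats(d, "Y"); dv2 <- deviation_stats(d2, "Y")
  expect_equal(dv2$mean_pct, dv1$mean_pct, tolerance = 1e-9)
  expect_equal(dv2$max_pct, dv1$max_pct, tolerance = 1e-9)
})

test_that("fixed effects are recovered within Monte-Carlo error at stress scale", {
  beta_sc <- c(50, 1, -0.5, 0.3, 0.2)  # scaled-basis truth
  ests <- matrix(NA_real_, 30, 5)
  for (r in 1:30) {
    d <- null_study(70000 + r, n_subjects = 100, sessions = c(13, 13),
                    subject_sd = 1, noise_cv = 0)
    ts <- (d$cycle_day - 14.5) / 13.5
    d$Y <- d$Y - 50 + as.numeric(cbind(1, ts, ts^2, ts^3, ts^4) %*% beta_sc) +
      with_seed_rnorm(80000 + r, nrow(d), 0.5)
    ests[r, ] <- fit_reml(build_design(d, "Y"))$beta
  }
  bias <- colMeans(ests) - beta_sc
  mcse <- apply(ests, 2, stats::sd) / sqrt(nrow(ests))
  expect_true(all(abs(bias) <= 2 * mcse + 1e-8))
})
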