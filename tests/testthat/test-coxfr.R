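test_that("fixed-effects engine matches an independent Cox implementation", {
  f <- Surv(time, event) ~ antagonism + concordance
  for (mode in c("continuous", "discrete")) {
    d <- simulate_study(sim_config(seed = 21, n_lines = 25,
                                   lineages_per_line = 10,
                                   time_mode = mode))
    for (ties in c("efron", "breslow")) {
      m1 <- coxfr(f, d$records_cov, ties = ties)
      m2 <- survival::coxph(f, d$records_cov, ties = ties)
      expect_equal(coef(m1), coef(m2), tolerance = 1e-6)
      expect_equal(m1$se, sqrt(diag(vcov(m2))),
                   tolerance = 1e-8, ignore_attr = TRUE)
      expect_equal(m1$loglik[["partial"]], m2$loglik[2],
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(m1$loglik[["null"]], m2$loglik[1],
                   tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("mixed fit with frailty variance fixed at zero equals the standard Cox fit", {
  d <- simulate_study(sim_config(seed = 22, n_lines = 20,
                                 lineages_per_line = 10))
  f <- Surv(time, event) ~ antagonism + concordance
  m0 <- coxfr(f, d$records_cov, random = ~ 1 | line_id, sigma2 = 0)
  m2 <- survival::coxph(f, d$records_cov, ties = "efron")
  expect_equal(coef(m0), coef(m2), tolerance = 1e-6)
  expect_equal(m0$frailty$variance, 0)
  expect_true(all(ranef(m0) == 0))
})

test_that("engine agrees with a brute-force partial likelihood on a toy set with ties", {
  d <- toy6()
  for (ties in c("efron", "breslow")) {
    fit <- coxfr(Surv(time, event) ~ x, d, ties = ties)
    oracle <- naive_cox_fit(d$time, d$event, cbind(d$x), ties = ties)
    expect_equal(unname(coef(fit)), oracle$coef, tolerance = 1e-6)
    expect_equal(fit$loglik[["partial"]],
                 naive_cox_loglik(coef(fit), d$time, d$event, cbind(d$x),
                                  ties = ties),
                 tolerance = 1e-10)
  }
})

test_that("a high-risk group gets a positive coefficient", {
  set.seed(4)
  d <- data.frame(time = c(rexp(50, 2), rexp(50, 0.2)),
                  group = rep(1:0, each = 50))
  d$event <- d$time <= 5
  d$time <- pmin(d$time, 5)
  fit <- coxfr(Surv(time, event) ~ group, d)
  expect_gt(coef(fit)[["group"]], 0)
})

test_that("rescaling a covariate rescales its coefficient exactly", {
  d <- simulate_study(sim_config(seed = 23, n_lines = 20,
                                 lineages_per_line = 10))
  rc <- d$records_cov
  f <- Surv(time, event) ~ antagonism + concordance
  m1 <- coxfr(f, rc)
  rc$antagonism <- rc$antagonism * 10
  m2 <- coxfr(f, rc)
  expect_equal(coef(m2)[["antagonism"]], coef(m1)[["antagonism"]] / 10,
               tolerance = 1e-7)
  expect_equal(coef(m2)[["concordance"]], coef(m1)[["concordance"]],
               tolerance = 1e-7)
})

test_that("rotated and unrotated parameterizations give the same fit, coefficients mapped by the inverse rotation", {
  d <- simulate_study(sim_config(seed = 24))
  rc <- d$records_cov
  m_ac <- coxfr(Surv(time, event) ~ antagonism + concordance, rc)
  m_mf <- coxfr(Surv(time, event) ~ male_std + female_std, rc)
  expect_equal(m_ac$loglik[["partial"]], m_mf$loglik[["partial"]],
               tolerance = 1e-9)
  ba <- coef(m_ac)[["antagonism"]]; bc <- coef(m_ac)[["concordance"]]
  expect_equal(coef(m_mf)[["male_std"]], (ba + bc) / sqrt(2),
               tolerance = 1e-6)
  expect_equal(coef(m_mf)[["female_std"]], (bc - ba) / sqrt(2),
               tolerance = 1e-6)
  # same equivalence holds for the frailty fits
  fr_ac <- coxfr(Surv(time, event) ~ antagonism + concordance, rc,
                 random = ~ 1 | line_id)
  fr_mf <- coxfr(Surv(time, event) ~ male_std + female_std, rc,
                 random = ~ 1 | line_id)
  expect_equal(fr_ac$frailty$variance, fr_mf$frailty$variance,
               tolerance = 1e-3)
  expect_equal(coef(fr_mf)[["female_std"]],
               (coef(fr_ac)[["concordance"]] - coef(fr_ac)[["antagonism"]]) / sqrt(2),
               tolerance = 1e-4)
})

test_that("a covariate unrelated to the hazard recovers zero on average", {
  coefs <- vapply(1:200, function(i) {
    d <- simulate_study(sim_config(seed = 600 + i, n_lines = 15,
                                   lineages_per_line = 8,
                                   beta_antagonism = 0,
                                   beta_concordance = 0,
                                   frailty_variance = 0.1))
    fit <- suppressWarnings(  # small designs hit the variance boundary
      coxfr(Surv(time, event) ~ antagonism, d$records_cov,
            random = ~ 1 | line_id))
    coef(fit)[["antagonism"]]
  }, numeric(1))
  se <- sd(coefs) / sqrt(length(coefs))
  expect_lt(abs(mean(coefs)), 3.5 * se + 0.01)
})

test_that("frailty variance collapses to the boundary when lines are homogeneous", {
  d <- simulate_study(sim_config(seed = 25, frailty_variance = 0,
                                 beta_antagonism = 0, beta_concordance = 0))
  fit <- suppressWarnings(
    coxfr(Surv(time, event) ~ antagonism, d$records_cov,
          random = ~ 1 | line_id))
  expect_lt(fit$frailty$variance, 0.05)
})

test_that("null frailty model recovers the ranking of planted line effects", {
  d <- simulate_study(sim_config(seed = 26, frailty_variance = 0.5,
                                 beta_antagonism = 0, beta_concordance = 0))
  risk <- line_extinction_risk(d$records)
  expect_equal(names(risk), names(d$frailties))
  expect_lt(abs(mean(risk)), 0.05)
  expect_gt(cor(risk, d$frailties, method = "spearman"), 0.7)
})

test_that("degenerate and invalid inputs are rejected informatively", {
  d <- simulate_study(sim_config(seed = 27, n_lines = 10,
                                 lineages_per_line = 5))
  rc <- d$records_cov
  rc0 <- rc; rc0$event <- FALSE
  expect_error(coxfr(Surv(time, event) ~ antagonism, rc0), "no events")
  rc2 <- rc; rc2$dup <- 2 * rc2$antagonism
  expect_error(coxfr(Surv(time, event) ~ antagonism + dup, rc2),
               "collinear.*dup")
  expect_error(coxfr(Surv(time, event) ~ antagonism, rc,
                     random = ~ 1 + antagonism | line_id), "random")
})

test_that("log-likelihood bookkeeping: df counts the estimated frailty variance and AIC follows", {
  d <- simulate_study(sim_config(seed = 28, n_lines = 15,
                                 lineages_per_line = 10))
  fit <- coxfr(Surv(time, event) ~ antagonism + concordance, d$records_cov,
               random = ~ 1 | line_id)
  ll <- logLik(fit)
  expect_equal(attr(ll, "df"), 3)  # 2 fixed + 1 variance
  expect_equal(AIC(fit), -2 * as.numeric(ll) + 2 * 3)
  fix <- coxfr(Surv(time, event) ~ antagonism + concordance, d$records_cov)
  expect_equal(attr(logLik(fix), "df"), 2)
})
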