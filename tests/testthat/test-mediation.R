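mk_est <- function(beta, se, method = "ivw", n = 10)
  mr_estimate(method, n, beta, se)

test_that("two-step effects combine alpha, beta2 and the total effect", {
  res <- two_step_effects(mk_est(0.12, 0.05), mk_est(log(0.622), 0.2),
                          mk_est(-0.887, 0.327))
  expect_equal(res$indirect_two_step, 0.12 * log(0.622), tolerance = 1e-12)
  expect_equal(res$proportion_two_step, 0.064, tolerance = 0.01)
  expect_equal(res$label, "mediation")
  # proportion times total recovers the indirect effect exactly
  expect_equal(res$proportion_two_step * res$total, res$indirect_two_step)
  # a zero alpha kills the indirect path
  res0 <- two_step_effects(mk_est(0, 0.05), mk_est(0.5, 0.2),
                           mk_est(-0.887, 0.327))
  expect_equal(res0$indirect_two_step, 0)
  expect_equal(res0$proportion_two_step, 0)
  expect_equal(res0$label, "none")
  expect_error(two_step_effects(mk_est(0.1, 0.05), mk_est(0.5, 0.2),
                                mk_est(0, 0.3)), "total")
})

test_that("the delta-method SE of the product matches Monte Carlo", {
  set.seed(3)
  a <- 0.4; sa <- 0.05; b <- -0.6; sb <- 0.08
  res <- two_step_effects(mk_est(a, sa), mk_est(b, sb), mk_est(-0.9, 0.3))
  draws <- rnorm(1e5, a, sa) * rnorm(1e5, b, sb)
  expect_lt(abs(res$indirect_se - sd(draws)) / sd(draws), 0.10)
})

test_that("effects are classified by sign agreement with the total", {
  expect_equal(classify_effect(-0.057, -0.887), "mediation")
  expect_equal(classify_effect(-0.1, 0.788), "suppression")
  expect_equal(classify_effect(0, 0.5), "none")
})

test_that("MVMR equals the two-regressor WLS oracle and nests univariable IVW", {
  set.seed(12)
  n <- 8
  X <- cbind(exposure = rnorm(n, 0.3, 0.1), mediator = rnorm(n, 0.2, 0.15))
  se_out <- runif(n, 0.05, 0.15)
  y <- 0.3 * X[, 1] + 0.5 * X[, 2] + rnorm(n, 0, se_out)
  fit <- mvmr_fit(X, y, se_out)
  or <- oracle_wls(X, y, 1 / se_out^2)
  expect_equal(fit$coefficients$beta, or$coef, tolerance = 1e-10)
  sigma2 <- sum((1 / se_out^2) * or$residuals^2) / (n - 2)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(or$cov_unscaled))) * max(1, sqrt(sigma2)),
               tolerance = 1e-10)
  # a silent mediator column reduces to the univariable IVW slope
  X0 <- X
  X0[, 2] <- 0
  h <- harmonized_set(paste0("rs", 1:n), X[, 1], rep(0.01, n), y, se_out)
  fit0 <- mvmr_fit(X0, h$beta_out[match(paste0("rs", 1:n), h$snp_id)],
                   h$se_out[match(paste0("rs", 1:n), h$snp_id)])
  expect_equal(fit0$coefficients$beta[1], mr_ivw(h)$beta, tolerance = 1e-10)
  expect_equal(fit0$coefficients$beta[2], 0)
  # duplicated columns are truly collinear
  expect_error(mvmr_fit(cbind(X[, 1], X[, 1]), y, se_out), "collinear")
  expect_error(mvmr_fit(X[1:2, ], y[1:2], se_out[1:2]), "too few")
})

test_that("mediation_summary recovers the generator's causal chain", {
  cfg <- sim_config(n_snp = 30, causal_alpha = 0.4, causal_beta2 = 0.5,
                    causal_direct = 0.3, gamma_sd = 0.15, seed = 31)
  sim <- simulate_mediation_dataset(cfg)
  expect_equal(sim$truth$proportion_mediated, 0.4)
  res <- mediation_summary(sim$exposure, sim$mediator, sim$outcome, sim$ld)
  expect_s3_class(res, "mediation_result")
  # single-replicate estimates are noisy; check they are in the right region
  expect_lt(abs(res$alpha - 0.4), 0.1)
  expect_lt(abs(res$beta2 - 0.5), 0.3)
  expect_equal(res$label, "mediation")
  expect_true(is.finite(res$direct_mvmr))
  expect_equal(res$indirect_mvmr, res$total - res$direct_mvmr)
})

test_that("a suppression construction is labelled suppression", {
  cfg <- sim_config(n_snp = 40, causal_alpha = 0.4, causal_beta2 = -0.5,
                    causal_direct = 0.5, gamma_sd = 0.15, seed = 33)
  sim <- simulate_mediation_dataset(cfg)
  expect_equal(sim$config$causal_total, 0.3)
  res <- mediation_summary(sim$exposure, sim$mediator, sim$outcome, sim$ld)
  expect_s3_class(res, "mediation_result")
  expect_equal(res$label, "suppression")
  expect_lt(res$indirect_two_step, 0)
  expect_gt(res$total, 0)
})

test_that("a mediator independent of the exposure is handled without crashing", {
  cfg <- sim_config(n_snp = 30, causal_alpha = 0, causal_beta2 = 0.5,
                    causal_direct = 0.4, gamma_sd = 0.15, seed = 35)
  sim <- simulate_mediation_dataset(cfg)
  res <- mediation_summary(sim$exposure, sim$mediator, sim$outcome, sim$ld)
  if (inherits(res, "mediation_result")) {
    expect_lt(abs(res$proportion_two_step), 0.15)
  } else {
    expect_s3_class(res, "mediation_skip")
    expect_match(res$reason, "no instruments")
  }
})

test_that("a missing stage yields a structured skip", {
  cfg <- sim_config(n_snp = 10, seed = 37)
  sim <- simulate_summary_dataset(cfg)
  # an exposure with no genome-wide-suggestive SNPs cannot be instrumented
  weak <- as.data.frame(sim$exposure)
  weak$pval <- pmax(weak$pval, 0.5)
  weak_tab <- gwas_table(weak, "weak_exposure", "quantitative")
  res <- mediation_summary(weak_tab, sim$mediator, sim$outcome, sim$ld)
  expect_s3_class(res, "mediation_skip")
  expect_match(res$reason, "exposure -> mediator")
})

test_that("the mediator screen applies the two-stage significance funnel", {
  cfg <- sim_config(n_snp = 25, causal_alpha = 0.4, causal_beta2 = 0.5,
                    causal_direct = 0.3, gamma_sd = 0.15, seed = 39)
  sim <- simulate_mediation_dataset(cfg)
  # a null mediator: independent of both exposure and outcome
  null_cfg <- sim_config(n_snp = 25, causal_alpha = 0, causal_beta2 = 0,
                         causal_direct = 0.3, gamma_sd = 0.15, seed = 40)
  null_sim <- simulate_mediation_dataset(null_cfg)
  scr <- screen_mediators(sim$exposure,
                          list(real = sim$mediator,
                               null = null_sim$mediator),
                          sim$outcome, sim$ld)
  expect_equal(nrow(scr$screen), 2)
  expect_true(scr$screen$kept[scr$screen$mediator == "real"])
  expect_false(scr$screen$kept[scr$screen$mediator == "null"])
  expect_named(scr$results, "real")
})
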