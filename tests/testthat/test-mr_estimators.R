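test_that("the Wald ratio is the outcome-to-exposure effect ratio", {
  est <- mr_wald_ratio(0.5, 0.05, 0.25, 0.1)
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  expect_equal(est$method, "wald")
  null <- mr_wald_ratio(0.5, 0.05, 0, 0.1)
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)
  expect_error(mr_wald_ratio(0, 0.05, 0.25, 0.1), "undefined ratio")
})

test_that("the delta-method Wald SE matches a Monte-Carlo ratio distribution", {
  set.seed(7)
  bx <- 0.5; sx <- 0.04; by <- 0.25; sy <- 0.1  # |bx/sx| = 12.5, strong
  draws <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  est <- mr_wald_ratio(bx, sx, by, sy)
  expect_lt(abs(est$se - sd(draws)) / sd(draws), 0.10)
})

test_that("IVW reduces to the Wald ratio for one SNP and is exact for equal ratios", {
  h1 <- harmonized_set("rs1", 0.5, 0.05, 0.25, 0.1)
  est1 <- mr_ivw(h1)
  wald <- mr_wald_ratio(0.5, 0.05, 0.25, 0.1)
  expect_equal(est1$beta, wald$beta)
  expect_equal(est1$se, wald$se)
  # five SNPs with identical per-SNP ratios 0.5: no residual inflation
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h5 <- harmonized_set(paste0("rs", 1:5), bx, rep(0.01, 5), 0.5 * bx,
                       rep(0.1, 5))
  est5 <- mr_ivw(h5)
  expect_equal(est5$beta, 0.5, tolerance = 1e-12)
  fixed_se <- 1 / sqrt(sum(bx^2 / 0.1^2))
  expect_equal(est5$se, fixed_se, tolerance = 1e-12)
  expect_error(mr_ivw(harmonized_set(paste0("rs", 1:3), rep(0, 3),
                                     rep(0.01, 3), rep(0.1, 3), rep(0.1, 3))),
               "no instrument signal")
})

test_that("IVW equals the closed-form WLS oracle through the origin", {
  h <- toy_harmonized(5, beta_true = 0.4, seed = 2)
  est <- mr_ivw(h)
  w <- 1 / h$se_out^2
  or <- oracle_wls(matrix(h$beta_exp, ncol = 1), h$beta_out, w)
  expect_equal(est$beta, or$coef, tolerance = 1e-10)
  sigma2 <- sum(w * or$residuals^2) / (nrow(h) - 1)
  se_expected <- sqrt(or$cov_unscaled[1, 1]) * max(1, sqrt(sigma2))
  expect_equal(est$se, se_expected, tolerance = 1e-10)
})

test_that("rescaling all outcome SEs leaves the IVW point estimate unchanged", {
  h <- toy_harmonized(8, beta_true = 0.3, seed = 4)
  h2 <- h
  h2$se_out <- h$se_out * 10
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(h2, random = FALSE)$se,
               10 * mr_ivw(h, random = FALSE)$se, tolerance = 1e-12)
})

test_that("the weighted median interpolates the ratio at half the weight", {
  h <- harmonized_set(paste0("rs", 1:3), rep(1, 3), rep(0.01, 3),
                      c(0.1, 0.5, 0.9), rep(0.1, 3))
  est <- mr_weighted_median(h, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.5)
  # with equal weights it equals the ordinary interpolated median
  set.seed(8)
  ratios <- rnorm(9)
  h9 <- harmonized_set(paste0("rs", 1:9), rep(1, 9), rep(0.01, 9), ratios,
                       rep(0.1, 9))
  expect_equal(mr_weighted_median(h9, n_boot = 100, seed = 1)$beta,
               oracle_weighted_median(ratios, rep(1, 9)))
})

test_that("weighted-median point estimates match the brute-force oracle", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 7
    bx <- rnorm(n, 0.3, 0.1)
    bx[bx == 0] <- 0.1
    so <- runif(n, 0.05, 0.2)
    by <- rnorm(n, 0.4 * bx, so)
    h <- harmonized_set(paste0("rs", 1:n), bx, rep(0.01, n), by, so)
    est <- mr_weighted_median(h, n_boot = 100, seed = seed)
    expect_equal(est$beta,
                 oracle_weighted_median(by / bx, bx^2 / so^2),
                 tolerance = 1e-12)
  }
})

test_that("the weighted median resists a minority of invalid instruments", {
  set.seed(11)
  n_valid <- 14; n_out <- 6
  bx <- runif(n_valid + n_out, 0.2, 0.4)
  ratio <- c(rep(0.5, n_valid), rep(3.0, n_out))
  by <- ratio * bx + rnorm(n_valid + n_out, 0, 0.01)
  h <- harmonized_set(paste0("rs", seq_along(bx)), bx,
                      rep(0.005, length(bx)), by, rep(0.02, length(bx)))
  est <- mr_weighted_median(h, n_boot = 200, seed = 3)
  expect_lt(abs(est$beta - 0.5), 0.05)
})

test_that("zero-exposure SNPs are excluded from the weighted median with warning", {
  h <- harmonized_set(paste0("rs", 1:4), c(0.3, 0, 0.2, 0.25),
                      rep(0.01, 4), c(0.15, 0.1, 0.1, 0.12), rep(0.05, 4))
  expect_warning(est <- mr_weighted_median(h, n_boot = 100, seed = 1),
                 "zero exposure effect")
  expect_equal(est$n_snp, 3L)
  h2 <- harmonized_set(paste0("rs", 1:3), c(0.3, 0, 0.2), rep(0.01, 3),
                       c(0.15, 0.1, 0.1), rep(0.05, 3))
  expect_warning(expect_error(mr_weighted_median(h2), "at least 3"))
})

test_that("MR-Egger recovers exact linear data and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  h <- harmonized_set(paste0("rs", 1:6), bx, rep(0.01, 6),
                      0.1 + 0.4 * bx, rep(0.1, 6))
  eg <- mr_egger(h)
  expect_equal(eg$intercept$beta, 0.1, tolerance = 1e-10)
  expect_equal(eg$slope$beta, 0.4, tolerance = 1e-10)
  # noisy instance against the two-parameter normal-equations oracle
  h2 <- toy_harmonized(6, beta_true = 0.4, seed = 6)
  eg2 <- mr_egger(h2)
  flip <- sign(h2$beta_exp)
  X <- cbind(1, h2$beta_exp * flip)
  w <- 1 / h2$se_out^2
  or <- oracle_wls(X, h2$beta_out * flip, w)
  expect_equal(eg2$intercept$beta, or$coef[1], tolerance = 1e-10)
  expect_equal(eg2$slope$beta, or$coef[2], tolerance = 1e-10)
  sigma2 <- sum(w * or$residuals^2) / (6 - 2)
  expect_equal(eg2$slope$se,
               sqrt(or$cov_unscaled[2, 2]) * max(1, sqrt(sigma2)),
               tolerance = 1e-10)
  # t-based two-sided p-values with n - 2 degrees of freedom
  expect_equal(eg2$slope$pval,
               2 * pt(-abs(eg2$slope$beta / eg2$slope$se), 4),
               tolerance = 1e-12)
  expect_error(mr_egger(toy_harmonized(2)), "at least 3")
})

test_that("Egger orientation makes the fit invariant to allele re-coding", {
  h <- toy_harmonized(8, beta_true = 0.3, seed = 9)
  h2 <- h
  flip <- c(1, -1, 1, -1, 1, -1, 1, -1)
  h2$beta_exp <- h$beta_exp * flip
  h2$beta_out <- h$beta_out * flip
  e1 <- mr_egger(h)
  e2 <- mr_egger(h2)
  expect_equal(e2$slope$beta, e1$slope$beta, tolerance = 1e-12)
  expect_equal(e2$intercept$beta, e1$intercept$beta, tolerance = 1e-12)
})

test_that("odds-ratio transformation reproduces reported report rows", {
  r <- to_odds_ratio(-2.521, 0.581)
  expect_equal(r$or, 0.080, tolerance = 0.02)
  expect_equal(r$ci_low, 0.026, tolerance = 0.02)
  expect_equal(r$ci_high, 0.251, tolerance = 0.02)
  expect_equal(r$pval, 1.42e-5, tolerance = 0.02)
  expect_equal(to_odds_ratio(0.964, 0.441)$or, 2.622, tolerance = 1e-3)
  null <- to_odds_ratio(0, 0.3)
  expect_equal(null$or, 1)
  expect_equal(null$pval, 1)
  # exp/log round trip
  expect_equal(log(to_odds_ratio(0.123456789, 0.05)$or), 0.123456789,
               tolerance = 1e-12)
})

test_that("estimate_from_summary applies the method's inference convention", {
  ivw <- estimate_from_summary("ivw", 10, -2.521, 0.581)
  expect_equal(ivw$pval, 2 * pnorm(-abs(-2.521 / 0.581)), tolerance = 1e-12)
  egger <- estimate_from_summary("mr_egger_slope", 10, -7.182, 2.315)
  expect_equal(egger$pval, 2 * pt(-abs(-7.182 / 2.315), 8), tolerance = 1e-12)
  expect_equal(egger$pval, 1.46e-2, tolerance = 0.01)
  expect_error(estimate_from_summary("mr_egger_slope", 2, 1, 1),
               "underdetermined")
})

test_that("the joint significance rule needs IVW significance and sign agreement", {
  mk_panel <- function(b_ivw, p_ivw, b_wm, b_eg) {
    structure(list(n_snp = 5, estimates = list(
      ivw = mr_estimate("ivw", 5, b_ivw, 0.1, pval = p_ivw),
      weighted_median = mr_estimate("weighted_median", 5, b_wm, 0.2),
      mr_egger_slope = mr_estimate("mr_egger_slope", 5, b_eg, 0.3))),
      class = "method_panel")
  }
  expect_true(significance_rule(mk_panel(-1, 0.03, -0.8, -1.2)))
  expect_false(significance_rule(mk_panel(-1, 0.03, -0.8, 1.2)))
  expect_false(significance_rule(mk_panel(-1, 0.06, -0.8, -1.2)))
  expect_false(significance_rule(mk_panel(-1, 0.03, 0, -1.2)))
  bad <- structure(list(n_snp = 5, estimates = list(
    ivw = mr_estimate("ivw", 5, -1, 0.1))), class = "method_panel")
  expect_error(significance_rule(bad), "lacks")
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  expect_equal(bonferroni_adjust(1.42e-5, 196), 0.0028, tolerance = 1e-2)
  expect_equal(bonferroni_adjust(0.01, 196), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.01), 1), c(0.2, 0.01))
})
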