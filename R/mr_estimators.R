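#' @export
`[.harmonized_set` <- function(x, i, j, drop = FALSE) {
  at <- attributes(x)
  out <- NextMethod()
  if (is.data.frame(out)) {
    for (a in c("exposure_name", "outcome_name", "n_dropped_palindromic",
                "n_dropped_incompatible", "no_overlap"))
      attr(out, a) <- at[[a]]
    class(out) <- at$class
    rownames(out) <- NULL
  }
  out
}

#' Convert a log-odds effect to an odds ratio with confidence interval
#'
#' Report-layer transformation used throughout: OR = exp(beta), normal-based
#' confidence bounds exp(beta ± z·se), and a two-sided normal p-value.
#'
#' @param beta effect on the log-odds scale.
#' @param se standard error (> 0).
#' @param ci_level confidence level in (0, 1), default 0.95.
#' @return list with `or`, `ci_low`, `ci_high`, `pval`.
#' @examples
#' to_odds_ratio(-2.521, 0.581)  # OR 0.080, CI 0.026-0.251
#' @export
to_odds_ratio <- function(beta, se, ci_level = 0.95) {
  stopifnot(all(se > 0), ci_level > 0, ci_level < 1)
  z <- qnorm(1 - (1 - ci_level) / 2)
  list(or = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
       pval = 2 * pnorm(-abs(beta / se)))
}

#' Construct an MR estimate record
#'
#' @param method one of `"wald"`, `"ivw"`, `"weighted_median"`,
#'   `"mr_egger_slope"`, `"mr_egger_intercept"`, `"mvmr_direct"`.
#' @param n_snp number of instruments used.
#' @param beta,se point estimate and standard error (log-odds scale for
#'   binary outcomes).
#' @param pval two-sided p-value; if `NULL`, a normal p is computed.
#' @param ci_level confidence level for the odds-ratio interval.
#' @return An `mr_estimate` list with `or`, `ci_low`, `ci_high` filled from
#'   [to_odds_ratio()] (the p-value is the method's own, e.g. t-based for
#'   MR-Egger).
#' @export
mr_estimate <- function(method, n_snp, beta, se, pval = NULL, ci_level = 0.95) {
  methods <- c("wald", "ivw", "weighted_median", "mr_egger_slope",
               "mr_egger_intercept", "mvmr_direct")
  method <- match.arg(method, methods)
  stopifnot(se > 0, n_snp >= 1)
  tr <- to_odds_ratio(beta, se, ci_level)
  if (is.null(pval)) pval <- tr$pval
  structure(list(method = method, n_snp = as.integer(n_snp), beta = beta,
                 se = se, pval = pval, or = tr$or, ci_low = tr$ci_low,
                 ci_high = tr$ci_high, ci_level = ci_level),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s (%d SNPs): beta %.3f (SE %.3f), p %.3g, OR %.3f [%.3f, %.3f]\n",
              x$method, x$n_snp, x$beta, x$se, x$pval, x$or, x$ci_low,
              x$ci_high))
  invisible(x)
}

#' Wald-ratio causal estimate from a single instrument
#'
#' The single-SNP estimate: ratio of the SNP-outcome to the SNP-exposure
#' effect, with a first-order delta-method standard error
#' `se_out / |beta_exp|` and a two-sided normal p-value.
#'
#' @param beta_exp,se_exp SNP-exposure effect and SE.
#' @param beta_out,se_out SNP-outcome effect and SE.
#' @return An [mr_estimate()] with method `"wald"`.
#' @export
mr_wald_ratio <- function(beta_exp, se_exp, beta_out, se_out) {
  if (beta_exp == 0) stop("undefined ratio: beta_exp is zero")
  beta <- beta_out / beta_exp
  se <- se_out / abs(beta_exp)
  mr_estimate("wald", 1L, beta, se)
}

ivw_fit <- function(bx, by, se_out, random = TRUE) {
  w <- 1 / se_out^2
  sw <- sum(w * bx^2)
  if (sw == 0) stop("no instrument signal: all exposure effects are zero")
  beta <- sum(w * bx * by) / sw
  se_fixed <- 1 / sqrt(sw)
  n <- length(bx)
  sigma2 <- if (n > 1) sum(w * (by - beta * bx)^2) / (n - 1) else 1
  se <- if (random) se_fixed * max(1, sqrt(sigma2)) else se_fixed
  list(beta = beta, se = se, se_fixed = se_fixed, sigma2 = sigma2)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure
#' effects through the origin, with weights 1/se_out². The reported standard
#' error uses a multiplicative random-effects model: the fixed-effect SE
#' scaled by the residual standard deviation when it exceeds 1, never below
#' the fixed-effect SE. The p-value is two-sided normal. With a single
#' instrument the estimate delegates to [mr_wald_ratio()].
#'
#' @param h a `harmonized_set`.
#' @param random use the multiplicative random-effects SE (default `TRUE`);
#'   `FALSE` gives the fixed-effect SE.
#' @return An [mr_estimate()] with method `"ivw"` (or `"wald"` for one SNP).
#' @export
mr_ivw <- function(h, random = TRUE) {
  n <- nrow(h)
  if (n == 0) stop("no instruments")
  if (n == 1)
    return(mr_wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out))
  fit <- ivw_fit(h$beta_exp, h$beta_out, h$se_out, random)
  mr_estimate("ivw", n, fit$beta, fit$se)
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  b <- ratios[ord]
  w <- weights[ord] / sum(weights)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  if (s[length(s)] <= 0.5) return(b[length(b)])
  stats::approx(s, b, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Consistent when at least half the instrument weight comes from valid
#' instruments. Per-SNP Wald ratios are weighted by
#' beta_exp²/se_out² (the inverse first-order variance of the ratio); the
#' estimate interpolates the ratio at cumulative standardized weight 0.5.
#' The standard error comes from a seeded parametric bootstrap resampling
#' the per-SNP effects from normal distributions with their reported SEs;
#' the p-value is two-sided normal.
#'
#' @param h a `harmonized_set` with at least 3 usable SNPs; SNPs with a zero
#'   exposure effect are excluded with a warning.
#' @param n_boot bootstrap iterations (default 1000).
#' @param seed integer seed for the bootstrap (`NULL` uses the ambient RNG
#'   stream).
#' @return An [mr_estimate()] with method `"weighted_median"`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = NULL) {
  keep <- h$beta_exp != 0
  if (any(!keep))
    warning(sum(!keep), " SNP(s) with zero exposure effect excluded")
  h <- h[keep, , drop = FALSE]
  n <- nrow(h)
  if (n < 3) stop("weighted median requires at least 3 usable instruments")
  ratios <- h$beta_out / h$beta_exp
  weights <- h$beta_exp^2 / h$se_out^2
  beta <- weighted_median_point(ratios, weights)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      bx <- rnorm(n, h$beta_exp, h$se_exp)
      by <- rnorm(n, h$beta_out, h$se_out)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / h$se_out[ok]^2)
    }, numeric(1))
  })
  se <- sd(boot)
  mr_estimate("weighted_median", n, beta, se)
}

egger_fit <- function(bx, by, se_out) {
  flip <- sign(bx)
  flip[flip == 0] <- 1
  bx <- bx * flip
  by <- by * flip
  w <- 1 / se_out^2
  X <- cbind(intercept = 1, slope = bx)
  xtwx <- crossprod(X * w, X)
  if (abs(det(xtwx)) < .Machine$double.xmin || qr(X)$rank < 2)
    stop("MR-Egger underdetermined: no spread in exposure effects")
  coef <- solve(xtwx, crossprod(X * w, by))
  res <- by - X %*% coef
  n <- length(bx)
  sigma2 <- sum(w * res^2) / (n - 2)
  vc <- solve(xtwx) * max(1, sigma2)
  list(intercept = coef[1], slope = coef[2],
       se_intercept = sqrt(vc[1, 1]), se_slope = sqrt(vc[2, 2]),
       sigma2 = sigma2, df = n - 2)
}

#' MR-Egger regression
#'
#' Weighted regression of SNP-outcome effects on SNP-exposure effects with
#' an intercept (weights 1/se_out²), after orienting every SNP so its
#' exposure effect is nonnegative. The slope is a pleiotropy-adjusted causal
#' estimate; the intercept estimates the average directional pleiotropic
#' effect. SEs carry the same multiplicative random-effects scaling as
#' [mr_ivw()]; both p-values are two-sided from the t distribution with
#' n_snp − 2 degrees of freedom.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return list with `slope` and `intercept`, both [mr_estimate()] objects.
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (n < 3) stop("MR-Egger underdetermined: needs at least 3 instruments")
  fit <- egger_fit(h$beta_exp, h$beta_out, h$se_out)
  p_slope <- 2 * pt(-abs(fit$slope / fit$se_slope), fit$df)
  p_int <- 2 * pt(-abs(fit$intercept / fit$se_intercept), fit$df)
  list(slope = mr_estimate("mr_egger_slope", n, fit$slope, fit$se_slope,
                           pval = p_slope),
       intercept = mr_estimate("mr_egger_intercept", n, fit$intercept,
                               fit$se_intercept, pval = p_int))
}

#' Run every applicable MR method on one harmonized set
#'
#' With one instrument only the Wald ratio is computed; with two, IVW; with
#' three or more, IVW, weighted median and MR-Egger.
#'
#' @param h a `harmonized_set`.
#' @param n_boot,seed passed to [mr_weighted_median()].
#' @param ci_level confidence level for odds-ratio intervals.
#' @return A `method_panel`: list with `exposure_name`, `outcome_name`,
#'   `estimates` (named list of [mr_estimate()]s), to be finished with
#'   [significance_rule()] and [bonferroni_adjust()].
#' @export
mr_all_methods <- function(h, n_boot = 1000, seed = NULL, ci_level = 0.95) {
  n <- nrow(h)
  if (n == 0) stop("no instruments")
  est <- list()
  if (n == 1) {
    est$wald <- mr_wald_ratio(h$beta_exp, h$se_exp, h$beta_out, h$se_out)
  } else if (n == 2) {
    est$ivw <- mr_ivw(h)
  } else {
    est$ivw <- mr_ivw(h)
    est$weighted_median <- mr_weighted_median(h, n_boot, seed)
    eg <- mr_egger(h)
    est$mr_egger_slope <- eg$slope
    est$mr_egger_intercept <- eg$intercept
  }
  structure(list(exposure_name = attr(h, "exposure_name"),
                 outcome_name = attr(h, "outcome_name"),
                 n_snp = n, estimates = est,
                 significant = NA, bonferroni_p = NA_real_),
            class = "method_panel")
}

#' Rebuild an MR estimate from reported summary values
#'
#' Reconstructs the full report row — odds ratio, confidence interval and
#' p-value — from a method's point estimate and standard error, applying
#' the method's inference convention: two-sided normal p for the Wald
#' ratio, IVW and weighted median; two-sided t with n_snp − 2 degrees of
#' freedom for MR-Egger. Useful for checking published results tables.
#'
#' @param method estimator name (see [mr_estimate()]).
#' @param n_snp number of instruments behind the estimate.
#' @param beta,se reported effect and standard error.
#' @param ci_level confidence level (default 0.95, normal-based bounds).
#' @return An [mr_estimate()].
#' @examples
#' estimate_from_summary("ivw", 10, -2.521, 0.581)
#' estimate_from_summary("mr_egger_slope", 10, -7.182, 2.315)
#' @export
estimate_from_summary <- function(method, n_snp, beta, se, ci_level = 0.95) {
  pval <- if (method %in% c("mr_egger_slope", "mr_egger_intercept")) {
    if (n_snp < 3) stop("MR-Egger underdetermined: needs at least 3 instruments")
    2 * pt(-abs(beta / se), n_snp - 2)
  } else {
    2 * pnorm(-abs(beta / se))
  }
  mr_estimate(method, n_snp, beta, se, pval = pval, ci_level = ci_level)
}

#' Joint significance rule across the three MR methods
#'
#' An exposure is called significant iff the IVW p-value is below `alpha`
#' and the IVW, weighted-median and MR-Egger slope estimates all share the
#' same sign (a zero effect counts as a direction mismatch). For a panel
#' estimated from a single instrument, the Wald p-value below `alpha`
#' decides.
#'
#' @param panel a `method_panel` from [mr_all_methods()].
#' @param alpha significance level (default 0.05).
#' @return logical scalar.
#' @export
significance_rule <- function(panel, alpha = 0.05) {
  est <- panel$estimates
  if (!is.null(est$wald) && is.null(est$ivw))
    return(est$wald$pval < alpha)
  if (is.null(est$ivw)) stop("panel lacks an IVW estimate")
  if (is.null(est$weighted_median) || is.null(est$mr_egger_slope)) {
    if (panel$n_snp < 3) return(est$ivw$pval < alpha)
    stop("panel lacks weighted_median or mr_egger_slope estimates")
  }
  signs <- sign(c(est$ivw$beta, est$weighted_median$beta,
                  est$mr_egger_slope$beta))
  est$ivw$pval < alpha && all(signs == signs[1]) && signs[1] != 0
}

#' Bonferroni adjustment over a family of comparisons
#'
#' Multiplies each p-value by the family size `m` and caps at 1.
#'
#' @param pvals numeric vector of p-values.
#' @param m number of comparisons (default `length(pvals)`).
#' @return adjusted p-values.
#' @examples
#' bonferroni_adjust(1.42e-5, 196)  # 0.0028
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  stopifnot(m >= 1)
  pmin(1, pvals * m)
}
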