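#' Cochran's Q heterogeneity test
#'
#' Measures dispersion of the per-SNP Wald ratios around the fixed-effect
#' IVW estimate: Q = sum over SNPs of w_j (b_j − b_ivw)², with ratio weights
#' w_j = beta_exp_j²/se_out_j² (equivalent to the fixed-effect IVW
#' weighting). The p-value is the upper tail of the chi-square distribution
#' with n_snp − 1 degrees of freedom; p < 0.05 indicates heterogeneity,
#' i.e. likely invalid instruments.
#'
#' @param h a `harmonized_set` with at least 2 SNPs and nonzero exposure
#'   effects.
#' @return list with `q`, `df`, `pval`, and `contributions` (per-SNP terms
#'   summing to `q`).
#' @export
cochran_q <- function(h) {
  n <- nrow(h)
  if (n < 2) stop("Cochran's Q requires at least 2 instruments")
  if (any(h$beta_exp == 0)) stop("zero exposure effect: ratio undefined")
  b <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  b_ivw <- sum(w * b) / sum(w)
  contrib <- w * (b - b_ivw)^2
  q <- sum(contrib)
  structure(list(q = q, df = n - 1L, pval = pchisq(q, n - 1, lower.tail = FALSE),
                 contributions = setNames(contrib, h$snp_id)),
            class = "heterogeneity_result")
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f, df = %d, p = %.3g\n", x$q, x$df, x$pval))
  invisible(x)
}

#' MR-Egger intercept test for directional pleiotropy
#'
#' Returns the intercept estimate of [mr_egger()] with its t-based p-value
#' (n_snp − 2 degrees of freedom). p > 0.05 means the intercept does not
#' differ from zero, i.e. no evidence of directional horizontal pleiotropy;
#' the verdict is attached as attribute `"verdict"`.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @return The intercept [mr_estimate()] with attribute `verdict`, either
#'   `"no horizontal pleiotropy"` or `"horizontal pleiotropy"`.
#' @export
egger_intercept_test <- function(h) {
  est <- mr_egger(h)$intercept
  attr(est, "verdict") <- if (est$pval > 0.05) "no horizontal pleiotropy"
                          else "horizontal pleiotropy"
  est
}

# Leave-one-out fixed-effect IVW slopes for all SNPs at once.
loo_ivw_beta <- function(bx, by, w) {
  s1 <- sum(w * bx * by)
  s2 <- sum(w * bx^2)
  (s1 - w * bx * by) / (s2 - w * bx^2)
}

#' MR-PRESSO residual-sum-of-squares outlier test
#'
#' Detects horizontally pleiotropic instruments by comparing each SNP's
#' observed squared residual — the deviation of its outcome effect from the
#' prediction of the leave-one-out fixed-effect IVW slope, weighted by
#' 1/se_out² — against a parametric null distribution generated by
#' simulation. The global test compares the total weighted residual sum of
#' squares against its simulated null. Empirical p-values use add-one
#' smoothing so they are never exactly zero. Per-SNP p-values are
#' Bonferroni-adjusted by the number of instruments; SNPs below
#' `outlier_alpha` are flagged, and when any are flagged, the IVW estimate
#' is recomputed without them.
#'
#' @param h a `harmonized_set` with at least 4 SNPs.
#' @param n_sim simulated null datasets (>= 100; default 1000).
#' @param seed integer seed; fixed seeds reproduce the p-values exactly.
#' @param outlier_alpha threshold on adjusted per-SNP p-values (default
#'   0.05).
#' @return A `presso_result` list: `rss_observed`, `global_pval`,
#'   `per_snp_pvals` (adjusted), `outliers`, and `corrected_estimate` (the
#'   outlier-free [mr_ivw()], present iff outliers were found).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = NULL, outlier_alpha = 0.05) {
  n <- nrow(h)
  if (n < 4) stop("too few instruments for PRESSO (need >= 4)")
  if (n_sim < 100) stop("n_sim must be at least 100")
  bx <- h$beta_exp; by <- h$beta_out
  w <- 1 / h$se_out^2
  b_loo <- loo_ivw_beta(bx, by, w)
  res_obs <- by - b_loo * bx
  rss_j_obs <- w * res_obs^2
  rss_obs <- sum(rss_j_obs)

  sims <- with_seed(seed, {
    bx_s <- matrix(rnorm(n * n_sim, bx, h$se_exp), nrow = n)
    by_s <- matrix(rnorm(n * n_sim, b_loo * bx, h$se_out), nrow = n)
    rss_j <- matrix(0, n, n_sim)
    for (k in seq_len(n_sim)) {
      bl <- loo_ivw_beta(bx_s[, k], by_s[, k], w)
      rss_j[, k] <- w * (by_s[, k] - bl * bx_s[, k])^2
    }
    rss_j
  })
  rss_sim <- colSums(sims)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  p_snp <- (1 + rowSums(sims >= rss_j_obs)) / (n_sim + 1)
  p_adj <- pmin(1, p_snp * n)
  outliers <- h$snp_id[p_adj < outlier_alpha]
  corrected <- NULL
  if (length(outliers) > 0 && length(outliers) < n - 1) {
    corrected <- mr_ivw(h[!(h$snp_id %in% outliers), , drop = FALSE])
  }
  structure(list(rss_observed = rss_obs, global_pval = global_p,
                 per_snp_pvals = setNames(p_adj, h$snp_id),
                 outliers = outliers, corrected_estimate = corrected),
            class = "presso_result")
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("MR-PRESSO: RSS = %.4g, global p = %.3g, %d outlier(s)%s\n",
              x$rss_observed, x$global_pval, length(x$outliers),
              if (length(x$outliers)) paste0(" (", paste(x$outliers, collapse = ", "), ")")
              else ""))
  invisible(x)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW effect with each instrument removed in turn. SNPs
#' whose removal changes the IVW significance status at `alpha`, or flips
#' the sign of the estimate relative to the all-SNP analysis, are flagged
#' as potentially driving the result.
#'
#' @param h a `harmonized_set` with at least 3 SNPs.
#' @param alpha significance level used for flagging (default 0.05).
#' @return A `loo_result`: `rows` (data frame `snp_id`, `beta_without`,
#'   `se_without`, `pval_without`), `flagged` (character vector), and
#'   `full` (the all-SNP [mr_ivw()] estimate).
#' @export
leave_one_out <- function(h, alpha = 0.05) {
  n <- nrow(h)
  if (n < 3) stop("leave-one-out requires at least 3 instruments")
  full <- mr_ivw(h)
  rows <- do.call(rbind, lapply(seq_len(n), function(j) {
    est <- mr_ivw(h[-j, , drop = FALSE])
    data.frame(snp_id = h$snp_id[j], beta_without = est$beta,
               se_without = est$se, pval_without = est$pval,
               stringsAsFactors = FALSE)
  }))
  flagged <- rows$snp_id[(rows$pval_without < alpha) != (full$pval < alpha) |
                           sign(rows$beta_without) != sign(full$beta)]
  structure(list(rows = rows, flagged = flagged, full = full),
            class = "loo_result")
}

#' @export
print.loo_result <- function(x, ...) {
  cat(sprintf("Leave-one-out over %d SNPs; %d flagged as influential\n",
              nrow(x$rows), length(x$flagged)))
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Full sensitivity battery for one exposure-outcome pair
#'
#' Runs Cochran's Q (>= 2 SNPs), the MR-Egger intercept test (>= 3),
#' MR-PRESSO (>= 4) and leave-one-out (>= 3); stages without enough
#' instruments are returned as `NULL`.
#'
#' @param h a `harmonized_set`.
#' @param n_sim,seed passed to [mr_presso()].
#' @param alpha flagging level for [leave_one_out()].
#' @return list with components `q`, `egger_intercept`, `presso`,
#'   `leave_one_out`.
#' @export
sensitivity_battery <- function(h, n_sim = 1000, seed = NULL, alpha = 0.05) {
  n <- nrow(h)
  list(q = if (n >= 2) cochran_q(h) else NULL,
       egger_intercept = if (n >= 3) egger_intercept_test(h) else NULL,
       presso = if (n >= 4) mr_presso(h, n_sim, seed) else NULL,
       leave_one_out = if (n >= 3) leave_one_out(h, alpha) else NULL)
}
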