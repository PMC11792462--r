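#' Classify an indirect effect as mediation or suppression
#'
#' If the indirect (exposure -> mediator -> outcome) effect has the same
#' sign as the total exposure -> outcome effect, the mediator transmits part
#' of the effect (mediation); if the signs oppose, the mediator counteracts
#' it (suppression); a zero indirect effect is neither.
#'
#' @param indirect indirect effect (alpha x beta2 or total - direct).
#' @param total total exposure -> outcome effect.
#' @return `"mediation"`, `"suppression"` or `"none"`.
#' @export
classify_effect <- function(indirect, total) {
  if (indirect == 0) return("none")
  if (sign(indirect) == sign(total) && total != 0) "mediation" else "suppression"
}

#' Two-step (network) MR mediation decomposition
#'
#' Combines three univariable MR estimates — exposure -> mediator (alpha),
#' mediator -> outcome (beta2), and exposure -> outcome (total beta) — into
#' the indirect effect alpha x beta2 and the proportion mediated
#' indirect / total. The indirect-effect standard error uses the delta
#' method for a product, sqrt(alpha² se_beta2² + beta2² se_alpha²), with a
#' normal p-value; the proportion inherits it treating the total as fixed.
#'
#' @param alpha [mr_estimate()] of the exposure -> mediator effect.
#' @param beta2 [mr_estimate()] of the mediator -> outcome effect.
#' @param total [mr_estimate()] of the exposure -> outcome effect; its beta
#'   must be nonzero.
#' @param exposure,mediator,outcome trait labels.
#' @return A `mediation_result` list with `alpha`, `beta2`, `total`,
#'   `indirect_two_step`, `indirect_se`, `indirect_pval`,
#'   `proportion_two_step`, `proportion_se`, `proportion_pval`, `label`.
#' @export
two_step_effects <- function(alpha, beta2, total,
                             exposure = "exposure", mediator = "mediator",
                             outcome = "outcome") {
  if (total$beta == 0) stop("proportion undefined: total effect is zero")
  ind <- alpha$beta * beta2$beta
  ind_se <- sqrt(alpha$beta^2 * beta2$se^2 + beta2$beta^2 * alpha$se^2)
  ind_p <- if (ind_se > 0) 2 * pnorm(-abs(ind / ind_se)) else 1
  prop <- ind / total$beta
  prop_se <- ind_se / abs(total$beta)
  prop_p <- if (prop_se > 0) 2 * pnorm(-abs(prop / prop_se)) else 1
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 alpha = alpha$beta, alpha_se = alpha$se,
                 beta2 = beta2$beta, beta2_se = beta2$se,
                 total = total$beta, total_se = total$se,
                 indirect_two_step = ind, indirect_se = ind_se,
                 indirect_pval = ind_p,
                 proportion_two_step = prop, proportion_se = prop_se,
                 proportion_pval = prop_p,
                 label = classify_effect(ind, total$beta)),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf("Mediation %s -> %s -> %s\n", x$exposure, x$mediator, x$outcome))
  cat(sprintf("  alpha %.3f, beta2 %.3f, total %.3f\n", x$alpha, x$beta2, x$total))
  cat(sprintf("  two-step indirect %.3f (prop %.1f%%), label: %s\n",
              x$indirect_two_step, 100 * x$proportion_two_step, x$label))
  if (!is.null(x$direct_mvmr))
    cat(sprintf("  MVMR direct %.3f, indirect %.3f (prop %.1f%%)\n",
                x$direct_mvmr, x$indirect_mvmr, 100 * x$proportion_mvmr))
  invisible(x)
}

#' @export
print.mediation_skip <- function(x, ...) {
  cat(sprintf("Mediation %s -> %s -> %s skipped: %s\n", x$exposure,
              x$mediator, x$outcome, x$reason))
  invisible(x)
}

#' Multivariable MR (MVMR) regression
#'
#' Weighted regression of per-SNP outcome effects on the SNP effects for
#' several exposures jointly, without intercept, weights 1/se_out². With an
#' exposure and a mediator as the two regressors, the exposure coefficient
#' is the direct effect (beta1) conditional on the mediator. SEs carry the
#' multiplicative random-effects scaling of [mr_ivw()] with residual
#' degrees of freedom n_snp minus the number of exposures; p-values are
#' two-sided normal.
#'
#' @param beta_mat numeric matrix (n_snp x n_exposure) of SNP-exposure
#'   effects, columns named for the exposures.
#' @param beta_out,se_out per-SNP outcome effects and SEs.
#' @return An `mvmr_fit`: data frame `coefficients` (exposure, beta, se,
#'   pval), plus `n_snp` and `sigma2`.
#' @export
mvmr_fit <- function(beta_mat, beta_out, se_out) {
  beta_mat <- as.matrix(beta_mat)
  n <- nrow(beta_mat)
  p <- ncol(beta_mat)
  if (is.null(colnames(beta_mat)))
    colnames(beta_mat) <- paste0("exposure", seq_len(p))
  if (n < p + 1) stop("too few instruments: need n_snp >= n_exposure + 1")
  # an exposure with no instrument signal at all contributes nothing to the
  # fit; report it with a zero coefficient rather than failing on rank
  zero_col <- colSums(beta_mat != 0) == 0
  active <- beta_mat[, !zero_col, drop = FALSE]
  if (ncol(active) == 0) stop("no instrument signal in any exposure")
  if (qr(active)$rank < ncol(active))
    stop("collinear instruments: rank-deficient design")
  w <- 1 / se_out^2
  xtwx <- crossprod(active * w, active)
  coef <- solve(xtwx, crossprod(active * w, beta_out))
  res <- beta_out - active %*% coef
  sigma2 <- sum(w * res^2) / (n - ncol(active))
  vc <- solve(xtwx) * max(1, sigma2)
  se_active <- unname(sqrt(diag(vc)))
  beta_all <- se_all <- pval_all <- rep(NA_real_, p)
  beta_all[zero_col] <- 0
  beta_all[!zero_col] <- as.numeric(coef)
  se_all[!zero_col] <- se_active
  pval_all[!zero_col] <- 2 * pnorm(-abs(as.numeric(coef) / se_active))
  structure(list(coefficients = data.frame(
                   exposure = colnames(beta_mat),
                   beta = beta_all, se = se_all, pval = pval_all,
                   stringsAsFactors = FALSE),
                 n_snp = n, sigma2 = sigma2),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("MVMR fit on %d SNPs\n", x$n_snp))
  print(x$coefficients, row.names = FALSE)
  invisible(x)
}

# Instruments for MVMR: union of the two instrument sets, de-duplicated and
# re-clumped at the same thresholds on the combined evidence (smallest
# available p per SNP).
mvmr_instruments <- function(exposure, mediator, iv_exp, iv_med, ld, cfg) {
  ids <- union(iv_exp, iv_med)
  rec_e <- as.data.frame(exposure)[exposure$snp_id %in% ids, , drop = FALSE]
  rec_m <- as.data.frame(mediator)[mediator$snp_id %in% setdiff(ids, rec_e$snp_id), , drop = FALSE]
  rec <- rbind(rec_e, rec_m)
  pm <- as.data.frame(mediator)$pval[match(rec$snp_id, mediator$snp_id)]
  rec$pval <- pmin(rec$pval, pm, na.rm = TRUE)
  tab <- gwas_table(rec, "mvmr_union", trait_type(exposure))
  clump(tab, ld, cfg$clump_r2, cfg$clump_window_kb)$snp_id
}

#' Full mediation analysis for one exposure-mediator-outcome triple
#'
#' Runs the complete pipeline: instrument selection and univariable MR for
#' exposure -> mediator (alpha), mediator -> outcome (beta2) and exposure ->
#' outcome (total beta); the two-step decomposition; and an MVMR model on
#' the union of the exposure's and mediator's instruments (de-duplicated
#' and re-clumped) giving the direct effect beta1, the MVMR indirect effect
#' beta - beta1, and the MVMR proportion mediated. The
#' mediation-versus-suppression label follows the sign of the two-step
#' indirect effect relative to the total.
#'
#' @param exposure,mediator,outcome [gwas_table()] objects.
#' @param ld an [ld_info()] table.
#' @param cfg a [selection_config()]; the mediator -> outcome step applies
#'   the same criteria with the mediator as the exposure.
#' @param n_boot,seed passed to the weighted-median bootstrap.
#' @return A `mediation_result` (see [two_step_effects()]) extended with
#'   `direct_mvmr`, `direct_mvmr_se`, `direct_mvmr_pval`, `indirect_mvmr`,
#'   `proportion_mvmr`, `mvmr_n_snp`. If any stage has no instruments, a
#'   `mediation_skip` list with a `reason`.
#' @export
mediation_summary <- function(exposure, mediator, outcome, ld,
                              cfg = selection_config(), n_boot = 1000,
                              seed = NULL) {
  skip <- function(reason)
    structure(list(exposure = trait_name(exposure),
                   mediator = trait_name(mediator),
                   outcome = trait_name(outcome), reason = reason),
              class = "mediation_skip")

  s_alpha <- select_ivs(exposure, mediator, ld, cfg)
  if (attr(s_alpha, "no_iv")) return(skip("no instruments for exposure -> mediator"))
  s_beta2 <- select_ivs(mediator, outcome, ld, cfg)
  if (attr(s_beta2, "no_iv")) return(skip("no instruments for mediator -> outcome"))
  s_total <- select_ivs(exposure, outcome, ld, cfg)
  if (attr(s_total, "no_iv")) return(skip("no instruments for exposure -> outcome"))

  est_alpha <- mr_ivw(s_alpha$harmonized)
  est_beta2 <- mr_ivw(s_beta2$harmonized)
  est_total <- mr_ivw(s_total$harmonized)
  if (est_total$beta == 0) return(skip("total effect is exactly zero"))

  res <- two_step_effects(est_alpha, est_beta2, est_total,
                          exposure = trait_name(exposure),
                          mediator = trait_name(mediator),
                          outcome = trait_name(outcome))

  ids <- mvmr_instruments(exposure, mediator, s_total$ivs$snp_ids,
                          s_beta2$ivs$snp_ids, ld, cfg)
  # align both the outcome and the mediator onto the exposure's allele coding
  he <- harmonize(exposure, outcome)
  hm <- harmonize(exposure, mediator)
  ids <- Reduce(intersect, list(ids, he$snp_id, hm$snp_id))
  if (length(ids) < 3) {
    res$direct_mvmr <- NA_real_
    res$mvmr_note <- "too few shared instruments for MVMR"
    return(res)
  }
  ie <- match(ids, he$snp_id)
  im <- match(ids, hm$snp_id)
  X <- cbind(he$beta_exp[ie], hm$beta_out[im])
  colnames(X) <- c(trait_name(exposure), trait_name(mediator))
  fit <- mvmr_fit(X, he$beta_out[ie], he$se_out[ie])
  direct <- fit$coefficients[1, ]
  res$direct_mvmr <- direct$beta
  res$direct_mvmr_se <- direct$se
  res$direct_mvmr_pval <- direct$pval
  res$beta2_mvmr <- fit$coefficients$beta[2]
  res$indirect_mvmr <- res$total - direct$beta
  res$proportion_mvmr <- res$indirect_mvmr / res$total
  res$mvmr_n_snp <- fit$n_snp
  res
}

#' Screen candidate mediators with the two-stage significance funnel
#'
#' A mediator is carried forward iff the exposure -> mediator IVW p-value
#' and the mediator -> outcome IVW p-value are both below `alpha`. Survivors
#' receive the full [mediation_summary()] including the
#' mediation/suppression label.
#'
#' @param exposure a [gwas_table()].
#' @param mediators named list of [gwas_table()] objects.
#' @param outcome a [gwas_table()].
#' @param ld,cfg,n_boot,seed as in [mediation_summary()].
#' @param alpha screening level (default 0.05).
#' @return list with `screen` (data frame of per-mediator step-1/step-2
#'   p-values and a `kept` flag) and `results` (named list of
#'   `mediation_result`s for kept mediators).
#' @export
screen_mediators <- function(exposure, mediators, outcome, ld,
                             cfg = selection_config(), alpha = 0.05,
                             n_boot = 1000, seed = NULL) {
  rows <- list()
  results <- list()
  for (nm in names(mediators)) {
    med <- mediators[[nm]]
    s1 <- select_ivs(exposure, med, ld, cfg)
    p1 <- if (attr(s1, "no_iv")) NA_real_ else mr_ivw(s1$harmonized)$pval
    s2 <- select_ivs(med, outcome, ld, cfg)
    p2 <- if (attr(s2, "no_iv")) NA_real_ else mr_ivw(s2$harmonized)$pval
    kept <- isTRUE(p1 < alpha) && isTRUE(p2 < alpha)
    rows[[nm]] <- data.frame(mediator = nm, pval_step1 = p1, pval_step2 = p2,
                             kept = kept, stringsAsFactors = FALSE)
    if (kept)
      results[[nm]] <- mediation_summary(exposure, med, outcome, ld, cfg,
                                         n_boot, seed)
  }
  list(screen = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       results = results)
}
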