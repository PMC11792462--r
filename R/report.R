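format_p <- function(p) {
  toupper(sub("e", "E", sprintf("%.2e", p)))
}

method_label <- function(method) {
  c(wald = "Wald ratio", ivw = "IVW", weighted_median = "Weighted median",
    mr_egger_slope = "MR Egger", mr_egger_intercept = "MR Egger intercept",
    mvmr_direct = "MVMR direct")[method]
}

#' Main-results table for an MR run
#'
#' One row per (exposure, method): exposure, method, N(SNP), beta, SE,
#' p-value, OR and 95% CI, the layout of a standard MR results table.
#'
#' @param run an `mr_run` from [run_univariable()] or [run_reverse()].
#' @param significant_only keep only exposures passing the joint
#'   significance rule (default `FALSE`).
#' @return data frame with full-precision numeric columns.
#' @export
results_table <- function(run, significant_only = FALSE) {
  rows <- list()
  for (nm in names(run$panels)) {
    p <- run$panels[[nm]]
    if (inherits(p, "panel_skip")) next
    if (significant_only && !isTRUE(p$significant)) next
    for (est in p$estimates) {
      if (est$method == "mr_egger_intercept") next
      rows[[length(rows) + 1L]] <- data.frame(
        exposure = nm, method = method_label(est$method), n_snp = est$n_snp,
        beta = est$beta, se = est$se, pval = est$pval, or = est$or,
        ci_low = est$ci_low, ci_high = est$ci_high,
        significant = isTRUE(p$significant),
        bonferroni_p = p$bonferroni_p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(exposure = character(), method = character(),
                      n_snp = integer(), beta = numeric(), se = numeric(),
                      pval = numeric(), or = numeric(), ci_low = numeric(),
                      ci_high = numeric(), significant = logical(),
                      bonferroni_p = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

format_results_table <- function(tab) {
  data.frame(Exposure = tab$exposure, Method = tab$method,
             `N (SNP)` = tab$n_snp,
             Beta = sprintf("%.3f", tab$beta), SE = sprintf("%.3f", tab$se),
             `P-value` = format_p(tab$pval),
             OR = sprintf("%.3f", tab$or),
             `95% CI` = sprintf("%.3f-%.3f", tab$ci_low, tab$ci_high),
             check.names = FALSE, stringsAsFactors = FALSE)
}

sensitivity_table <- function(run) {
  rows <- list()
  for (nm in names(run$panels)) {
    p <- run$panels[[nm]]
    if (inherits(p, "panel_skip") || is.null(p$sensitivity)) next
    s <- p$sensitivity
    rows[[length(rows) + 1L]] <- data.frame(
      exposure = nm,
      q = if (!is.null(s$q)) s$q$q else NA_real_,
      q_df = if (!is.null(s$q)) s$q$df else NA_integer_,
      q_pval = if (!is.null(s$q)) s$q$pval else NA_real_,
      egger_intercept = if (!is.null(s$egger_intercept)) s$egger_intercept$beta else NA_real_,
      egger_intercept_se = if (!is.null(s$egger_intercept)) s$egger_intercept$se else NA_real_,
      egger_intercept_pval = if (!is.null(s$egger_intercept)) s$egger_intercept$pval else NA_real_,
      presso_global_pval = if (!is.null(s$presso)) s$presso$global_pval else NA_real_,
      presso_outliers = if (!is.null(s$presso)) paste(s$presso$outliers, collapse = ",") else "",
      loo_flagged = if (!is.null(s$leave_one_out)) paste(s$leave_one_out$flagged, collapse = ",") else "",
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

mediation_table <- function(mediation) {
  rows <- list()
  for (res in mediation) {
    if (inherits(res, "mediation_skip")) next
    rows[[length(rows) + 1L]] <- data.frame(
      exposure = res$exposure, mediator = res$mediator,
      alpha = res$alpha, beta2 = res$beta2, total = res$total,
      indirect_two_step = res$indirect_two_step,
      direct_mvmr = if (is.null(res$direct_mvmr)) NA_real_ else res$direct_mvmr,
      proportion_two_step = res$proportion_two_step,
      proportion_mvmr = if (is.null(res$proportion_mvmr)) NA_real_ else res$proportion_mvmr,
      proportion_pval = res$proportion_pval,
      label = res$label, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  do.call(rbind, rows)
}

#' Render an MR run (and optional mediation results) to report files
#'
#' Writes `mr_results.tsv` (the main results table, three rows per
#' significant exposure, formatted to report precision: 3 decimals for
#' beta/SE/OR, scientific notation for p-values), `mr_results_full.tsv`
#' (all exposures, full precision), `sensitivity.tsv`, `mediation.tsv`
#' (omitted when there are no mediation results), `leave_one_out.tsv` and a
#' machine-readable `results.json` holding everything at full precision.
#'
#' @param run an `mr_run`.
#' @param mediation optional list of `mediation_result`s.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
render_report <- function(run, mediation = NULL, out_dir) {
  stopifnot(inherits(run, "mr_run"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  tab <- results_table(run)
  sig <- results_table(run, significant_only = TRUE)
  write.table(format_results_table(sig), file.path(out_dir, "mr_results.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tab, file.path(out_dir, "mr_results_full.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  sens <- sensitivity_table(run)
  if (!is.null(sens))
    write.table(sens, file.path(out_dir, "sensitivity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  loo <- list()
  for (nm in names(run$panels)) {
    p <- run$panels[[nm]]
    if (inherits(p, "panel_skip") || is.null(p$sensitivity$leave_one_out)) next
    r <- p$sensitivity$leave_one_out$rows
    r$exposure <- nm
    loo[[nm]] <- r[, c("exposure", setdiff(names(r), "exposure"))]
  }
  if (length(loo) > 0)
    write.table(do.call(rbind, loo), file.path(out_dir, "leave_one_out.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

  med_tab <- if (!is.null(mediation)) mediation_table(mediation) else NULL
  if (!is.null(med_tab))
    write.table(med_tab, file.path(out_dir, "mediation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  payload <- list(direction = run$direction, alpha = run$alpha,
                  bonferroni_m = run$bonferroni_m, results = tab,
                  sensitivity = sens, mediation = med_tab,
                  skipped = names(run$panels)[vapply(run$panels, inherits,
                                                     TRUE, "panel_skip")])
  jsonlite::write_json(payload, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(out_dir)
}
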