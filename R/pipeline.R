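#' Pipeline run configuration
#'
#' @param exposures named list of [gwas_table()]s (or a single table).
#' @param outcome a [gwas_table()].
#' @param mediators optional named list of [gwas_table()]s.
#' @param ld an [ld_info()] table.
#' @param selection a [selection_config()].
#' @param alpha per-test significance level (default 0.05).
#' @param bonferroni_m Bonferroni family size; defaults to the number of
#'   exposures attempted (including ones skipped for lack of instruments).
#' @param n_boot weighted-median bootstrap iterations.
#' @param seed integer seed governing every stochastic step.
#' @param out_dir optional output directory for [render_report()].
#' @return A `run_config` list.
#' @export
run_config <- function(exposures, outcome, mediators = NULL, ld = ld_info(),
                       selection = selection_config(), alpha = 0.05,
                       bonferroni_m = NULL, n_boot = 1000, seed = 1,
                       out_dir = NULL) {
  if (inherits(exposures, "gwas_table")) {
    exposures <- setNames(list(exposures), trait_name(exposures))
  }
  if (length(exposures) == 0) stop("empty exposure list")
  if (is.null(names(exposures)) || any(names(exposures) == ""))
    names(exposures) <- vapply(exposures, trait_name, "")
  structure(list(exposures = exposures, outcome = outcome,
                 mediators = mediators, ld = ld, selection = selection,
                 alpha = alpha, bonferroni_m = bonferroni_m,
                 n_boot = n_boot, seed = seed, out_dir = out_dir),
            class = "run_config")
}

run_one_exposure <- function(exposure, outcome, cfg, seed) {
  sel <- select_ivs(exposure, outcome, cfg$ld, cfg$selection)
  if (attr(sel, "no_iv"))
    return(structure(list(exposure_name = trait_name(exposure),
                          reason = "no instruments survived selection",
                          selection_log = sel$ivs$selection_log),
                     class = "panel_skip"))
  h <- sel$harmonized
  panel <- mr_all_methods(h, n_boot = cfg$n_boot, seed = seed)
  panel$significant <- significance_rule(panel, cfg$alpha)
  panel$sensitivity <- sensitivity_battery(h, seed = sub_seed(seed, 17L),
                                           alpha = cfg$alpha)
  panel$selection_log <- sel$ivs$selection_log
  panel$harmonized <- h
  panel
}

#' Run univariable MR for every exposure against one outcome
#'
#' For each exposure: instrument selection, then the Wald ratio (one
#' instrument) or all three estimators, the sensitivity battery, the joint
#' significance rule, and finally Bonferroni adjustment of the IVW (or
#' Wald) p-values across the whole exposure family. An exposure with no
#' surviving instruments is recorded as a skip and the run continues; the
#' Bonferroni family size still counts it.
#'
#' @param cfg a [run_config()].
#' @param direction label stored on the result (`"forward"` or
#'   `"reverse"`).
#' @return An `mr_run`: list with `panels` (per-exposure `method_panel` or
#'   `panel_skip`), `bonferroni_m`, `alpha`, `direction`.
#' @export
run_univariable <- function(cfg, direction = "forward") {
  stopifnot(inherits(cfg, "run_config"))
  panels <- list()
  for (i in seq_along(cfg$exposures)) {
    nm <- names(cfg$exposures)[i]
    panels[[nm]] <- run_one_exposure(cfg$exposures[[i]], cfg$outcome, cfg,
                                     seed = sub_seed(cfg$seed, i))
  }
  m <- if (is.null(cfg$bonferroni_m)) length(panels) else cfg$bonferroni_m
  for (nm in names(panels)) {
    p <- panels[[nm]]
    if (inherits(p, "panel_skip")) next
    primary <- if (!is.null(p$estimates$ivw)) p$estimates$ivw else p$estimates$wald
    panels[[nm]]$bonferroni_p <- bonferroni_adjust(primary$pval, m)
  }
  structure(list(panels = panels, bonferroni_m = m, alpha = cfg$alpha,
                 direction = direction),
            class = "mr_run")
}

#' Run reverse MR: the disease as exposure, each taxon as outcome
#'
#' Identical machinery to [run_univariable()] with the roles swapped: the
#' configured outcome becomes the exposure and every configured exposure
#' becomes an outcome in turn, using the same selection thresholds. Both
#' unadjusted and Bonferroni-adjusted p-values are reported.
#'
#' @param cfg a [run_config()].
#' @return An `mr_run` with `direction = "reverse"`.
#' @export
run_reverse <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  panels <- list()
  for (i in seq_along(cfg$exposures)) {
    nm <- names(cfg$exposures)[i]
    panels[[nm]] <- run_one_exposure(cfg$outcome, cfg$exposures[[i]], cfg,
                                     seed = sub_seed(cfg$seed, 1000L + i))
  }
  m <- if (is.null(cfg$bonferroni_m)) length(panels) else cfg$bonferroni_m
  for (nm in names(panels)) {
    p <- panels[[nm]]
    if (inherits(p, "panel_skip")) next
    primary <- if (!is.null(p$estimates$ivw)) p$estimates$ivw else p$estimates$wald
    panels[[nm]]$bonferroni_p <- bonferroni_adjust(primary$pval, m)
  }
  structure(list(panels = panels, bonferroni_m = m, alpha = cfg$alpha,
                 direction = "reverse"),
            class = "mr_run")
}

#' @export
print.mr_run <- function(x, ...) {
  n_skip <- sum(vapply(x$panels, inherits, TRUE, "panel_skip"))
  cat(sprintf("MR run (%s): %d exposures (%d skipped), Bonferroni m = %d\n",
              x$direction, length(x$panels), n_skip, x$bonferroni_m))
  sig <- names(x$panels)[vapply(x$panels, function(p)
    isTRUE(p$significant), TRUE)]
  if (length(sig)) cat("  significant:", paste(sig, collapse = ", "), "\n")
  invisible(x)
}
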