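#' Instrument-selection configuration
#'
#' Bundles the thresholds of the four instrument-selection criteria used for
#' gut-microbiome exposures: genome-wide-suggestive association with the
#' exposure, LD independence, no association with the outcome, and
#' instrument strength (F-statistic), plus an explicit list of SNPs known to
#' act through confounders.
#'
#' @param exposure_p_threshold retain SNPs with exposure p below this
#'   (default 1e-5, the conventional suggestive threshold for microbiome
#'   GWAS instruments).
#' @param outcome_p_threshold drop SNPs with outcome p at or below this
#'   (default 1e-5): instruments must not be directly associated with the
#'   outcome.
#' @param clump_r2,clump_window_kb LD-clumping parameters (defaults 0.001
#'   and 10000 kb).
#' @param f_threshold weak-instrument cutoff; SNPs are retained iff
#'   F > `f_threshold` (strict; default 10).
#' @param confounder_snps character vector of SNP ids associated with known
#'   confounders of the exposure-outcome relationship, to be excluded (the
#'   role a PhenoScanner lookup plays when network access is available).
#' @return A `selection_config` list.
#' @export
selection_config <- function(exposure_p_threshold = 1e-5,
                             outcome_p_threshold = 1e-5,
                             clump_r2 = 0.001, clump_window_kb = 10000,
                             f_threshold = 10,
                             confounder_snps = character()) {
  stopifnot(exposure_p_threshold > 0, exposure_p_threshold < 1,
            outcome_p_threshold > 0, clump_r2 > 0, clump_window_kb > 0,
            f_threshold > 0)
  structure(list(exposure_p_threshold = exposure_p_threshold,
                 outcome_p_threshold = outcome_p_threshold,
                 clump_r2 = clump_r2, clump_window_kb = clump_window_kb,
                 f_threshold = f_threshold,
                 confounder_snps = as.character(confounder_snps)),
            class = "selection_config")
}

#' Per-SNP instrument strength (F-statistic)
#'
#' Computes the variance in the exposure explained by each SNP,
#' R² = 2·MAF·(1−MAF)·β², and the corresponding F-statistic
#' F = (R²/(1−R²))·((n−k−1)/k) with k = 1 instrument per SNP, the standard
#' single-instrument form. SNPs are retained iff F is strictly greater than
#' `f_threshold`; F = 10 exactly is not retained.
#'
#' Assumes `beta` is on a standardized scale (as microbiome-consortium
#' summary statistics report); this is documented, not enforced.
#'
#' @param beta per-allele effect estimate(s).
#' @param eaf effect-allele frequency in (0, 1); a frequency of exactly 0 or
#'   1 yields R² = 0, F = 0, not retained.
#' @param n exposure GWAS sample size.
#' @param k number of instruments attributed to the statistic (default 1).
#' @param f_threshold strength cutoff (default 10).
#' @param snp_id optional ids carried into the result.
#' @return data frame with columns `snp_id` (if given), `r2`, `f`,
#'   `retained`.
#' @examples
#' f_statistic(0.1, 0.5, 18340)  # R2 = 0.005, F = 92.15
#' @export
f_statistic <- function(beta, eaf, n, k = 1, f_threshold = 10, snp_id = NULL) {
  stopifnot(all(eaf >= 0 & eaf <= 1), all(n > k + 1), k >= 1)
  maf <- pmin(eaf, 1 - eaf)
  r2 <- 2 * maf * (1 - maf) * beta^2
  if (any(r2 >= 1)) stop("variance explained not below 1")
  f <- (r2 / (1 - r2)) * ((n - k - 1) / k)
  out <- data.frame(r2 = r2, f = f, retained = f > f_threshold)
  if (!is.null(snp_id)) out <- cbind(data.frame(snp_id = as.character(snp_id),
                                                stringsAsFactors = FALSE), out)
  out
}

iv_set <- function(exposure_name, snp_ids, selection_log) {
  structure(list(exposure_name = exposure_name,
                 snp_ids = as.character(snp_ids),
                 selection_log = selection_log),
            class = "iv_set")
}

#' @export
print.iv_set <- function(x, ...) {
  cat(sprintf("Instrument set for %s: %d SNPs\n", x$exposure_name,
              length(x$snp_ids)))
  print(x$selection_log, row.names = FALSE)
  invisible(x)
}

log_step <- function(log, step, removed, remaining, detail = "") {
  rbind(log, data.frame(step = step, removed = removed, remaining = remaining,
                        detail = detail, stringsAsFactors = FALSE))
}

#' Remove confounder-associated SNPs from an instrument set
#'
#' Drops instruments that a confounder lookup has linked to known risk
#' factors of the outcome, to avoid horizontal pleiotropy; removals are
#' appended to the selection log with the offending ids.
#'
#' @param ivs an `iv_set` as returned by [select_ivs()].
#' @param confounders character vector of SNP ids to exclude.
#' @return The pruned `iv_set`.
#' @export
exclude_confounder_snps <- function(ivs, confounders) {
  stopifnot(inherits(ivs, "iv_set"))
  hit <- intersect(ivs$snp_ids, confounders)
  keep <- setdiff(ivs$snp_ids, confounders)
  log <- log_step(ivs$selection_log, "confounder_exclusion",
                  length(hit), length(keep),
                  if (length(hit)) paste(hit, collapse = ",") else "")
  iv_set(ivs$exposure_name, keep, log)
}

#' Select instrumental variables for one exposure
#'
#' Applies the four selection criteria in order: (1) exposure association
#' p < `exposure_p_threshold`; (2) LD clumping at `clump_r2` within
#' `clump_window_kb`; (3) harmonization with the outcome followed by removal
#' of SNPs with outcome p <= `outcome_p_threshold` (instruments must not be
#' associated with the outcome); (4) instrument strength F >
#' `f_threshold`; finally any confounder-listed SNPs are removed. Every
#' step's removal count is recorded in the selection log.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param ld an [ld_info()] table.
#' @param cfg a [selection_config()].
#' @return list with elements `ivs` (an `iv_set`) and `harmonized` (the
#'   [harmonize()]d rows restricted to the final instruments). If no SNP
#'   survives, `ivs$snp_ids` is empty and the result carries attribute
#'   `no_iv = TRUE` so callers can skip the exposure rather than crash.
#' @export
select_ivs <- function(exposure, outcome, ld, cfg = selection_config()) {
  stopifnot(inherits(cfg, "selection_config"))
  if (nrow(exposure) == 0) stop("exposure table is empty")
  log <- data.frame(step = character(), removed = integer(),
                    remaining = integer(), detail = character(),
                    stringsAsFactors = FALSE)
  n0 <- nrow(exposure)
  log <- log_step(log, "input", 0L, n0)

  sig <- exposure[exposure$pval < cfg$exposure_p_threshold, , drop = FALSE]
  sig <- structure(sig, trait_name = trait_name(exposure),
                   trait_type = trait_type(exposure),
                   rejected = attr(exposure, "rejected"),
                   class = c("gwas_table", "data.frame"))
  log <- log_step(log, "exposure_pvalue", n0 - nrow(sig), nrow(sig))

  finish <- function(snp_ids, h, log) {
    res <- list(ivs = iv_set(trait_name(exposure), snp_ids, log),
                harmonized = h)
    attr(res, "no_iv") <- length(snp_ids) == 0
    res
  }
  empty_h <- harmonized_set(character(0), numeric(0), numeric(0), numeric(0),
                            numeric(0), exposure_name = trait_name(exposure),
                            outcome_name = trait_name(outcome))
  if (nrow(sig) == 0) return(finish(character(0), empty_h, log))

  cl <- clump(sig, ld, cfg$clump_r2, cfg$clump_window_kb)
  log <- log_step(log, "ld_clump", nrow(sig) - nrow(cl), nrow(cl))

  h <- harmonize(cl, outcome)
  log <- log_step(log, "harmonize", nrow(cl) - nrow(h), nrow(h),
                  sprintf("palindromic=%d,incompatible=%d,unshared=%d",
                          attr(h, "n_dropped_palindromic"),
                          attr(h, "n_dropped_incompatible"),
                          nrow(cl) - nrow(h) -
                            attr(h, "n_dropped_palindromic") -
                            attr(h, "n_dropped_incompatible")))
  if (nrow(h) == 0) return(finish(character(0), h, log))

  keep <- h$pval_out > cfg$outcome_p_threshold
  log <- log_step(log, "outcome_pvalue", sum(!keep), sum(keep))
  h <- h[keep, , drop = FALSE]
  if (nrow(h) == 0) return(finish(character(0), h, log))

  fs <- f_statistic(h$beta_exp, h$eaf_exp, h$n_exp,
                    f_threshold = cfg$f_threshold, snp_id = h$snp_id)
  log <- log_step(log, "instrument_strength", sum(!fs$retained),
                  sum(fs$retained))
  h <- h[fs$retained, , drop = FALSE]
  if (nrow(h) == 0) return(finish(character(0), h, log))

  ivs <- iv_set(trait_name(exposure), h$snp_id, log)
  ivs <- exclude_confounder_snps(ivs, cfg$confounder_snps)
  h <- h[h$snp_id %in% ivs$snp_ids, , drop = FALSE]
  rownames(h) <- NULL
  finish(ivs$snp_ids, h, ivs$selection_log)
}
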