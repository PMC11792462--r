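allele_complement <- function(x) chartr("ACGT", "TGCA", x)

is_palindromic <- function(ea, oa) ea == allele_complement(oa)

#' Align outcome effects to the exposure's effect alleles
#'
#' Restricts two summary-statistics tables to their shared SNPs and orients
#' the outcome effects onto the exposure's effect-allele coding, the step
#' that makes per-SNP (beta_exposure, beta_outcome) pairs interpretable as
#' instrument-outcome associations for MR.
#'
#' Orientation rules per SNP:
#' * identical effect/other alleles (possibly after a strand flip for
#'   non-palindromic SNPs): outcome beta kept as is;
#' * swapped alleles: outcome beta negated, frequency complemented;
#' * palindromic SNPs (A/T or C/G) cannot be resolved by allele letters.
#'   If either table's effect-allele frequency lies within
#'   `palindrome_freq_window` of 0.5 the SNP is ambiguous and dropped.
#'   Otherwise, under `action = "infer"` the orientation is fixed by
#'   matching minor-allele status between the two tables; under
#'   `action = "drop_palindromic"` all palindromic SNPs are dropped.
#' * allele sets that cannot be reconciled at all (e.g. A/G vs A/C) are
#'   dropped and counted as incompatible.
#'
#' @param exposure,outcome [gwas_table()] objects.
#' @param palindrome_freq_window half-width of the ambiguity window around
#'   frequency 0.5 (default 0.08, i.e. eaf in \[0.42, 0.58\] is ambiguous).
#' @param action `"infer"` (frequency-based orientation of unambiguous
#'   palindromic SNPs) or `"drop_palindromic"`.
#' @return A `harmonized_set`: data frame with columns `snp_id`, `beta_exp`,
#'   `se_exp`, `pval_exp`, `eaf_exp`, `n_exp`, `beta_out`, `se_out`,
#'   `pval_out`, sorted by `snp_id`, with attributes `exposure_name`,
#'   `outcome_name`, `n_dropped_palindromic`, `n_dropped_incompatible`. If
#'   no SNPs overlap, an empty set flagged with attribute `no_overlap`.
#' @export
harmonize <- function(exposure, outcome, palindrome_freq_window = 0.08,
                      action = c("infer", "drop_palindromic")) {
  action <- match.arg(action)
  stopifnot(inherits(exposure, "gwas_table"), inherits(outcome, "gwas_table"))
  if (nrow(exposure) == 0 || nrow(outcome) == 0)
    stop("both tables must be nonempty")
  if (palindrome_freq_window < 0 || palindrome_freq_window >= 0.5)
    stop("palindrome_freq_window must lie in [0, 0.5)")

  shared <- intersect(exposure$snp_id, outcome$snp_id)
  e <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  o <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  n_pal <- 0L
  n_inc <- 0L
  keep <- logical(length(shared))
  beta_out <- eaf_out <- numeric(length(shared))

  for (i in seq_along(shared)) {
    ee <- e$effect_allele[i]; eo <- e$other_allele[i]
    oe <- o$effect_allele[i]; oo <- o$other_allele[i]
    pal <- is_palindromic(ee, eo)
    b <- o$beta[i]; f <- o$eaf[i]
    if (pal) {
      if (!is_palindromic(oe, oo) || !setequal(c(oe, oo), c(ee, eo))) {
        n_inc <- n_inc + 1L
        next
      }
      if (action == "drop_palindromic" ||
          abs(e$eaf[i] - 0.5) <= palindrome_freq_window ||
          abs(f - 0.5) <= palindrome_freq_window) {
        n_pal <- n_pal + 1L
        next
      }
      # letter alignment first, then fix strand by minor-allele concordance
      if (oe == eo) { b <- -b; f <- 1 - f }
      if ((f - 0.5) * (e$eaf[i] - 0.5) < 0) { b <- -b; f <- 1 - f }
    } else {
      if (oe == ee && oo == eo) {
        # aligned
      } else if (oe == eo && oo == ee) {
        b <- -b; f <- 1 - f
      } else if (allele_complement(oe) == ee && allele_complement(oo) == eo) {
        # opposite strand, same orientation
      } else if (allele_complement(oe) == eo && allele_complement(oo) == ee) {
        b <- -b; f <- 1 - f
      } else {
        n_inc <- n_inc + 1L
        next
      }
    }
    keep[i] <- TRUE
    beta_out[i] <- b
    eaf_out[i] <- f
  }

  rows <- data.frame(snp_id = shared[keep],
                     beta_exp = e$beta[keep], se_exp = e$se[keep],
                     pval_exp = e$pval[keep], eaf_exp = e$eaf[keep],
                     n_exp = e$n[keep],
                     beta_out = beta_out[keep], se_out = o$se[keep],
                     pval_out = o$pval[keep],
                     stringsAsFactors = FALSE)
  rows <- rows[order(rows$snp_id), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows,
            exposure_name = trait_name(exposure),
            outcome_name = trait_name(outcome),
            n_dropped_palindromic = n_pal,
            n_dropped_incompatible = n_inc,
            no_overlap = length(shared) == 0,
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulations and tests where the per-SNP
#' exposure and outcome effects are already on the same allele coding.
#'
#' @param snp_id,beta_exp,se_exp,beta_out,se_out aligned per-SNP vectors.
#' @param eaf_exp,pval_exp,pval_out,n_exp optional extra columns.
#' @param exposure_name,outcome_name trait labels.
#' @return A `harmonized_set` (see [harmonize()]).
#' @export
harmonized_set <- function(snp_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, pval_exp = NA_real_,
                           pval_out = NA_real_, n_exp = NA_real_,
                           exposure_name = "exposure", outcome_name = "outcome") {
  stopifnot(all(se_exp > 0), all(se_out > 0), !anyDuplicated(snp_id))
  n <- length(snp_id)
  rows <- data.frame(snp_id = as.character(snp_id),
                     beta_exp = beta_exp, se_exp = se_exp,
                     pval_exp = rep_len(pval_exp, n),
                     eaf_exp = rep_len(eaf_exp, n),
                     n_exp = rep_len(n_exp, n),
                     beta_out = beta_out, se_out = se_out,
                     pval_out = rep_len(pval_out, n),
                     stringsAsFactors = FALSE)
  rows <- rows[order(rows$snp_id), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, exposure_name = exposure_name, outcome_name = outcome_name,
            n_dropped_palindromic = 0L, n_dropped_incompatible = 0L,
            no_overlap = nrow(rows) == 0,
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set %s -> %s: %d SNPs (%d palindromic, %d incompatible dropped)\n",
              attr(x, "exposure_name"), attr(x, "outcome_name"), nrow(x),
              attr(x, "n_dropped_palindromic"), attr(x, "n_dropped_incompatible")))
  print(utils::head(as.data.frame(x), 10), ...)
  invisible(x)
}
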