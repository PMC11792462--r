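#' Greedy LD clumping of a summary-statistics table
#'
#' Prunes SNPs so that retained instruments are approximately independent:
#' records are ranked by association p-value (ties broken by chromosome,
#' position, then SNP id, making the result deterministic and independent of
#' input order) and a record is retained iff its r² with every
#' already-retained record on the same chromosome within `window_kb`
#' kilobases is below `r2_threshold`.
#'
#' SNP pairs inside the window with no entry in `ld` are treated as
#' independent (r² = 0) and counted in the `"n_ld_missing"` attribute of the
#' result.
#'
#' @param table a [gwas_table()].
#' @param ld an [ld_info()] pairwise r² table.
#' @param r2_threshold clumping threshold in (0, 1\] (default 0.001).
#' @param window_kb window size in kilobases (default 10000, i.e. 10 Mb).
#' @return A [gwas_table()] of retained records, in selection (p-value)
#'   order, with attribute `n_ld_missing`.
#' @export
clump <- function(table, ld, r2_threshold = 0.001, window_kb = 10000) {
  stopifnot(inherits(table, "gwas_table"), inherits(ld, "ld_info"))
  if (r2_threshold <= 0 || r2_threshold > 1) stop("r2_threshold must be in (0,1]")
  if (window_kb <= 0) stop("window_kb must be positive")
  if (nrow(table) == 0) return(structure(table, n_ld_missing = 0L))

  ord <- order(table$pval, table$chrom, table$pos, table$snp_id)
  x <- as.data.frame(table)[ord, , drop = FALSE]
  window_bp <- window_kb * 1000

  retained <- integer(0)
  n_missing <- 0L
  for (i in seq_len(nrow(x))) {
    ok <- TRUE
    for (j in retained) {
      if (x$chrom[j] != x$chrom[i]) next
      if (abs(x$pos[j] - x$pos[i]) > window_bp) next
      r2 <- ld_r2(ld, x$snp_id[i], x$snp_id[j], default = NA)
      if (is.na(r2)) {
        n_missing <- n_missing + 1L
        r2 <- 0
      }
      if (r2 >= r2_threshold) { ok <- FALSE; break }
    }
    if (ok) retained <- c(retained, i)
  }

  out <- x[retained, , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            trait_name = trait_name(table), trait_type = trait_type(table),
            rejected = attr(table, "rejected"), n_ld_missing = n_missing,
            class = c("gwas_table", "data.frame"))
}
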