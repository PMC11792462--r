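#' GWAS summary-statistics table
#'
#' A `gwas_table` is a data frame of per-SNP association summary statistics
#' for one trait, the basic currency of two-sample Mendelian randomization.
#' Each row holds the variant identifier, genomic location, effect and other
#' allele, effect-allele frequency, effect estimate (log-odds for binary
#' traits, standardized units for quantitative traits), its standard error,
#' the association p-value and the sample size.
#'
#' Rows violating the record invariants (non-ACGT or identical alleles,
#' non-positive SE, frequency outside \[0, 1\], p-value outside (0, 1\],
#' non-positive n) are removed, counted, and kept with a reason in the
#' `"rejected"` attribute — never silently dropped.
#'
#' @param data data frame with columns `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#' @param trait_name character scalar naming the trait.
#' @param trait_type `"quantitative"` or `"binary"`.
#' @return A `gwas_table`: the validated data frame with attributes
#'   `trait_name`, `trait_type` and `rejected` (a data frame of dropped rows
#'   with a `reason` column).
#' @examples
#' d <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1", pos = c(1e5, 2e5),
#'                 effect_allele = c("A", "C"), other_allele = c("G", "T"),
#'                 eaf = c(0.3, 0.4), beta = c(0.1, -0.05),
#'                 se = c(0.01, 0.02), pval = c(1e-8, 0.01), n = 10000)
#' gwas_table(d, "trait", "quantitative")
#' @export
gwas_table <- function(data, trait_name, trait_type = c("quantitative", "binary")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "pval", "n")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0)
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  data <- as.data.frame(data)[required]
  data$snp_id <- as.character(data$snp_id)
  data$chrom <- as.character(data$chrom)
  data$effect_allele <- toupper(as.character(data$effect_allele))
  data$other_allele <- toupper(as.character(data$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pval", "n"))
    data[[col]] <- as.numeric(data[[col]])

  dup <- duplicated(data$snp_id)
  if (any(dup))
    stop("duplicate snp_id: ", data$snp_id[which(dup)[1]])

  reason <- rep(NA_character_, nrow(data))
  bad_allele <- !(data$effect_allele %in% c("A", "C", "G", "T")) |
    !(data$other_allele %in% c("A", "C", "G", "T")) |
    data$effect_allele == data$other_allele
  reason[is.na(reason) & bad_allele] <- "invalid alleles"
  reason[is.na(reason) & (!is.finite(data$se) | data$se <= 0)] <- "nonpositive se"
  reason[is.na(reason) & (!is.finite(data$eaf) | data$eaf < 0 | data$eaf > 1)] <- "eaf outside [0,1]"
  reason[is.na(reason) & (!is.finite(data$pval) | data$pval <= 0 | data$pval > 1)] <- "pval outside (0,1]"
  reason[is.na(reason) & (!is.finite(data$beta))] <- "nonfinite beta"
  reason[is.na(reason) & (!is.finite(data$n) | data$n <= 0)] <- "nonpositive n"

  bad <- !is.na(reason)
  rejected <- data[bad, , drop = FALSE]
  if (nrow(rejected) > 0) rejected$reason <- reason[bad]
  else rejected$reason <- character(0)
  out <- data[!bad, , drop = FALSE]
  rownames(out) <- NULL
  rownames(rejected) <- NULL
  structure(out,
            trait_name = trait_name,
            trait_type = trait_type,
            rejected = rejected,
            class = c("gwas_table", "data.frame"))
}

#' @export
print.gwas_table <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s (%s), %d SNPs, %d rejected rows\n",
              attr(x, "trait_name"), attr(x, "trait_type"), nrow(x),
              nrow(attr(x, "rejected"))))
  print(utils::head(as.data.frame(x), 10), ...)
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

trait_name <- function(x) attr(x, "trait_name")
trait_type <- function(x) attr(x, "trait_type")

# Default header aliases for summary-statistics files (left: internal name).
default_aliases <- function() {
  list(snp_id = c("SNP", "RSID", "ID", "SNP_ID", "VARIANT_ID"),
       chrom = c("CHR", "CHROM", "CHROMOSOME"),
       pos = c("POS", "BP", "POSITION", "BASE_PAIR_LOCATION"),
       effect_allele = c("EA", "EFFECT_ALLELE", "A1", "ALT"),
       other_allele = c("OA", "OTHER_ALLELE", "A2", "REF", "NON_EFFECT_ALLELE"),
       eaf = c("EAF", "EFFECT_ALLELE_FREQUENCY", "FREQ", "AF", "MAF"),
       beta = c("BETA", "B", "EFFECT"),
       se = c("SE", "STANDARD_ERROR", "STDERR"),
       pval = c("P", "PVAL", "P_VALUE", "PVALUE"),
       n = c("N", "SAMPLE_SIZE", "NSAMPLES"))
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Expects a UTF-8, tab-separated file with a header row naming at least the
#' ten standard summary-statistics columns (`SNP, CHR, POS, EA, OA, EAF,
#' BETA, SE, P, N` by default; alternative spellings configurable through
#' `aliases`). Malformed data rows are retained in the table's `"rejected"`
#' attribute with a reason.
#'
#' @param path path to the file.
#' @param trait_name,trait_type passed to [gwas_table()].
#' @param aliases named list mapping each internal column name to the header
#'   spellings accepted for it (case-insensitive); defaults cover common
#'   GWAS-catalog style headers.
#' @return A [gwas_table()].
#' @export
read_gwas <- function(path, trait_name, trait_type = c("quantitative", "binary"),
                      aliases = default_aliases()) {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (nrow(raw) == 0) stop("empty file: ", path)
  hdr <- toupper(names(raw))
  out <- list()
  for (field in names(aliases)) {
    hit <- which(hdr %in% toupper(aliases[[field]]))
    if (length(hit) == 0)
      stop("missing mandatory column for '", field, "' (accepted: ",
           paste(aliases[[field]], collapse = ", "), ")")
    out[[field]] <- raw[[hit[1]]]
  }
  gwas_table(as.data.frame(out, stringsAsFactors = FALSE), trait_name, trait_type)
}

#' Write GWAS summary statistics to a tab-separated file
#'
#' Inverse of [read_gwas()]: writes the canonical ten-column header
#' `SNP CHR POS EA OA EAF BETA SE P N`. Numeric columns are written with
#' enough digits for a faithful round trip.
#'
#' @param x a [gwas_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gwas <- function(x, path) {
  stopifnot(inherits(x, "gwas_table"))
  out <- data.frame(SNP = x$snp_id, CHR = x$chrom, POS = format(x$pos, scientific = FALSE, trim = TRUE),
                    EA = x$effect_allele, OA = x$other_allele,
                    EAF = format(x$eaf, digits = 15, trim = TRUE),
                    BETA = format(x$beta, digits = 15, trim = TRUE),
                    SE = format(x$se, digits = 15, trim = TRUE),
                    P = format(x$pval, digits = 15, trim = TRUE),
                    N = format(x$n, scientific = FALSE, trim = TRUE),
                    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise linkage-disequilibrium table
#'
#' Holds r-squared values for SNP pairs; pairs absent from the table are
#' treated as r² = 0 (independent). Symmetry and r²(x, x) = 1 are implied by
#' the unordered-pair representation.
#'
#' @param pairs data frame with columns `snp_a`, `snp_b`, `r2` (or a
#'   three-column data frame in that order).
#' @return An `ld_info` object.
#' @export
ld_info <- function(pairs = NULL) {
  if (is.null(pairs) || nrow(pairs) == 0) {
    map <- numeric(0)
  } else {
    pairs <- as.data.frame(pairs)
    if (!all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
      names(pairs)[1:3] <- c("snp_a", "snp_b", "r2")
    r2 <- as.numeric(pairs$r2)
    if (any(!is.finite(r2) | r2 < 0 | r2 > 1))
      stop("r2 values must lie in [0,1]")
    key <- pair_key(as.character(pairs$snp_a), as.character(pairs$snp_b))
    map <- setNames(r2, key)
    map <- map[!duplicated(names(map))]
  }
  structure(list(map = map), class = "ld_info")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Look up pairwise r-squared values
#'
#' @param ld an [ld_info()] object.
#' @param a,b character vectors of SNP ids (recycled).
#' @param default value returned for absent pairs (`NA` to detect missing
#'   entries, `0` to treat them as independent).
#' @return numeric vector of r² values; identical ids give 1.
#' @export
ld_r2 <- function(ld, a, b, default = 0) {
  stopifnot(inherits(ld, "ld_info"))
  key <- pair_key(as.character(a), as.character(b))
  out <- unname(ld$map[key])
  out[a == b] <- 1
  out[is.na(out) & a != b] <- default
  out
}

#' Read a pairwise LD table from a three-column file
#'
#' @param path tab-separated file with columns `SNP_A`, `SNP_B`, `R2`.
#' @return An [ld_info()] object.
#' @export
read_ld <- function(path) {
  raw <- read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("snp_a", "snp_b", "r2") %in% names(raw)))
    stop("LD file must have columns SNP_A, SNP_B, R2")
  ld_info(raw)
}

#' Write a pairwise LD table
#'
#' @param ld an [ld_info()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld <- function(ld, path) {
  stopifnot(inherits(ld, "ld_info"))
  key <- names(ld$map)
  if (length(key) == 0) {
    writeLines("SNP_A\tSNP_B\tR2", path)
    return(invisible(path))
  }
  parts <- strsplit(key, "\r", fixed = TRUE)
  out <- data.frame(SNP_A = vapply(parts, `[`, "", 1),
                    SNP_B = vapply(parts, `[`, "", 2),
                    R2 = format(unname(ld$map), digits = 15, trim = TRUE))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
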