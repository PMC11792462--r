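# Independent oracles, deliberately written along different code paths from
# the package implementations they check.

# Weighted least squares via explicit normal equations on the raw matrices.
oracle_wls <- function(X, y, w) {
  X <- as.matrix(X)
  A <- matrix(0, ncol(X), ncol(X))
  b <- numeric(ncol(X))
  for (i in seq_len(nrow(X))) {
    A <- A + w[i] * (X[i, ] %o% X[i, ])
    b <- b + w[i] * X[i, ] * y[i]
  }
  coef <- solve(A, b)
  res <- y - X %*% coef
  list(coef = as.numeric(coef), cov_unscaled = solve(A), residuals = as.numeric(res))
}

# Weighted median by stepping through the sorted ratios and interpolating at
# cumulative standardized weight 1/2.
oracle_weighted_median <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- 0
  s_prev <- NA_real_
  r_prev <- NA_real_
  for (i in seq_along(r)) {
    s_i <- cum + w[i] / 2
    if (s_i >= 0.5) {
      if (i == 1) return(r[1])
      return(r_prev + (r[i] - r_prev) * (0.5 - s_prev) / (s_i - s_prev))
    }
    cum <- cum + w[i]
    s_prev <- s_i
    r_prev <- r[i]
  }
  r[length(r)]
}

# Brute-force greedy clumping over explicit pair checks.
oracle_clump_ids <- function(df, ld_pairs, r2_threshold, window_kb) {
  df <- df[order(df$pval, df$chrom, df$pos, df$snp_id), ]
  lookup <- function(a, b) {
    hit <- (ld_pairs$snp_a == a & ld_pairs$snp_b == b) |
      (ld_pairs$snp_a == b & ld_pairs$snp_b == a)
    if (any(hit)) ld_pairs$r2[which(hit)[1]] else 0
  }
  kept <- character(0)
  for (i in seq_len(nrow(df))) {
    ok <- TRUE
    for (k in kept) {
      j <- which(df$snp_id == k)
      if (df$chrom[j] == df$chrom[i] &&
          abs(df$pos[j] - df$pos[i]) <= window_kb * 1000 &&
          lookup(df$snp_id[i], k) >= r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, df$snp_id[i])
  }
  kept
}

pair_key_test <- function(a, b) paste(pmin(a, b), pmax(a, b))

# Single summary-statistics row with sensible defaults.
toy_row <- function(snp_id, pval = 1e-8, beta = 0.15, chrom = "1",
                    pos = 1e6, eaf = 0.3, se = 0.02, n = 10000) {
  data.frame(snp_id = snp_id, chrom = chrom, pos = pos, effect_allele = "A",
             other_allele = "G", eaf = eaf, beta = beta, se = se,
             pval = pval, n = n, stringsAsFactors = FALSE)
}

# Minimal well-formed summary-statistics data frame for constructing tables.
toy_gwas_df <- function(n = 5, seed = 1) {
  set.seed(seed)
  data.frame(snp_id = sprintf("rs%03d", seq_len(n)),
             chrom = as.character(rep(1:22, length.out = n)),
             pos = 1e6 + seq_len(n) * 2e7,
             effect_allele = rep(c("A", "C", "G", "T", "A"), length.out = n),
             other_allele = rep(c("G", "T", "A", "C", "C"), length.out = n),
             eaf = runif(n, 0.05, 0.45),
             beta = rnorm(n, 0, 0.1),
             se = runif(n, 0.005, 0.02),
             pval = runif(n, 1e-9, 0.5),
             n = 18340,
             stringsAsFactors = FALSE)
}

# Harmonized set with effects drawn around a true causal slope.
toy_harmonized <- function(n = 10, beta_true = 0.5, se_out = 0.1,
                           se_exp = 0.01, seed = 1) {
  set.seed(seed)
  bx <- rnorm(n, 0.3, 0.1)
  harmonized_set(sprintf("rs%03d", seq_len(n)),
                 beta_exp = bx, se_exp = rep(se_exp, n),
                 beta_out = rnorm(n, beta_true * bx, se_out),
                 se_out = rep(se_out, n))
}
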