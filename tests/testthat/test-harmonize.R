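mk_table <- function(name, df) gwas_table(df, name, "quantitative")

base_row <- function(snp_id, ea, oa, eaf, beta, pval = 0.5) {
  data.frame(snp_id = snp_id, chrom = "1", pos = 1e6, effect_allele = ea,
             other_allele = oa, eaf = eaf, beta = beta, se = 0.1,
             pval = pval, n = 10000, stringsAsFactors = FALSE)
}

test_that("matching, swapped and strand-flipped alleles are aligned", {
  exp <- mk_table("e", rbind(
    base_row("rs1", "A", "G", 0.3, 0.10),   # identical coding
    base_row("rs2", "A", "G", 0.3, 0.10),   # outcome swapped
    base_row("rs3", "A", "G", 0.3, 0.10),   # outcome on other strand
    base_row("rs4", "A", "G", 0.3, 0.10)))  # other strand and swapped
  out <- mk_table("o", rbind(
    base_row("rs1", "A", "G", 0.3, 0.05),
    base_row("rs2", "G", "A", 0.7, 0.05),
    base_row("rs3", "T", "C", 0.3, 0.05),
    base_row("rs4", "C", "T", 0.7, 0.05)))
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 4)
  expect_equal(h$beta_out, c(0.05, -0.05, 0.05, -0.05))
  expect_equal(h$beta_exp, rep(0.10, 4))
  expect_equal(attr(h, "n_dropped_incompatible"), 0L)
})

test_that("ambiguous palindromic SNPs are dropped and counted", {
  exp <- mk_table("e", rbind(base_row("rs1", "A", "T", 0.50, 0.1),
                             base_row("rs2", "C", "G", 0.30, 0.1)))
  out <- mk_table("o", rbind(base_row("rs1", "A", "T", 0.50, 0.05),
                             base_row("rs2", "C", "G", 0.30, 0.05)))
  h <- harmonize(exp, out)
  expect_equal(h$snp_id, "rs2")
  expect_equal(attr(h, "n_dropped_palindromic"), 1L)
  # frequencies inside the window are ambiguous, outside are usable
  exp2 <- mk_table("e", base_row("rs3", "A", "T", 0.45, 0.1))
  out2 <- mk_table("o", base_row("rs3", "A", "T", 0.45, 0.05))
  expect_equal(nrow(harmonize(exp2, out2)), 0)
  exp3 <- mk_table("e", base_row("rs3", "A", "T", 0.40, 0.1))
  out3 <- mk_table("o", base_row("rs3", "A", "T", 0.40, 0.05))
  expect_equal(nrow(harmonize(exp3, out3)), 1)
  # drop_palindromic removes them all regardless of frequency
  h3 <- harmonize(exp, out, action = "drop_palindromic")
  expect_equal(nrow(h3), 0)
  expect_equal(attr(h3, "n_dropped_palindromic"), 2L)
})

test_that("unambiguous palindromic SNPs are oriented by minor-allele status", {
  # reported on opposite strands: letters look swapped but frequencies agree
  exp <- mk_table("e", base_row("rs1", "A", "T", 0.2, 0.1))
  out <- mk_table("o", base_row("rs1", "T", "A", 0.2, 0.05))
  h <- harmonize(exp, out)
  expect_equal(h$beta_out, 0.05)
  # genuinely swapped effect allele: frequency complements
  out2 <- mk_table("o", base_row("rs1", "T", "A", 0.8, 0.05))
  h2 <- harmonize(exp, out2)
  expect_equal(h2$beta_out, -0.05)
})

test_that("incompatible allele sets are excluded and counted", {
  exp <- mk_table("e", rbind(base_row("rs1", "A", "G", 0.3, 0.1),
                             base_row("rs2", "A", "G", 0.3, 0.1)))
  out <- mk_table("o", rbind(base_row("rs1", "A", "C", 0.3, 0.05),
                             base_row("rs2", "A", "G", 0.3, 0.05)))
  h <- harmonize(exp, out)
  expect_equal(h$snp_id, "rs2")
  expect_equal(attr(h, "n_dropped_incompatible"), 1L)
})

test_that("zero overlap yields a structured empty result", {
  exp <- mk_table("e", base_row("rs1", "A", "G", 0.3, 0.1))
  out <- mk_table("o", base_row("rs2", "A", "G", 0.3, 0.05))
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 0)
  expect_true(attr(h, "no_overlap"))
})

test_that("harmonization is idempotent", {
  sim <- simulate_summary_dataset(sim_config(n_snp = 60, causal_total = 0.2,
                                             seed = 9))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild both tables on the exposure's allele coding and harmonize again
  ex <- as.data.frame(sim$exposure)
  ex <- ex[match(h1$snp_id, ex$snp_id), ]
  ou <- ex
  ou$beta <- h1$beta_out
  ou$se <- h1$se_out
  ou$pval <- h1$pval_out
  h2 <- harmonize(gwas_table(ex, "e", "quantitative"),
                  gwas_table(ou, "o", "quantitative"))
  expect_equal(h2$snp_id, h1$snp_id)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(h2$beta_exp, h1$beta_exp)
  expect_equal(attr(h2, "n_dropped_palindromic") +
                 attr(h2, "n_dropped_incompatible"), 0L)
})

test_that("scrambled simulated outcomes are restored to the true effects", {
  # with a strong causal effect and tiny outcome noise the aligned outcome
  # betas must track beta_true * beta_exp; a single mis-oriented SNP would
  # show up as a sign error of order 1
  cfg <- sim_config(n_snp = 200, causal_total = 1, n_outcome = 5e6,
                    case_fraction = 0.4, palindromic_frac = 0.3,
                    swap_frac = 0.5, strand_frac = 0.5, seed = 21)
  sim <- simulate_summary_dataset(cfg)
  h <- harmonize(sim$exposure, sim$outcome)
  expect_gt(nrow(h), 150)
  expect_true(all(abs(h$beta_out - h$beta_exp) < 0.05))
})
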