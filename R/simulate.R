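#' Simulation configuration for summary-level GWAS triples
#'
#' Describes a synthetic exposure / mediator / outcome system mirroring the
#' structure of a microbiome-metabolite-disease MR study: a panel of
#' instruments with realistic allele frequencies, per-SNP exposure effects,
#' an exposure -> mediator -> outcome causal chain with configurable direct
#' and indirect components, a rare binary outcome, optional balanced or
#' directional pleiotropy, and optional LD blocks for clumping tests.
#'
#' The default sample sizes and outcome prevalence mirror the study design
#' the generator emulates: 18,340 individuals for the microbiome exposure,
#' 8,299 for the plasma-metabolite mediator, and 247,540 for the disease
#' outcome with 261 cases (case fraction about 0.00105).
#'
#' When `causal_alpha`, `causal_beta2` and `causal_direct` are all given,
#' the total effect is enforced as
#' `causal_total = causal_direct + causal_alpha * causal_beta2`; supplying
#' an inconsistent `causal_total` as well is an error.
#'
#' @param n_snp number of exposure-instrument SNPs (default 30).
#' @param n_snp_mediator number of mediator-specific instrument SNPs added
#'   in mediation datasets (default `n_snp`).
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes.
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param gamma_sd SD of per-SNP exposure effects (standardized scale).
#' @param eta_sd SD of mediator-specific per-SNP effects.
#' @param causal_total true total exposure -> outcome effect (log-odds per
#'   exposure SD); default 0.
#' @param causal_alpha true exposure -> mediator effect.
#' @param causal_beta2 true mediator -> outcome effect.
#' @param causal_direct true direct exposure -> outcome effect.
#' @param pleiotropy_frac fraction of SNPs with direct outcome effects.
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of pleiotropic effects,
#'   defined relative to the exposure-increasing allele (a nonzero mean
#'   gives directional pleiotropy; zero mean, balanced).
#' @param case_fraction outcome prevalence in (0, 0.5); default 261/247540.
#' @param ld_blocks `NULL` for an independent panel, or
#'   `list(n_blocks =, r2 =)` to group SNPs into LD blocks with the given
#'   within-block r².
#' @param palindromic_frac,swap_frac,strand_frac fractions of SNPs given
#'   palindromic alleles, allele-swapped outcome records, and strand-flipped
#'   outcome records, to exercise harmonization.
#' @param seed integer root seed; per-table sub-streams are derived from it
#'   so adding a table does not perturb existing draws.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snp = 30, n_snp_mediator = n_snp,
                       n_exposure = 18340, n_mediator = 8299,
                       n_outcome = 247540,
                       maf_range = c(0.05, 0.5), gamma_sd = 0.1,
                       eta_sd = 0.15,
                       causal_total = 0, causal_alpha = NULL,
                       causal_beta2 = NULL, causal_direct = NULL,
                       pleiotropy_frac = 0, pleiotropy_mean = 0,
                       pleiotropy_sd = 0.05,
                       case_fraction = 261 / 247540,
                       ld_blocks = NULL,
                       palindromic_frac = 0.1, swap_frac = 0.2,
                       strand_frac = 0.1, seed = 1) {
  stopifnot(n_snp >= 1, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            pleiotropy_frac >= 0, pleiotropy_frac <= 1,
            case_fraction > 0, case_fraction < 0.5)
  chain <- c(!is.null(causal_alpha), !is.null(causal_beta2),
             !is.null(causal_direct))
  if (all(chain)) {
    implied <- causal_direct + causal_alpha * causal_beta2
    if (!is.null(causal_total) && !missing(causal_total) &&
        abs(causal_total - implied) > 1e-12)
      stop("inconsistent causal chain: causal_total must equal ",
           "causal_direct + causal_alpha * causal_beta2")
    causal_total <- implied
  }
  structure(list(n_snp = n_snp, n_snp_mediator = n_snp_mediator,
                 n_exposure = n_exposure, n_mediator = n_mediator,
                 n_outcome = n_outcome, maf_range = maf_range,
                 gamma_sd = gamma_sd, eta_sd = eta_sd,
                 causal_total = causal_total, causal_alpha = causal_alpha,
                 causal_beta2 = causal_beta2, causal_direct = causal_direct,
                 pleiotropy_frac = pleiotropy_frac,
                 pleiotropy_mean = pleiotropy_mean,
                 pleiotropy_sd = pleiotropy_sd,
                 case_fraction = case_fraction, ld_blocks = ld_blocks,
                 palindromic_frac = palindromic_frac, swap_frac = swap_frac,
                 strand_frac = strand_frac, seed = seed),
            class = "sim_config")
}

# Non-palindromic allele pairs to draw from.
nonpal_pairs <- function() {
  rbind(c("A", "G"), c("A", "C"), c("G", "A"), c("C", "A"),
        c("T", "G"), c("T", "C"), c("G", "T"), c("C", "T"))
}
pal_pairs <- function() rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# Draw the shared SNP panel: ids, locations, alleles, frequencies, true
# per-SNP effect components, and presentation scrambling flags.
draw_panel <- function(cfg, n_total, n_expo_snps) {
  with_seed(sub_seed(cfg$seed, 0L), {
    id <- sprintf("rs%06d", seq_len(n_total))
    if (is.null(cfg$ld_blocks)) {
      chrom <- as.character(rep(1:22, length.out = n_total))
      idx <- stats::ave(seq_len(n_total), chrom, FUN = seq_along)
      pos <- 1e6 + (idx - 1) * 2e7
      ld <- ld_info(NULL)
    } else {
      nb <- cfg$ld_blocks$n_blocks
      block <- rep(seq_len(nb), length.out = n_total)
      chrom <- as.character(((block - 1) %% 22) + 1)
      within <- stats::ave(seq_len(n_total), block, FUN = seq_along)
      pos <- 1e6 + ((block - 1) %/% 22) * 2e7 + (within - 1) * 1e3
      pairs <- do.call(rbind, lapply(seq_len(nb), function(b) {
        ids <- id[block == b]
        if (length(ids) < 2) return(NULL)
        cmb <- utils::combn(ids, 2)
        data.frame(snp_a = cmb[1, ], snp_b = cmb[2, ],
                   r2 = cfg$ld_blocks$r2, stringsAsFactors = FALSE)
      }))
      ld <- ld_info(pairs)
    }
    maf <- runif(n_total, cfg$maf_range[1], cfg$maf_range[2])
    pal <- runif(n_total) < cfg$palindromic_frac
    np <- nonpal_pairs(); pp <- pal_pairs()
    pick_np <- np[sample(nrow(np), n_total, replace = TRUE), , drop = FALSE]
    pick_p <- pp[sample(nrow(pp), n_total, replace = TRUE), , drop = FALSE]
    ea <- ifelse(pal, pick_p[, 1], pick_np[, 1])
    oa <- ifelse(pal, pick_p[, 2], pick_np[, 2])

    gamma <- c(rnorm(n_expo_snps, 0, cfg$gamma_sd),
               rep(0, n_total - n_expo_snps))
    eta <- c(rep(0, n_expo_snps),
             rnorm(n_total - n_expo_snps, 0, cfg$eta_sd))
    pleio <- ifelse(runif(n_total) < cfg$pleiotropy_frac,
                    rnorm(n_total, cfg$pleiotropy_mean, cfg$pleiotropy_sd), 0)
    swap <- runif(n_total) < cfg$swap_frac
    strand <- runif(n_total) < cfg$strand_frac
    list(id = id, chrom = chrom, pos = pos, ea = ea, oa = oa, maf = maf,
         gamma = gamma, eta = eta, pleio = pleio, swap = swap,
         strand = strand, ld = ld)
  })
}

# One summary-statistics table from true per-SNP effects; `scramble` applies
# allele swaps / strand flips so harmonization has work to do. A pre-drawn
# effect vector can be supplied through `beta`.
make_table <- function(panel, true_beta, se, n, name, type, seed,
                       scramble = FALSE, beta = NULL) {
  if (is.null(beta))
    beta <- with_seed(seed, rnorm(length(true_beta), true_beta, se))
  ea <- panel$ea; oa <- panel$oa
  eaf <- panel$maf
  if (scramble) {
    sw <- panel$swap
    tmp <- ea[sw]; ea[sw] <- oa[sw]; oa[sw] <- tmp
    beta[sw] <- -beta[sw]
    eaf[sw] <- 1 - eaf[sw]
    st <- panel$strand
    ea[st] <- allele_complement(ea[st])
    oa[st] <- allele_complement(oa[st])
  }
  gwas_table(data.frame(snp_id = panel$id, chrom = panel$chrom,
                        pos = panel$pos, effect_allele = ea,
                        other_allele = oa, eaf = eaf, beta = beta, se = se,
                        # floor against underflow for very strong associations
                        pval = pmax(2 * pnorm(-abs(beta / se)), 1e-300), n = n,
                        stringsAsFactors = FALSE),
             name, type)
}

simulate_core <- function(cfg, with_mediator_instruments) {
  n_expo <- cfg$n_snp
  n_total <- if (with_mediator_instruments) n_expo + cfg$n_snp_mediator
             else n_expo
  if (cfg$case_fraction * cfg$n_outcome < 10)
    warning("effectively unidentified outcome SEs: fewer than 10 expected cases")
  panel <- draw_panel(cfg, n_total, n_expo)
  vg <- 2 * panel$maf * (1 - panel$maf)
  se_exp <- 1 / sqrt(vg * cfg$n_exposure)
  se_med <- 1 / sqrt(vg * cfg$n_mediator)
  se_out <- 1 / sqrt(vg * cfg$n_outcome * cfg$case_fraction *
                       (1 - cfg$case_fraction))

  alpha <- if (is.null(cfg$causal_alpha)) 0 else cfg$causal_alpha
  beta2 <- if (is.null(cfg$causal_beta2)) 0 else cfg$causal_beta2
  total <- if (is.null(cfg$causal_total)) 0 else cfg$causal_total
  true_exp <- panel$gamma
  beta_exp_obs <- with_seed(sub_seed(cfg$seed, 1L),
                            rnorm(length(true_exp), true_exp, se_exp))
  # directional pleiotropy acts on the reported exposure-increasing allele,
  # the orientation MR-Egger fits under, so the intercept is centred on
  # pleiotropy_mean * pleiotropy_frac
  orient <- ifelse(beta_exp_obs != 0, sign(beta_exp_obs), 1)
  dir_pleio <- orient * panel$pleio
  true_med <- alpha * panel$gamma + panel$eta
  true_out <- total * panel$gamma + beta2 * panel$eta + dir_pleio

  exposure <- make_table(panel, true_exp, se_exp, cfg$n_exposure,
                         "exposure", "quantitative", sub_seed(cfg$seed, 1L),
                         beta = beta_exp_obs)
  mediator <- make_table(panel, true_med, se_med, cfg$n_mediator,
                         "mediator", "quantitative", sub_seed(cfg$seed, 2L),
                         scramble = TRUE)
  outcome <- make_table(panel, true_out, se_out, cfg$n_outcome,
                        "outcome", "binary", sub_seed(cfg$seed, 3L),
                        scramble = TRUE)
  truth <- list(causal_total = cfg$causal_total,
                causal_alpha = cfg$causal_alpha,
                causal_beta2 = cfg$causal_beta2,
                causal_direct = cfg$causal_direct,
                pleiotropy_frac = cfg$pleiotropy_frac,
                pleiotropy_mean = cfg$pleiotropy_mean)
  if (!is.null(cfg$causal_alpha) && !is.null(cfg$causal_beta2) &&
      !is.null(cfg$causal_direct) && cfg$causal_total != 0)
    truth$proportion_mediated <- cfg$causal_alpha * cfg$causal_beta2 /
      cfg$causal_total
  structure(list(exposure = exposure, mediator = mediator, outcome = outcome,
                 ld = panel$ld, truth = truth, config = cfg),
            class = "sim_dataset")
}

#' Simulate a summary-level GWAS dataset with known causal structure
#'
#' Draws a shared SNP panel (MAFs uniform on `maf_range`, per-SNP exposure
#' effects normal with SD `gamma_sd`) and emits exposure, mediator and
#' outcome summary-statistics tables. Standard errors follow the analytic
#' forms `1/sqrt(2 maf (1-maf) n)` for quantitative traits and
#' `1/sqrt(2 maf (1-maf) n phi (1-phi))` (logistic-score approximation with
#' prevalence `phi`) for the binary outcome, so the very large SEs implied
#' by a rare outcome are reproduced. Outcome and mediator tables receive
#' random allele swaps and strand flips, including palindromic SNPs, to
#' exercise harmonization.
#'
#' @param cfg a [sim_config()].
#' @return A `sim_dataset`: list with `exposure`, `mediator`, `outcome`
#'   ([gwas_table()]s sharing one SNP panel), `ld` ([ld_info()]), `truth`
#'   (the causal parameters), and `config`.
#' @export
simulate_summary_dataset <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  simulate_core(cfg, with_mediator_instruments = FALSE)
}

#' Simulate a mediation dataset with exposure and mediator instruments
#'
#' As [simulate_summary_dataset()], but requires the full causal chain
#' (`causal_alpha`, `causal_beta2`, `causal_direct`; the total effect is
#' enforced as their combination) and appends `n_snp_mediator`
#' mediator-specific instrument SNPs (effects with SD `eta_sd`, no exposure
#' effect) so that two-step MR and MVMR are identified. The truth records
#' the implied proportion mediated.
#'
#' @param cfg a [sim_config()] with the three chain parameters set.
#' @return A `sim_dataset` (see [simulate_summary_dataset()]).
#' @export
simulate_mediation_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(cfg$causal_alpha) || is.null(cfg$causal_beta2) ||
      is.null(cfg$causal_direct))
    stop("mediation dataset requires causal_alpha, causal_beta2 and causal_direct")
  if (cfg$causal_total == 0 &&
      (cfg$causal_alpha * cfg$causal_beta2 != 0 || cfg$causal_direct != 0))
    stop("undefined proportion: total effect is zero with nonzero components")
  simulate_core(cfg, with_mediator_instruments = TRUE)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated summary dataset: %d SNPs (seed %d)\n",
              nrow(x$exposure), x$config$seed))
  utils::str(x$truth, give.head = FALSE)
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits `exposure.tsv`, `mediator.tsv`, `outcome.tsv`, `ld.tsv` and
#' `truth.json` into a directory.
#'
#' @param sim a `sim_dataset`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_gwas(sim$exposure, file.path(dir, "exposure.tsv"))
  write_gwas(sim$mediator, file.path(dir, "mediator.tsv"))
  write_gwas(sim$outcome, file.path(dir, "outcome.tsv"))
  write_ld(sim$ld, file.path(dir, "ld.tsv"))
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
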