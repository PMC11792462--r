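---
title: "Methods: two-sample MR with mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR with mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The model

Two-sample Mendelian randomization estimates the causal effect of an
exposure X (here: the relative abundance of a gut-microbiota taxon,
standardized) on an outcome Y (a binary disease, on the log-odds scale)
from two independent GWAS. For each instrument SNP *j* we observe the
SNP-exposure association $\hat\gamma_j$ (SE $\sigma_{xj}$) and the
SNP-outcome association $\hat\Gamma_j$ (SE $\sigma_{yj}$). Under the
instrumental-variable assumptions (relevance, independence from
confounders, and exclusion — no path to the outcome except through the
exposure), each ratio $\hat\Gamma_j/\hat\gamma_j$ estimates the same
causal effect $\beta$.

The three estimators combine the ratios differently, and their agreement
is itself the robustness argument:

* **IVW** regresses $\hat\Gamma_j$ on $\hat\gamma_j$ through the origin
  with weights $1/\sigma_{yj}^2$. It is efficient when all instruments
  are valid. We report multiplicative random-effects standard errors: the
  fixed-effect SE scaled by the residual standard deviation
  $\hat\sigma$ when $\hat\sigma > 1$, never deflated below the
  fixed-effect SE. Inference is normal. With a single instrument the
  estimator degenerates to the Wald ratio with the first-order delta SE
  $\sigma_{yj}/|\hat\gamma_j|$.
* **Weighted median** is consistent when at least half of the total
  instrument weight comes from valid instruments. Ratios are weighted by
  $\hat\gamma_j^2/\sigma_{yj}^2$ (the inverse first-order variance of the
  ratio) and the estimate interpolates the sorted ratios at cumulative
  standardized weight 1/2. The SE comes from a seeded parametric
  bootstrap (default 1000 draws of all per-SNP effects from normals with
  their reported SEs).
* **MR-Egger** adds an intercept to the weighted regression after
  orienting every SNP to a nonnegative exposure effect. The slope is a
  pleiotropy-adjusted causal estimate under the InSIDE assumption; the
  intercept estimates the mean directional pleiotropic effect, and its
  test is the pleiotropy diagnostic. Both use t inference with
  $n_{\mathrm{snp}} - 2$ degrees of freedom — with the handful of
  instruments typical per taxon (3–21), normal inference would be
  anticonservative.

An exposure is declared significant only if the IVW p-value is below 0.05
*and* all three point estimates share a sign; family-wise error across
taxa is controlled by Bonferroni multiplication (family size = number of
exposures attempted, including ones skipped for lack of instruments).
Odds ratios and 95% CIs are always the normal-based
$\exp(\hat\beta \pm 1.96\,\mathrm{SE})$, including for MR-Egger, matching
the reporting convention of the field's toolkits even where the p-value
is t-based.

# Instrument selection

`select_ivs()` applies, in order: exposure association p < 1e-5 (the
conventional suggestive threshold for microbiome GWAS, where few taxa
have genome-wide-significant hits); greedy LD clumping (r² < 0.001 within
10,000 kb, p-ranked with ties broken by chromosome, position, and SNP id
so results are order-independent); harmonization; removal of SNPs
associated with the outcome at p ≤ 1e-5 (a conservative guard for a
hypothesis-free disease screen); the weak-instrument filter F > 10
(strict) with per-SNP $R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$ and
$F = \frac{R^2}{1-R^2}\cdot\frac{n-k-1}{k}$, $k = 1$; and finally removal
of SNPs from a user-supplied confounder list, the offline replacement
for an interactive phenome-scanner lookup. Every step logs its removal
count. LD is supplied as an explicit pairwise r² table (`ld_info`);
computing LD from a reference panel is out of scope, and pairs absent
from the table are treated as independent (counted, so a missing panel
is visible in the log).

Harmonization matches SNPs across tables by rsID only (mixed genome
builds make positions unreliable; positions are used solely for clump
windows). Allele swaps and strand flips are resolved by letter matching;
palindromic (A/T, C/G) SNPs cannot be, so those with either table's
effect-allele frequency in [0.42, 0.58] are dropped, and the rest are
oriented by minor-allele concordance (`action = "infer"`, the common
toolkit default; `"drop_palindromic"` drops them all).

# Sensitivity battery

* **Cochran's Q** over per-SNP ratios with weights
  $\hat\gamma_j^2/\sigma_{yj}^2$ (equivalent to fixed-effect IVW), upper
  chi-square tail with $n-1$ df. Q p < 0.05 flags heterogeneity.
* **MR-Egger intercept test**: p > 0.05 is read as no directional
  pleiotropy.
* **MR-PRESSO**: the observed weighted residual sum of squares around
  leave-one-out IVW predictions is compared against a parametric
  simulated null (default 1000 simulations, seeded; empirical p-values
  use add-one smoothing so they are never 0). Per-SNP outlier p-values
  are Bonferroni-adjusted by the instrument count; if outliers are
  flagged, IVW is re-run without them. The distortion test is not
  implemented: the pipeline's decision rule only consumes the global test
  and the outlier list.
* **Leave-one-out**: IVW without each SNP in turn; a SNP is flagged as
  influential when its removal changes the significance status at
  α = 0.05 or flips the estimate's sign. No closed-form definition of
  "influential" is standard; this one captures "exclusion of this SNP may
  affect the significance" directly.

# Mediation

For an exposure → mediator → outcome chain, two strategies are run side
by side:

* **Two-step MR**: α (exposure → mediator), β₂ (mediator → outcome) and
  the total β (exposure → outcome) are each estimated by the univariable
  pipeline above; the indirect effect is α·β₂ with the product
  delta-method SE $\sqrt{\alpha^2 SE_{\beta_2}^2 + \beta_2^2
  SE_\alpha^2}$, and the proportion mediated is indirect/total.
* **MVMR**: SNP-outcome effects are regressed jointly on the SNP effects
  for exposure and mediator (no intercept, weights $1/\sigma_{yj}^2$,
  random-effects scaling as in IVW). The exposure coefficient is the
  direct effect β₁; the indirect effect is β − β₁. Instruments are the
  union of the exposure's and the mediator's selected IVs, de-duplicated
  and re-clumped at the same thresholds, and both regressor columns are
  aligned onto the exposure's allele coding before fitting.

A mediator whose indirect effect shares the total effect's sign is
labelled *mediation*; opposite signs, *suppression* (the mediator
counteracts the exposure). Proportions may exceed 1 or be negative and
are reported unclipped — the label carries the interpretation.
Proportion inference treats the total as fixed (delta method); this
understates uncertainty when the total is imprecise, which is why the
package's own validation works with replicate means rather than
single-run proportions.

Two deliberate consequences of running "the same procedure" at every
stage are worth knowing. First, the outcome-association filter is also
applied in the exposure → mediator step with the mediator in the outcome
role, so under a strong true α the strongest mediating instruments are
removed and $\hat\alpha$ is attenuated (about 10% in the validation
scenario). Second, exposure-driven SNPs whose mediator association
crosses the selection threshold contaminate the mediator → outcome step
and inflate $\hat\beta_2$ (their ratio estimates β/α, not β₂). The two
biases act in opposite directions on the product α·β₂ and largely cancel
there; both are visible in the generator's ground-truth checks.

# The synthetic-data generator

`simulate_summary_dataset()` draws a shared SNP panel — MAF uniform on
(0.05, 0.5), per-SNP exposure effects $\gamma_j \sim N(0,
\texttt{gamma\_sd}^2)$ with `gamma_sd = 0.1` by default (instrument F
mostly between ~12 and ~150 at the default exposure sample size of
18,340, the realistic strength range for microbiome instruments) — and
emits summary statistics with exact analytic SEs:
$1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n}$ for quantitative traits
and, for the binary outcome, the logistic-score form
$1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n\,\phi(1-\phi)}$ with default
prevalence $\phi = 261/247{,}540$. The rare-outcome default reproduces
the very large outcome SEs (≈ 0.1–0.3) that dominate real analyses of
uncommon diseases, and is the reason single-replicate causal estimates
are noisy by design. Mediation datasets
(`simulate_mediation_dataset()`) enforce β = β₁ + α·β₂ and add
mediator-specific instruments ($\eta_j \sim N(0, 0.15^2)$ at the default
mediator sample size 8,299, strong enough to pass selection while
exposure-driven mediator associations typically do not).

Pleiotropic outcome effects are applied on the *observed*
exposure-increasing allele — the orientation MR-Egger fits under — so
that with directional pleiotropy the Egger intercept is centred on
`pleiotropy_mean × pleiotropy_frac`; defining pleiotropy on the
true-effect allele instead would let weak-instrument orientation flips
attenuate the intercept and break that correspondence. Outcome and
mediator tables receive random allele swaps (20%), strand flips (10%)
and palindromic alleles (10%) so harmonization is always exercised.
Optional LD blocks with a fixed within-block r² support clumping tests.
A single root seed drives deterministic per-table sub-streams, so adding
a table does not perturb existing draws. Simulated p-values are floored
at 1e-300 to avoid underflow to an invalid 0.

What the generator does *not* emulate: individual-level genotypes,
realistic LD decay, winner's curse from discovery in an external sample,
sample overlap between exposure and outcome GWAS, and non-normal effect
distributions. Passing tests therefore demonstrate correctness of the
estimators and pipeline wiring under the stated sampling model, not
robustness to every pathology of real consortium data.

# Validation scenarios and problem sizes

The test suite and `scripts/acceptance.R` validate operating
characteristics at these sizes, chosen to make Monte-Carlo error small
relative to the property being checked:

* IVW type-I error: 1000 replicates × 30 SNPs under a zero causal
  effect (observed ≈ 0.04–0.05 at α = 0.05).
* IVW recovery: 500 replicates at true β = 0.3 with exposure n = 20,000
  (bias < 0.01, CI coverage ≈ 0.95).
* Weighted median: exact agreement with an independently coded
  brute-force cumulative-weight oracle on 100 random 7-SNP instances;
  IVW/Egger/MVMR agree with normal-equations oracles to 1e-10.
* MR-PRESSO: a 10-SE planted outlier among 20 SNPs is flagged in ~100%
  of 100 replicates (500 simulations each); the global test rejects in
  ≤ 5% of 100 null replicates.
* Egger intercept: power ≈ 0.74 against directional pleiotropy of mean
  0.1 across 30 SNPs (200 replicates).
* Mediation: with truth proportion 0.4 (α = 0.4, β₂ = 0.5, β₁ = 0.3) and
  strong instruments — 60 exposure plus 60 mediator SNPs with
  `gamma_sd = 0.15` — the replicate-mean two-step and MVMR proportions
  land within 0.05 of the truth over 200 replicates. The larger panel is
  what "strong instruments" requires here: with 30-SNP panels the total
  effect's sampling CV (~0.35, driven by the rare outcome) inflates the
  mean of the ratio indirect/total by about 0.1 on its own.

# Numerical choices and degenerate inputs

Ties in clumping are broken lexicographically (p, chromosome, position,
id). A zero exposure effect is an error for the Wald ratio, exclusion
with a warning for the weighted median, and harmless for the regression
estimators. MVMR drops all-zero regressor columns (coefficient 0, no SE)
rather than failing on rank; genuinely collinear designs are an error.
Zero overlap in harmonization, an empty instrument set, or a missing
mediation stage each return structured "skip" objects instead of
crashing, so batch runs continue. The boundary F = 10 is not retained
(the rule is strictly F > 10). The weighted-median bootstrap,
MR-PRESSO simulations and pipeline runs are all seeded; identical
configuration and seed give byte-identical report directories.

# Limitations

Proportion-mediated p-values treat the total effect as fixed; reverse
runs with a rare binary trait as the exposure usually find no
instruments at stringent thresholds (reported as skips, mirroring
practice of relaxing thresholds explicitly rather than silently); and
the package deliberately implements no Steiger filtering, mode-based
estimators, or distortion test, none of which are part of the pipeline
it reproduces.
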