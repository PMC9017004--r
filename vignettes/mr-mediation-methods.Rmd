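---
title: "Methods: two-sample MR estimation and mediation in mrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation and mediation in mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

# The problem

Elevated adiposity raises the risk of several cancers, and a natural
follow-up question is *through which molecular pathways*. With only GWAS
summary statistics available — one file per trait, one row per SNP —
two-sample Mendelian randomization (MR) treats germline variants as
instrumental variables: a SNP that robustly shifts an exposure, and that
affects disease only through that exposure, identifies the exposure's causal
effect from the ratio of its SNP-outcome to SNP-exposure associations.
`mrpath` implements the full workflow needed to go one step further and ask
how much of an exposure's effect on a binary outcome travels through
candidate molecular mediators (for example, how much of the BMI effect on a
hormone-sensitive cancer is carried by fasting insulin, bioavailable
testosterone or SHBG): instrument construction, five univariable
estimators with pleiotropy and directionality diagnostics, multivariable MR
(MVMR), and product-of-coefficients mediation.

All binary-outcome effects are held internally on the log-odds scale; odds
ratios are a presentation transform `exp(beta)` applied only when printing.

# Instruments and harmonization

Instruments are built by significance selection (default genome-wide,
p < 5e-8), an optional cis window around a gene, and greedy LD clumping:
the smallest-p unprocessed SNP is retained and every SNP with squared
correlation at or above the threshold (default r² < 0.001) against it is
discarded; ties on p break by rsid so runs are reproducible. LD enters as an
explicit correlation matrix keyed by rsid — the package never downloads a
reference panel. When an analysis deliberately retains weakly linked SNPs
(r² < 0.10, a common choice for cis instruments of proteins to maximize
strength), the correlation matrix must be carried into estimation and the
pipeline switches to the generalized-least-squares IVW.

Harmonization aligns every dataset to the first exposure's effect allele.
Swapped allele labels flip the sign of beta and replace the frequency by its
complement; non-palindromic strand flips resolve through complementary
alleles. Palindromic SNPs (A/T, C/G) carry no strand information in their
labels, so they are dropped whenever either side's effect-allele frequency
sits within 0.5 ± 0.08 (or is missing). Outside that window the default
`drop_ambiguous` policy keeps the label orientation but treats a frequency
disagreement as an unlabelled strand flip, while `infer_by_eaf` orients
purely by frequency. The window of 0.08 is the conventional conservative
choice; the underlying studies rarely state their dialect, and silent strand
errors are far more damaging than a few dropped SNPs. Every exclusion is
recorded with a reason in the harmonized set's drop log, so
`|kept| + |dropped|` always equals the rsid intersection.

Per-SNP variance explained uses the t-statistic approximation
r² = t²/(t² + n − 2); for case-control traits n is replaced by the effective
sample size 4/(1/n_cases + 1/n_controls). The per-SNP F is then
(n − 2) r²/(1 − r²) (algebraically t²) and the instrument F is the mean.
Published instrument tables are not always reproducible from any single
textbook convention, which is one reason the package states its own
explicitly. Steiger filtering compares these r² values SNP by SNP and
removes any variant explaining more variance in the outcome than in the
exposure — the signature of a reversed causal arrow.

# Estimators

For a single SNP the Wald ratio by/bx is used, with either the first-order
standard error sy/|bx| or the second-order form
sqrt(sy²/bx² + by² sx²/bx⁴). Both are delta-method approximations: they are
accurate when the SNP-exposure t-statistic is large (always true for
genome-wide significant instruments) and should not be trusted when the
denominator's coefficient of variation exceeds roughly 10%.

The inverse-variance weighted (IVW) estimator is the weighted zero-intercept
regression of by on bx with weights 1/sy². The default is the
multiplicative random-effects flavour: the fixed-effects standard error is
inflated by φ = max(1, sqrt(Q/(k−1))), with Q Cochran's heterogeneity
statistic, so that the estimate reduces exactly to fixed effects under
homogeneity. This floor makes the test mildly conservative under the null
(empirically a rejection rate a little below the nominal 5%), which is the
accepted trade-off in trait screens.

Three pleiotropy-robust estimators complement IVW, applied by the pipeline
when an instrument has at least 10 SNPs (below that their power to detect
pleiotropy is too low to be informative):

* **MR-Egger** re-fits the weighted regression with a free intercept after
  orienting every SNP to a positive exposure effect; the intercept estimates
  average directional pleiotropy and the slope remains consistent under the
  InSIDE assumption. SEs carry a φ inflation with k − 2 denominator.
* **Weighted median** interpolates the inverse-variance-weighted median of
  the per-SNP ratio estimates (cumulative-weight convention
  p_i = (S_i − w_i/2)/ΣW), consistent when at least half the weight is valid.
* **Weighted mode** maximizes a weighted Gaussian kernel density over the
  ratio estimates, consistent under plurality validity. The bandwidth is the
  modified Silverman rule 0.9·min(SD, MAD/0.6745)·k^(−1/5) times a
  user-facing factor, and the density is evaluated on a 512-point grid
  spanning the ratios ± 3 bandwidths; refining the grid changes the
  estimate by less than a tenth of a bandwidth, which is the discretization
  tolerance we consider acceptable.

Weighted-median and mode standard errors come from a parametric bootstrap
(1000 redraws of bx and by from their sampling distributions by default,
seeded from the run configuration). The underlying studies rarely publish
bootstrap counts or bandwidths; these defaults are stated so results are
reproducible bit-for-bit.

Leave-one-out re-estimates IVW k times with each SNP removed and flags
sign flips. The pipeline triggers it for nominally significant findings
(p < 0.05) when the instrument is small (< 10 SNPs) or when all three robust
estimators agree in sign with IVW — a formalization of the qualitative
"consistent across sensitivity analyses" rule; sign concordance was chosen
because it is scale-free and decidable without further thresholds.

Evidence labels follow a Bonferroni heuristic: "strong" below 0.05/n_traits
(3.33e-3 for a 15-trait screen), "suggestive" between that and 0.05.
Post-hoc power uses the asymptotic binary-outcome approximation
Φ(|ln OR|·sqrt(n·r²·cf(1−cf)) − z_{1−α/2}), validated in the test suite
against a matched simulation rather than against any published table.

# Multivariable MR and mediation

MVMR regresses the SNP-outcome effects jointly on K exposures' SNP-effect
columns (weights 1/sy², no intercept) over the union of the per-exposure
instruments — union rather than intersection, mirroring standard MVMR
practice and maximizing k. The coefficient on each exposure is its direct
effect conditional on the others. Exposures whose SNP-effect column is
identically zero are excluded with NA coefficients rather than crashing the
solve; near-collinear columns raise an error naming the offending pair.
Conditional instrument strength for exposure j is the weighted residual sum
of squares of its SNP-effect column regressed on the other columns, scaled
by 1/(k − K); with K = 1 this reduces to the mean univariable F. The
degrees-of-freedom convention is stated rather than inherited, because the
published conditional-F tables we would compare against are not available;
values below 10 are flagged as weak-instrument territory. The conditional F
assumes independent errors across the exposure GWAS; the consequences of
overlap are explored by simulation, not corrected analytically.

Mediation uses the product of coefficients: with `a` the exposure→mediator
effect (univariable MR) and `b` the mediator's direct effect on the outcome
(MVMR conditional on the exposure), the indirect effect is a·b with
delta-method SE sqrt(b² se_a² + a² se_b²), and the proportion mediated is
indirect/total with SE |pm|·sqrt(se_ind²/ind² + se_tot²/tot²). Independence
of the component estimation errors is assumed, as the three quantities come
from distinct GWAS samples; the covariance terms that sample overlap would
introduce are left to the simulator to quantify. Proportions outside [0, 1]
are reported as computed — negative and >100% values are informative about
weak instruments and are never truncated. The difference-method indirect
effect (total − direct) is attached to every result as a cross-check; on
simulated linear chains the two agree to within a few percent of the total
effect. Pairwise mediator-only models report the percent log-odds
attenuation 100·(1 − β_conditional/β_univariable) of each mediator when a
presumed downstream partner enters the model.

# The simulator

`simulate_mr_study()` instantiates the full causal diagram at the individual
level: genotypes are binomial(2, maf) dosages (Gaussian-copula blocks with a
tetrachorically calibrated latent correlation when LD blocks are requested,
so the *genotype-scale* correlation matches the requested rho); the exposure
is an additive polygenic trait plus a shared confounder; mediators are
linear in the exposure with their own SNP panels; and the outcome is a
Bernoulli draw from a logistic liability whose intercept is solved
numerically for the target case fraction. Summary statistics are produced
exactly as a GWAS would: single-SNP linear regression for continuous traits
and a one-step score-based logistic fit for the binary outcome (beta = U/I
at the null fit), the approximation that matches how case-control GWAS
effect estimates behave for small per-SNP effects. These scans are
implemented in C++ because the calibration experiments need hundreds of
cohorts of 2×10⁵ individuals.

Defaults emulate a large adiposity-to-cancer study: ~100 exposure SNPs
explaining 8% of variance in a 200,000-person GWAS, 50 SNPs per mediator
explaining 5%, an outcome GWAS of 120,000 with a 10% case fraction, total
effect OR 1.88 per exposure SD, and a standard-normal confounder loading 0.3
on both exposure and liability. Mediation proportions are imposed by
construction: a_m is fixed (0.3 by default), b_m = pm·total/a_m, and the
direct effect absorbs the remainder, so a·b/total equals the requested
proportion exactly on the liability scale. Directional pleiotropy is
injected on the *exposure-increasing allele* — without that orientation a
mean-zero effect panel cancels the directional component and there is
nothing for the Egger intercept to detect. Reverse-causation SNPs act on an
outcome-proximal factor that leaks into the exposure (transmission 0.3),
giving Steiger filtering a ground truth. Sample overlap re-uses individuals
between the exposure and outcome cohorts; winner's curse splits the exposure
cohort into discovery and replication halves and lets the instrument reuse
discovery betas (curse present) or take replication betas (curse absent).

Two deliberate simplifications: marginal per-SNP log-odds from a logistic
liability are non-collapsible, so estimated total and direct effects are
attenuated a few percent relative to the liability-scale truth — the
proportion mediated is a ratio and the attenuation cancels, which the
recovery experiments confirm; and the generator makes no attempt at
realistic allele-frequency spectra, genomic positions or imputation noise,
so passing tests demonstrate statistical calibration of the estimators, not
robustness to data-quality pathologies of real GWAS files.

For estimator-calibration experiments that need thousands of replicates
(type-I error, power, pleiotropy behaviour), `simulate_summary_mr()` draws
the summary statistics directly from their large-sample Gaussian sampling
distributions parameterized by the GWAS sample sizes
(sx = 1/sqrt(2·maf(1−maf)·n) for a unit-variance trait and the
cf(1−cf)-scaled analogue for log-odds). At the per-SNP level this is exactly
the distribution the individual-level scan converges to, at a tiny fraction
of the cost; individual-level structure is used whenever overlap, selection
or reverse causation matter.

Problem sizes used by the validation experiments (chosen as the package's
own desk-scale study conditions): the mediation-recovery experiment runs
200 replicates of a 150-SNP study with three cohorts of 200,000; the type-I
experiment 2000 summary-level replicates of 50 SNPs; the winner's-curse
experiment 200 replicates of a 60-SNP, 40,000-person exposure cohort; the
Steiger experiment one 60-SNP study of 100,000 with 20 reverse SNPs.

# Running from configuration

`run_screen()` / `run_mediate()` (and the `inst/exec/mrpipe` command line)
drive the pipeline from a YAML file:

```yaml
outcome:
  path: outcome.tsv          # summary-stats TSV (tab-separated)
  trait_type: binary
  case_fraction: 0.10        # or per-SNP ncase column
exposures:                   # one named entry per trait
  bmi:
    path: bmi.tsv
    p_threshold: 5.0e-8      # instrument construction overrides
    clump_r2: 0.001
    ld: bmi_ld.tsv           # optional LD matrix for clumping / GLS
  insulin:
    path: insulin.tsv
mediation:                   # optional section for run_mediate
  exposure: bmi
  mediators: [insulin]
  pairwise: true             # mediator-pair models without the exposure
n_traits_for_bonferroni: 15
steiger: true
n_boot: 1000
seed: 1
output_dir: out/
```

Column names differing from the defaults (`rsid`, `effect_allele`,
`other_allele`, `eaf`, `beta`, `se`, `pval`, `n`, `ncase`) are remapped per
dataset with a `column_map` entry. Sex-specific sensitivity reruns and
stricter winner's-curse thresholds (5e-9, 5e-10) are expressed as
alternative paths / `p_threshold` overrides in this file rather than as
separate code paths.

# Numerical choices and degenerate inputs

* 95% intervals use the conventional 1.96 multiplier exactly.
* Exact regression fits (zero residuals) and extreme associations are
  clamped so emitted summary rows respect se > 0 and p ∈ (0, 1] instead of
  underflowing to zero.
* The GLS IVW adds a ridge of 1e-6 × mean diagonal before factorizing the
  SNP-correlation covariance; a matrix still singular after that raises an
  error reporting the condition number.
* Identical ratio estimates give the weighted mode a zero bandwidth; the
  common ratio is returned directly.
* Clumping ties on p-value break lexicographically by rsid.
* The liability intercept is solved by `uniroot` on [−50, 50] to 1e-10.

# A worked example

```{r example, eval = FALSE}
truth <- simulate_mediation_study(sim_config(
  n_snps = 100, n_snps_mediator = 50,
  true_total_logor = log(1.88),
  true_mediation_proportions = c(insulin = 0.15),
  seed = 1))
med <- mediation_analysis(truth$datasets$exposure,
                          truth$datasets$mediators,
                          truth$datasets$outcome)
med$table
```

The chunk is not evaluated when building this vignette (the full-scale
simulation draws three cohorts of 200,000 individuals); the README shows the
output of this exact code.

# Known limitations

* No MR-PRESSO/contamination-mixture estimators and no I²_GX
  weak-instrument correction for Egger.
* No proxy-SNP lookup, liftover or reference-panel LD computation: LD is an
  input.
* Delta-method mediation SEs ignore cross-sample covariance; with heavy
  sample overlap the intervals are optimistic (use the simulator's overlap
  switch to gauge the size of the problem for a given design).
* The power formula and Steiger r² for binary traits rely on the effective
  sample-size approximation; both are validated by simulation, not exact.
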