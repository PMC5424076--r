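---
title: "Polygenic scores, education and IQ: the prsmediate pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores, education and IQ: the prsmediate pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Attention-deficit hyperactivity disorder (ADHD) is highly heritable and
children with the diagnosis face worse school outcomes. Polygenic risk
scores (PRS) built from a clinical case-control discovery GWAS summarize an
individual's common-variant loading for the disorder, and in population
cohorts such scores predict small but systematic decrements in exam
performance and IQ — in children and, one generation up, in their mothers.
`prsmediate` implements that analysis chain as a tested, reusable pipeline:

1. **Scoring** — select discovery SNPs below a P-value threshold (the
   conventional permissive `P < 0.5`), prune the target panel to approximate
   linkage equilibrium, and score each individual as the weighted mean
   number of risk alleles, weights being discovery log odds ratios.
2. **Association** — covariate-adjusted linear/logistic regression of
   outcomes on the standardized score, reporting likelihood-ratio P-values
   and the pseudo-R² difference against a covariates-only null.
3. **Mediation** — decompose the score's effect on exam results into a
   direct path and paths through IQ and childhood ADHD symptoms
   (Sobel–Goodman, bootstrap CIs, and a two-mediator seemingly-unrelated-
   regression decomposition).
4. **Synthetic data** — because neither the discovery GWAS nor the cohort
   data are deposited anywhere, a first-class generator simulates the whole
   world: a liability-threshold case-control discovery sample, Mendelian
   mother–child duos, and phenotypes with a configurable mediation
   structure.

## The generative world

### Discovery sample

`simulate_discovery_gwas()` draws genotypes at Hardy–Weinberg proportions,
assigns `n_causal` SNPs Gaussian liability effects on the standardized
genotype scale rescaled so they contribute `h2_liability` of liability
variance, and labels an individual a case when genetic plus standard-normal
environmental liability exceeds the threshold for the assumed prevalence
(default 5%). Cases and controls are ascertained to fixed counts — by
default 727 cases and 5081 controls, the scale of the clinical ADHD
discovery GWAS this design emulates — and each SNP is tested with a 2×2
allele-count Wald test (Haldane correction on empty cells, flagged). Under
a null architecture the P-values are uniform; the test suite checks the
type-I error rate directly.

### Mother–child duos

`simulate_duos()` draws mothers from Hardy–Weinberg, simulates a father per
duo from the same frequencies (random mating) and discards him, and
transmits one uniformly chosen maternal and one paternal allele per SNP.
Parent–offspring additive genotype correlation is exactly 1/2 per SNP, so
with thousands of independent score SNPs the mother–child standardized PRS
correlation concentrates near 0.5 (cohort studies report about 0.46; the
sample correlation at 2000 duos has SD ≈ 0.017, so occasional draws fall
slightly below that). `check_mendelian()` asserts consistency exhaustively.

### Phenotypes: the calibrated path model

`mediation_preset()` states the phenotype world. With Z the standardized
child score, sex coded male/female and centered, and Gaussian residuals:

* IQ = 91.9 − 0.8·Z + e₁ (marginal SD 13)
* ADHD symptoms = 3 + 0.3·Z + sex effect + e₂ (marginal SD 3)
* GCSE = intercept − 1.5·Z + 2.469·(IQ − 91.9) − 1.75·(ADHD − 3)
  + sex effect + e₃, clipped to [0, 483]
* KS3: same structure scaled so the total effect is −1.4, clipped to
  [0, 141]
* sitting KS5 ~ Bernoulli(logit⁻¹(intercept + log(0.90)·Z))
* maternal IQ = 98.9 − 0.6·Z_mother + noise; maternal education = a latent
  Gaussian in Z_mother thresholded at population quintiles into 5 levels.

The defaults are calibrated so the published effect sizes are the
generative truth: total GCSE effect −4.0 points per SD; two-mediator
indirect effects −1.975 (IQ) and −0.525 (symptoms), i.e. a total indirect
of −2.5 with 79% attributed to IQ; and single-mediator proportions mediated
of ≈49% (IQ) and 16% (symptoms). Three derivations deserve spelling out.

**Mediator residual correlation.** In a single-mediator regression the
mediator's coefficient absorbs part of the omitted mediator's path through
the residual correlation ρ of the two mediators: the fitted IQ coefficient
is b₁ + b₂·ρ·s₂/s₁ (and symmetrically for symptoms). Requiring the
single-mediator symptom proportion to equal 16% fixes

ρ = (0.16·c/a₂ − b₂)·s₂ / (b₁·s₁) ≈ −0.035,

after which the single-mediator IQ proportion lands at 49.7%, consistent
with the printed 49%. A textbook-sized IQ–symptom correlation (≈ −0.25)
would be incompatible with the printed single- and two-mediator results
simultaneously; the near-zero value is what the published numbers jointly
imply, and the constructor solves it in closed form rather than hard-coding
it.

**Clipped moments.** The published exam-score means and SDs describe the
*capped* scores (GCSE caps at 483; about 4–8% of a Gaussian with these
moments sits above the cap). The constructor therefore inverts the
clipped-normal moment equations to find the pre-clip location and scale
whose clipped distribution reproduces the published mean and SD, instead of
using the published values directly and letting clipping shrink them.
Clipping attenuates all outcome-side regression coefficients by roughly the
unclipped probability (≈0.95); proportions and attributions are ratios of
equally attenuated quantities and are unaffected, while the recovered total
indirect effect sits near −2.4 rather than −2.5, well inside the
Monte-Carlo tolerance used by the acceptance checks.

**Maternal education.** The published slope (−0.09 points on the 5-level
scale per SD) is an ordinal-as-linear coefficient. Thresholding a latent
Gaussian at quintiles attenuates a latent slope by Σφ(thresholds) ≈ 1.33,
so the generator uses a latent slope of −0.09/1.33 ≈ −0.068.

The linear identity total = direct + Σ aⱼ·bⱼ holds exactly by construction
(`implied_total_effect()`), and all randomness flows from one root seed
through named substreams (`derive_seed(seed, "gwas")`, `"duos"`,
`"phenotypes"`, `"bootstrap"`), so each stage is independently
reproducible.

### What the generator does *not* emulate

Genotyping error, imputation, population structure, assortative mating,
sibling structure, X-chromosome inheritance, realistic LD (the optional
block-LD mode is a pruning exercise: members copy a block anchor with
probability r, so anchor–member correlation is r and member–member r²),
missing phenotype data, and the skewed count distribution of real
DAWBA-derived symptom scores (the symptom score here is a continuous
Gaussian proxy, deliberately left unclipped so the linear path identities
stay exact). A green test therefore establishes that the *methods* recover
a known truth under their own assumptions — not that the synthetic cohort
is demographically realistic.

## Key tunable parameters

| parameter | default | units / meaning |
|---|---|---|
| `p_threshold` | 0.5 | discovery P-value cut (strict `<`) for score SNPs |
| `r2_threshold`, `window_size`, `step` | 0.25, 50, 5 | greedy LD pruning (the source analysis says only "relative linkage equilibrium"; these PLINK-style defaults are configurable) |
| `drop_ambiguous` | TRUE | remove A/T and C/G SNPs before scoring |
| `missing_policy` | `"skip"` | per-individual mean over observed SNPs; `"impute_mean"` substitutes 2·frequency |
| `pi_hat_threshold` | 0.125 | flag third-degree-or-closer cross-cohort relatives |
| `n_boot` | 1000 | bootstrap replications for indirect-effect CIs |
| `ci_type` | `"percentile"` | bootstrap CI; `"bias_corrected"` available |
| `prevalence` | 0.05 | assumed ADHD population prevalence (liability threshold) |
| `h2_liability` | 0.3 | liability-scale SNP heritability of the discovery trait |

## Numerical and convention choices

* **Strict threshold**: `p_value < threshold`, matching the stated
  "P < 0.5"; SNP weights are oriented to the risk allele so every weight is
  positive (rankings and standardized scores are unchanged).
* **Pseudo-R²**: logistic models use Nagelkerke's rescaled likelihood-ratio
  R². For linear models the package returns the likelihood-ratio
  (Cox–Snell) term computed from Gaussian ML likelihoods, which equals the
  classical R²; the Nagelkerke rescaling `1 − L0^{2/n}` is not invariant to
  the outcome's unit of measurement when L0 is a density, so applying it to
  continuous outcomes would make "variance explained" depend on whether IQ
  is recorded in points or tenths of points.
* **Proportion mediated** is indirect/total (`a·b/c`), the Sobel–Goodman
  convention; `c = c' + a·b` holds to machine precision because the three
  regressions share rows and covariates.
* **SUR**: one-step feasible GLS over the mediator and outcome equations.
  With identical mediator-equation regressors, and outcome-equation OLS
  residuals exactly orthogonal to the mediators in-sample, the FGLS point
  estimates coincide with per-equation OLS (Kruskal's identity) — the
  system is still estimated because the joint covariance feeds the SEs.
* **Bootstrap**: case resampling of whole rows; percentile CI by default;
  degenerate (rank-deficient) resamples are dropped and counted.
* **Averaging recovery experiments over seeds**: a per-dataset proportion
  mediated divides by an estimated total effect whose SE at n = 7000 is
  about 1.1 GCSE points, so the per-seed ratio is heavy-tailed and its
  plain mean across seeds has effectively unbounded variance. Multi-seed
  summaries therefore pool as ratio-of-means (mean indirect over mean
  total), the standard summary for replicated ratio estimands. Single-
  dataset results report the ordinary per-dataset proportion.
* **Degenerate inputs**: monomorphic SNPs are retained by pruning (their
  r² is undefined) and reported; zero-variance scores refuse to
  standardize; perfect logistic separation and rank-deficient designs are
  errors naming the culprit; an individual with no usable score SNPs gets a
  missing score and a warning.

## Running the pipeline

```{r example}
library(prsmediate)

co <- simulate_cohort(n_duos = 2000, n_snps = 2000, seed = 1)
cor(co$scores_child$std_score, co$scores_mother$std_score)

fit_model(co$phenotypes, model_spec("gcse", "prs_child", "sex"))
sobel_goodman(co$phenotypes, "prs_child", "iq", "gcse", "sex")
multiple_mediation_sur(co$phenotypes, "prs_child",
                       c("iq", "adhd_symptoms"), "gcse", "sex",
                       n_boot = 1000, seed = 1)

# or end to end, with files and logs:
run_all(pipeline_config(seed = 1, out_dir = "run1", sim_n_duos = 1000))
```

A command-line front end with `simulate`, `score`, `assoc`, `mediate` and
`run-all` subcommands ships in `inst/scripts/prs_mediate.R`.

## Known limitations

* Weights come from a simulated discovery sample; the pipeline makes no
  claim about the real cohort's point estimates, which are not publicly
  available.
* The single-mediator recovery of the proportion mediated is intrinsically
  noisy at the study's own scale (see above); acceptance checks on it
  carry Monte-Carlo tolerances of a few percentage points.
* Greedy r²-pruning is implemented; discovery-P-indexed clumping is not
  (the source analysis does not say which was used).
* Mediation assumes observed-variable linear paths with no
  exposure–mediator interaction and no unmeasured mediator–outcome
  confounding; no sensitivity analysis is provided.
* Maternal education is modelled as linear-in-levels by default; an
  ordinal model is a straightforward extension but not the default, since
  the emulated analysis reports a linear coefficient.
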