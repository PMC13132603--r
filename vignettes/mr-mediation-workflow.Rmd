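---
title: "Summary-statistics MR, mediation, colocalization and single-cell stratification with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Summary-statistics MR, mediation, colocalization and single-cell stratification with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The scientific problem

`mrmediate` implements a five-stage summary-statistics Mendelian
randomization (MR) workflow of the kind used to dissect how a circulating
exposure (for example a plasma metabolite) influences a disease outcome
through an intermediate molecular trait (for example an inflammatory
receptor):

1. **Discovery.** Two-sample MR of every exposure in a panel against a
   discovery outcome GWAS, with Benjamini–Hochberg FDR control.
2. **Replication.** Surviving exposures re-estimated against an independent
   outcome GWAS; kept only with a consistent direction of effect and clean
   sensitivity diagnostics.
3. **Bidirectional MR.** Forward and reverse two-sample MR between the
   replicated exposure and each candidate mediator, to orient the causal
   arrow.
4. **Multivariable MR (MVMR).** Joint models of the exposure and
   mediator(s) against the outcome, isolating each trait's direct effect.
5. **Mediation.** The product-of-coefficients decomposition. Writing
   $\beta_1$ for the total exposure$\to$outcome effect, $\beta_2$ for the
   exposure$\to$mediator effect (univariable MR), and $\beta_4$ for the
   mediator's direct effect on the outcome (MVMR, adjusting for the
   exposure), the indirect effect is $\beta_2\beta_4$, the direct effect
   $\beta_1 - \beta_2\beta_4$, and the mediated proportion
   $100\cdot\beta_2\beta_4/\beta_1$ percent. A univariable
   mediator$\to$outcome estimate ($\beta_3$) is recorded for reference but
   never enters the product.

Two companion analyses complete the toolkit: Bayesian colocalization over a
genomic region (Wakefield approximate Bayes factors, posterior probabilities
for hypotheses H0–H4), and a single-cell expression stage that scores a
gene set per cell, splits cells at the median score, and tests differential
expression between the strata.

## Instrument selection and harmonization

Instruments pass four sequential filters — association
($p < 5\times10^{-6}$), greedy LD clumping ($r^2 < 0.001$ within a
10,000 kb window, visiting candidates in ascending p-value order with
lexicographic tie-breaks so the output is order-invariant), per-variant
instrument strength ($F = (\hat\beta/\mathrm{se})^2 \ge 10$; exactly 10 is
kept), and an optional blacklist of variants known to associate with
confounders. Each step's removals are logged.

Harmonization expresses all effects relative to the exposure's effect
allele: matching allele pairs are kept, swapped (or strand-flipped) pairs
have the outcome beta negated and the allele frequency reflected, and any
other pair is dropped as incompatible. Palindromic variants (A/T, C/G)
cannot be oriented by allele labels alone, so they are dropped whenever any
trait's effect-allele frequency is missing or within 0.08 of 0.5 (the band
[0.42, 0.58]). This drop-if-ambiguous policy is deliberately conservative;
the window is a package default, not a value taken from any particular
study, and is tunable via `palindrome_eaf_window`. Indels are accepted as
multi-character alleles; the palindrome rule only applies to single bases.
Chromosome labels are compared after stripping a leading `"chr"`.

## The estimator battery

With one instrument the Wald ratio $\hat\beta_y/\hat\beta_x$ is used (SE by
the first-order delta method, $\mathrm{se}_y/|\hat\beta_x|$; the
second-order term in $\mathrm{se}_x$ is omitted, the conventional
approximation). With two instruments, inverse-variance weighting (IVW)
only; with three or more, five estimators whose agreement in sign is the
robustness summary (`direction_consistent`, operationalized as at least
three estimates sharing the IVW sign):

* **IVW** — weighted regression of outcome on exposure effects through the
  origin, weights $1/\mathrm{se}_y^2$. The default variance model is
  *multiplicative random effects when over-dispersed*: the fixed-effect SE
  is inflated by $\sqrt{Q/(k-1)}$ only when $Q/(k-1) > 1$. This "auto" rule
  mirrors dominant practice; fixed and always-random variants are
  selectable.
* **MR-Egger** — the same regression with an intercept; the slope is the
  causal estimate and the intercept indexes directional pleiotropy. SEs are
  inflated by $\max(1, \sqrt{\mathrm{RSS}/(k-2)})$.
* **Weighted median** — ordered per-variant ratios interpolated at
  cumulative weight 0.5 (weights $\hat\beta_x^2/\mathrm{se}_y^2$
  normalized); consistent when half the weight is valid.
* **Weighted and simple mode** — the argmax of a normal-kernel density over
  the ratios, bandwidth $\phi \cdot 0.9\min(\mathrm{sd},
  \mathrm{IQR}/1.349)k^{-1/5}$ evaluated on a 512-point grid spanning the
  ratio range padded by one bandwidth; when every ratio is identical the
  common ratio is returned directly.

Median and mode SEs come from a seeded parametric bootstrap (default 1000
resamples of $\hat\beta_x$ and $\hat\beta_y$ around their observed values);
the seed is a required argument, so results are reproducible bit for bit.

## Sensitivity diagnostics

Cochran's Q (ratio heterogeneity against the IVW estimate, chi-square with
$k-1$ df), the MR-Egger intercept test, leave-one-out IVW, and a
MR-PRESSO-style global/outlier test: the observed residual sum of squares
under leave-one-out IVW fits is compared against a seeded parametric null
distribution (both $\hat\beta_x$ and $\hat\beta_y$ redrawn around the
fitted model, leave-one-out estimates recomputed per resample), with
$p = (1 + \#\{\mathrm{RSS}^* \ge \mathrm{RSS}\})/(1 + n_\mathrm{sim})$.
Per-variant outlier p-values use each variant's own simulated residual
distribution, Bonferroni-corrected; with the default 1000 resamples the
smallest attainable corrected p for 30 instruments is
$30/1001 \approx 0.03$, so the default resolves outliers at the 0.05 level
— smaller `n_sim` values may not. The distortion test of the published
MR-PRESSO procedure is out of scope here; the global and outlier tests are
what the screening rule ("no evidence when $p > .05$") consumes. PRESSO
requires at least four instruments so each leave-one-out fit retains the
IVW minimum of two, plus one for stability.

## MVMR and mediation

`mvmr_ivw()` regresses the outcome effects on all exposure-effect columns
jointly (no intercept, weights $1/\mathrm{se}_y^2$); the coefficient
covariance is the inverse weighted normal matrix scaled by
$\max(1, \mathrm{RSS}/(k-m))$. The joint instrument set is the union of the
per-trait instrument sets, re-clumped at the same thresholds and harmonized
across all traits — the union rule is an interpretation (publications
rarely state their MVMR set construction), recorded here as the package's
choice. `mediation_effects()` is exact arithmetic on its three inputs and
optionally a Sobel SE $\sqrt{\beta_2^2\mathrm{se}_4^2 +
\beta_4^2\mathrm{se}_2^2}$; when $\beta_1 = 0$ the proportion is flagged
undefined rather than reported as infinite. Because published tables round
each coefficient to three decimals before printing, a mediated proportion
recomputed from printed values can differ from the printed proportion in
the second decimal; `mrmediate` always reports full-precision arithmetic
and rounds only for display.

## Colocalization

`coloc_abf()` enumerates the five single-causal-variant hypotheses over a
region from per-variant Wakefield log approximate Bayes factors
($\log\mathrm{ABF} = \tfrac12\log(1-r) + \tfrac12 z^2 r$ with
$r = W/(V+W)$), with per-configuration priors $p_1 = p_2 = 10^{-4}$,
$p_{12} = 10^{-5}$ and prior effect SDs of 0.15 (quantitative) or 0.2
(case-control) — the conventional defaults of this algorithm family; no
study-specific values are assumed. All hypothesis sums are carried in log
space with log-sum-exp; the H3 sum over distinct pairs is computed as a
stable log-difference. Classification follows the standard thresholds:
PPH4 $\ge 0.8$ strong, $[0.5, 0.8)$ moderate, below 0.5 none. Defining the
region (the window around a lead variant) is the caller's responsibility.

## Single-cell stage

Cells pass QC when their detected-gene count lies in [500, 4000] and their
mitochondrial fraction is at most 10% (boundaries kept; exclusion rules are
strict inequalities). Log-normalization is
$\log(1 + \mathrm{count}/\mathrm{total}\times 10^4)$. Module scores follow
the binned-control recipe: genes ranked by mean expression, cut into 25
equal-frequency bins, and each gene-set gene compared against 100 control
genes drawn (seeded) from its own bin; the score is the set mean minus the
pooled control mean, so adding a constant to the whole matrix leaves scores
unchanged. The bin and control counts are the method's conventional
defaults (the underlying publication names the method but no parameters);
bins smaller than the control count are sampled with replacement with a
warning — expected for matrices under ~2500 genes. Cells strictly above the
median score are "high", ties go to "low" (an explicit tie-break the source
method leaves undefined). Differential expression uses the two-sided
Wilcoxon rank-sum normal approximation with tie correction, restricted to
genes detected in at least 10% of either group; fold changes are computed
on the count scale, $\log_2[(\overline{e^{x_\mathrm{high}} - 1} +
\varepsilon)/(\overline{e^{x_\mathrm{low}} - 1} + \varepsilon)]$ with
$\varepsilon = 10^{-9}$, and the
pass gate is FDR < 0.05 with $|\log_2\mathrm{FC}| > 0.585$ (1.5-fold). A
constant gene reports $p = 1$. Where a source reports both 0.585 and 0.5
thresholds in different sections, the methods-section value 0.585 is the
default and the threshold is an argument.

## The synthetic-data generators

Real pipelines of this kind consume controlled-access GWAS and large
single-cell cohorts; the generators provide study-shaped substitutes with
known truth so every stage is testable offline.

`simulate_gwas_triplet()` draws summary statistics directly from
marginal-effect theory rather than simulating individual-level genotypes —
the same statistical structure at desk scale. Traits have unit variance and
follow the structural equations
$X = \sum_j \gamma_j G_j + e_X$,
$M = \beta_2 X + \sum_j \alpha_j G_j + e_M$,
$Y = \delta X + \beta_4 M + \sum_j \delta_j G_j + e_Y$ (writing $\delta$
for the direct effect), with residual variances completing unit trait
variance (an infeasible budget raises an error). Reported effects are the
LD-folded marginals plus noise with
$\mathrm{se} = (2\,\mathrm{maf}(1-\mathrm{maf})N)^{-1/2}$, drawn
independently for three non-overlapping cohorts — emulating the
independent-consortia design in which sample overlap is minimal. A binary
outcome is treated on the liability/log-odds scale without explicit
prevalence modelling.

Default conditions: 150 exposure instruments explaining 30% of exposure
variance and 50 mediator-specific instruments explaining 15% of mediator
variance. These are molecular-QTL-class instruments (per-instrument
$F \approx 200\text{–}300$, as is routine for metabolite and cis-pQTL lead
variants); at this strength the $p < 5\times10^{-6}$ selection is
essentially non-binding and the classical winner's-curse/weak-instrument
attenuation (of order $1/F$) sits below Monte-Carlo resolution, so
parameter-recovery checks measure the estimators rather than selection
artefacts. The mediator-specific instruments are essential for
identification: without them the two MVMR design columns are proportional
($\hat\beta_x^{(M)} \approx \beta_2 \hat\beta_x^{(X)}$) and the joint model
is collinear up to noise — just as a real metabolite/protein pair is only
jointly analyzable because each has QTLs of its own. Structural defaults
$\beta_2 = 0.3$, $\beta_4 = 0.2$, direct $= 0.14$ give a total effect of
0.2 and a mediated proportion of 30%. Horizontal pleiotropy
(`pleiotropy_fraction`, `pleiotropy_sd`) adds mean-zero direct paths from a
fraction of exposure instruments to mediator and outcome; LD blocks place
consecutive instruments in exchangeable-correlation blocks within the
clumping window. What the generator does **not** emulate: genome-wide
realistic LD panels, population stratification, relatedness, allele-coding
errors, or sample overlap — so passing tests demonstrate estimator
correctness under the stated model, not robustness to those data
pathologies.

`simulate_expression()` is a log-normal/Poisson sampler: log-normal gene
base means and library sizes, Poisson counts, a known fraction of cells
with gene-set means multiplied by `activity_effect`, and optional spiked DE
genes at a known fold change between the latent groups. It does not model
zero inflation beyond Poisson sampling, batch structure, or cell-type
mixtures.

## Worked example

```{r example, eval = FALSE}
library(mrmediate)

sim <- simulate_gwas_triplet(sim_config(seed = 7))
cfg <- pipeline_config(seed = 7)

iv <- select_instruments(sim$exposure, sim$ld)
expo <- as_summary_stats(
  as.data.frame(sim$exposure)[sim$exposure$variant_id %in% iv$variant_id, ],
  "exposure")

beta1 <- ivw(harmonize(expo, sim$outcome))$beta    # total effect
beta2 <- ivw(harmonize(expo, sim$mediator))$beta   # exposure -> mediator
mv <- stage4_mvmr(sim$exposure, list(sim$mediator), sim$outcome,
                  sim$ld, cfg)[[1]]
stage5_mediation(beta1, beta2, mv, mediator_id = "mediator")
```

## Numerical choices and limitations

* Reproducibility: every stochastic routine takes an explicit seed; the
  pipeline manifest records a configuration hash so a run can be replayed
  bit for bit.
* Problem sizes in the test and acceptance suites (400-variant panels,
  100-seed recovery ensembles, 1000-replicate null calibrations,
  2000-gene/1000-cell expression matrices) were chosen as the smallest
  ensembles at which Monte-Carlo error is comfortably below the tolerances
  being checked.
* The p-value tie-break in clumping, the "low" assignment of median-tied
  cells, and the union-then-reclump MVMR instrument rule are explicit
  determinism choices where common practice is silent.
* Missing LD entries are treated as $r = 0$ with a warning — clumping on a
  sparse panel thins less than it would with complete LD, it never fails
  silently.
* Not implemented (out of scope): Steiger directionality filtering,
  MR-RAPS/debiased IVW, the PRESSO distortion test, SuSiE-style
  multi-causal-variant colocalization, proxy-variant lookup, liftover, and
  any network-access data clients.
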