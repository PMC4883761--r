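---
title: "Methods: models, preprocessing and design choices in postoprisk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, preprocessing and design choices in postoprisk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

We forecast two binary postoperative complications — acute kidney injury
(AKI) and severe sepsis — from features available before surgery. The
statistical difficulties are not in the classifiers themselves but in the
data: clinical labs are skewed and contain entry errors; many features are
near-duplicates of each other (hemoglobin and hematocrit, two creatinine
derivations, a block of neighborhood census variables); and the strongest
predictors are high-cardinality nominal identifiers (surgeon, residence
area, procedure code) that cannot enter a regression as hundreds of dummy
columns without overfitting. The package therefore couples four standard
risk models to a bespoke preprocessing chain, and evaluates everything with
repeated stratified hold-out.

## The synthetic cohort generator

Real perioperative registries are protected, so the package ships a
generator (`cohort_spec()` / `generate_cohort()`) whose defaults emulate a
large academic surgical cohort; it is first-class, tested code, and every
downstream stage is validated against its known ground truth.

The generative model is additive on the logit scale. For patient $j$ with
covariates $x_j$,

$$\operatorname{logit} P(E_j = 1) = \alpha + \sum_i f_i(x_{ij}),$$

with one Bernoulli draw per outcome given the shared covariates. The
intercept $\alpha$ is calibrated per outcome by monotone root-finding so
that the mean predicted probability equals the target prevalence (0.36 for
AKI, 0.05 for sepsis) to within $10^{-6}$; realized prevalence then differs
from the target only by binomial noise.

Design choices that define the default "study conditions":

* **Continuous block (12 features).** Multivariate normal on a latent
  standardized scale with a factor-structured correlation matrix: a renal
  factor (two near-duplicate creatinine measures, r = 0.89, against eGFR at
  r = -0.64), a red-cell factor (hematocrit-hemoglobin r = 0.90), and a
  neighborhood socio-economic factor tying five census-style variables and
  distance-to-hospital together. Skewed variables (creatinine, census
  counts, income, distance) are lognormal: the latent normal is
  exponentiated, and true effects act on the latent (log) scale. This
  matters: it makes a linear-in-the-raw-value model mildly misspecified for
  skewed labs, exactly as in practice.
* **Effect shapes.** Age and creatinine carry linear effects; eGFR and
  hematocrit carry U-shaped effects $f(z) = c\,(z^2 - 1)$ with $c = 0.18$
  on the standardized scale. The curvature is deliberately mild: risk
  curves for these labs are clinically "mostly monotone with bends at the
  extremes", and under strong curvature a purely linear model would be
  unrealistically crippled. Hemoglobin, the duplicate creatinine, and most
  census variables have *zero* conditional effect — they are informative
  only through correlation, which is what punishes classifiers that assume
  feature independence.
* **Binary indicators (24).** Comorbidity/medication/operative flags drawn
  from a latent Gaussian threshold model with within-cluster correlation
  0.55 (cardiac, renal, metabolic, oncologic, infection, acuity clusters);
  several cluster members again have zero conditional effect.
* **Nominal features.** A 500-level surgeon identifier and a 71-level
  county, with Zipf-distributed level frequencies (exponents 1.1 and 1.0)
  and i.i.d. normal level effects (sd 0.30 / 0.20).
* **Procedure codes.** A random 4-digit prefix hierarchy under 18 top-level
  classes; every tree node at depths 2/3/4 carries a normal effect
  (sd 0.25/0.15/0.08), so related procedures share risk. Leaf frequencies
  are Zipf (exponent 1.05), giving the long tail of rare codes that makes
  aggregation necessary.
* **Corruption.** Missingness is injected completely at random (5% per
  feature) — the simplest mechanism consistent with mean imputation; gross
  outliers replace 1% of each continuous feature at more than 8 scale units
  from the center, with their indices recorded for test oracles.
* **Outcomes are conditionally independent** given covariates; the real
  AKI-sepsis dependence is not modeled, as nothing downstream uses it.
* **Seeds.** One master seed; every stage derives a child seed through a
  fixed congruential map, so identical specs give bitwise-identical cohorts.

What the generator does *not* emulate: informative missingness,
measurement drift over calendar time, outcome-label noise, and dependence
between the two outcomes. Passing tests therefore demonstrate correctness
of the machinery and its operating characteristics under a known additive
truth — not clinical performance on any real registry.

## Cleaning

Continuous columns: values strictly below the 1st or strictly above the
99th percentile (type-7 linear-interpolation quantiles; the estimator is a
deliberate, documented choice since several conventions exist) are flagged,
then flagged-or-missing entries are replaced by the mean of the retained
values. Nominal and code columns: missing becomes the reserved
`__missing__` level, which the encoder treats as an ordinary level. Binary
columns are mode-imputed. Cleaning an already-cleaned cohort is a no-op:
re-flagging is disabled on the second pass, since quantile trimming would
otherwise shave another 1% tail on every application. In the evaluation
harness the cleaning statistics are fitted on the training fold and applied
to validation (honest mode); `paper_mode = TRUE` fits them on the whole
cohort before splitting, which is how such pipelines are often run in
practice and is measurably optimistic for high-cardinality features.

## Outcome-conditional encoding

Each nominal level is scored by the smoothed log-likelihood ratio
$\log\frac{(n_1 + s)/(N_1 + 2s)}{(n_0 + s)/(N_0 + 2s)}$ with pseudo-count
$s = 0.5$ by default; the unsmoothed ratio is the $s \to 0$ limit, and the
pseudo-count exists because zero cells occur in real strata even after
grouping. Levels with fewer than 100 records (strict inequality) are pooled
into an "other" group and subgrouped by 1-D k-means on their event
proportions — for a binary outcome the "proportions of patients from
different classes" are one-dimensional, so the clustering is on $\hat p$
with 10 restarts and a deterministic seed; the effective number of clusters
is capped at the number of distinct proportions. Transform-time levels
unseen at fit time receive the score of the largest other-subgroup (the
least-informative pooled estimate available); this situation only arises in
honest fold-wise fitting, which is precisely when a principled fallback is
needed.

The encoding's justification is the optimal-split property: ordering levels
by this score makes the best Gini-impurity threshold split coincide with
the best over all $2^{k-1}-1$ binary level partitions. The acceptance suite
verifies this by exhaustive enumeration on randomly generated 8-level
problems.

## Procedure-code aggregation

Codes are digit strings of length 2-4 (decimal points stripped), forming a
prefix tree whose nodes are code classes. Aggregation walks each top-level
class depth-first: a leaf with at least `min_count` patients becomes its
own group; under-threshold siblings merge into their parent's residual
(lexicographic sibling order for determinism), residuals still under
threshold merge upward, and residuals reaching the 2-digit top level are
retained as groups regardless of size — so every non-top-level group meets
the threshold, groups partition the observed codes, and counts are
conserved. The number of top-level classes is whatever the data contain;
nothing is hard-coded to a particular coding system's 18 classes. The
threshold is chosen by grid search over {50, 100, 150, 250, 500}; the
selection criterion (held-out univariate AUC of the encoded grouping) is a
package decision, as is retaining per-class top-level residuals rather
than one global pool (a flag could pool them globally; per-class retention
preserves more structure). At a registry-like patients-per-level ratio this
aggregation removes over 80% of the levels.

## Models

* **Logistic regression** is the `stats::glm` IRLS fit.
* **GAM**: `mgcv::gam` with cubic regression splines (`bs = "cr"`, basis
  dimension 10 per term) and REML smoothness selection, restricted to the
  four clinically plausible non-monotone labs (age, eGFR, hematocrit,
  hemoglobin) by default. After the first fit, smooth terms with effective
  degrees of freedom below 1.5 are demoted to linear and the model is
  refitted — "close to 1" is unquantified in general usage, and 1.5 is the
  package's threshold; terms with fewer than 10 distinct values are demoted
  up front. With every term linear the GAM reproduces logistic regression
  to numerical precision (a nesting the tests assert at $10^{-6}$). One
  caveat the tests encode honestly: under a truly linear effect, REML edf
  concentrates near 1.01 but roughly one noise realization in eight
  supports edf > 1.5 at n = 20,000, so linearization is asserted as a
  majority property over replicate cohorts rather than per-cohort.
* **Naive Bayes** is implemented in the package (typed conditionals:
  Gaussian for continuous columns, Laplace-smoothed Bernoulli for 0/1
  columns, variances floored at $10^{-9}$, posterior normalized over both
  classes); a general-purpose external implementation is used in the test
  suite as an independent cross-check on continuous data.
* **SVM**: `e1071::svm`, RBF kernel, cost 1, inverse-prevalence class
  weights (which matter at 5% prevalence), features standardized
  internally. Kernel and cost are package defaults, not claims about any
  particular prior work; decision scores are used directly for AUC and
  thresholded at 0 for accuracy/PPV, and no probability calibration is
  applied by default (so calibration statistics are skipped for the SVM).

## Evaluation harness

Stratified 70/30 splits allocate each outcome class separately, so both
partitions match the cohort prevalence to within half a percentage point.
Default 50 repetitions (the analysis scripts use 10 to stay in minutes at
n = 20,000; the acceptance script uses 2 — the reported quantities are
means over repetitions either way). AUC is the Mann-Whitney rank form with
ties counted half, asserted against exhaustive pair enumeration at
$10^{-12}$. Accuracy and PPV use threshold 0.5 on probabilities (0 on SVM
scores); PPV is reported missing when no patient is predicted positive.
Two kinds of 95% interval are computed and labeled: a percentile bootstrap
over validation patients within a split (B = 2000 by default) and
across-repetition percentile intervals; published repeated-split studies
are often ambiguous about which is meant, so both are available. The
Hosmer-Lemeshow statistic groups patients into risk deciles and refers
$\sum_g (O_g - E_g)^2 / (n_g \bar p_g (1 - \bar p_g))$ to $\chi^2_{g-2}$,
merging groups with vanishing expected counts; its type-I error and the
bootstrap's coverage are verified by simulation in the acceptance suite.
Model pairs are compared by a two-sided Wilcoxon signed-rank test on
per-repetition AUC differences ("nonparametric comparison" made concrete;
all-zero differences return p = 1).

## Numerical and degenerate-input conventions

Quantiles are type 7 with strict inequalities for flagging; constant
vectors flag nothing. The encoder refuses a single-class outcome; the
smoothing-zero score errors on zero cells rather than returning infinity.
k-means on fewer distinct proportions than requested clusters silently
reduces the cluster count. The AUC and split functions reject one-class
inputs. PCA refuses constant columns (the harness drops them first) and
more components than features. Perfect separation in the logistic fit
surfaces as a warning, not an error.

## Problem sizes

The test suite runs the full property checks at the sizes stated in each
test: brute-force encoder optimality at n = 2,000 over 50 fixtures,
recovery and model-ordering checks on n = 20,000 cohorts (20 seeds for the
ordering), operating-characteristic simulations at 200 replicates, and the
Bayes-bound check at n = 8,000 including the SVM. The acceptance script
evaluates the full factorial at n = 20,000 with 2 repetitions. These sizes
were chosen so the whole suite completes in minutes on one core while
keeping every Monte-Carlo band comfortably away from its pass boundary.

## Known limitations

The generator's truth is additive — no interactions — so the comparison
cannot reward models for finding interaction structure. MCAR missingness
makes mean imputation benign; under informative missingness the same
pipeline would be biased, and no multiple-imputation alternative is
provided. The SVM is not tuned (no kernel/cost search), matching its role
as a comparison arm rather than a production model. The Hosmer-Lemeshow
variance form is the classical one; its known sensitivity to grouping
choices is not addressed beyond decile grouping. Sample-size planning
utilities (e.g. CI-width targets for a validation cohort) are out of scope.
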