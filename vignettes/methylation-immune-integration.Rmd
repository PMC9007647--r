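---
title: "Methods: immunophenotype scoring, methylation integration and prognostic screening"
author: "epiImmune"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: immunophenotype scoring, methylation integration and prognostic screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiImmune)
```

This vignette is the package's account of its own methods: the models and
their assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic-cohort generator does and does not emulate,
and the places where the design was genuinely open and a choice had to be
made.

## 1. Immune scoring

### ssGSEA

`ssgseaScore()` implements the rank-weighted running-sum enrichment score.
Genes are ranked by decreasing expression with *average ranks for ties* —
the tie policy matters because the rank weight
$v_i = (N - \mathrm{rank}_i + 1)^\alpha$ enters the in-set partial sum
directly, and average ranks make the score invariant to the storage order
of tied genes. The in-set ECDF is weighted by $v$, the out-of-set ECDF is
unweighted, and the score is the sum of their differences over all ranked
positions. With $\alpha = 0$ the score is a pure rank statistic, invariant
under any strictly monotone transformation of the expression column.

The exponent defaults to $\alpha = 0.25$, a mild emphasis of top-ranked
genes; the method's behaviour is not sensitive to it in the range
$[0, 1]$, and it is exposed everywhere. There is deliberately **no
cross-sample normalization of raw scores inside `ssgseaScore`**; whether
scores are standardized is decided one level up.

### IMaS, IMpS, CYT

`computeImas()` z-standardizes each gene set's scores across samples
before averaging within a feature category and applying the $\pm 1$ sign
weight. Standardization makes categories with different set sizes (the
effector category holds four sets, Th1 one) commensurable in the
downstream clustering; raw-score mode is available via
`standardize = FALSE`, and neither mode is claimed to be canonical.
`computeImps()` is the plain sum of the seven signed IMaS values — an
exact identity that the tests assert, not an approximation. `computeCyt()`
is the geometric mean of GZMA and PRF1 on the linear scale with a
pseudocount (default 1.0) because microarray/RNA-seq zero-handling is
otherwise undefined; at typical immune-gene expression the pseudocount is
negligible.

### Clustering and canonical labels

`clusterImmunophenotypes()` uses Euclidean distance with Ward linkage
(`ward.D2`), both configurable. Hierarchical clustering was chosen over
k-means for fidelity to standard practice in this analysis family; the
labels are **canonicalized by mean IMpS** (C2 highest, C3 lowest, C1 the
remainder) rather than by dendrogram order, which makes the labelling
deterministic and comparable across cohorts. Degenerate inputs
(all-identical rows, fewer samples than clusters) are hard errors.

### Deconvolution

`deconvolveFractions()` solves
$\min_f \lVert \beta - R f \rVert^2$ subject to $f \ge 0,\ \sum f \le 1$
per sample. The inequality-constrained problem is reduced to non-negative
least squares by adding a slack fraction and a heavily weighted penalty row
that enforces $\sum f + s = 1$; the penalty weight starts at $10^3 \cdot
\max(1, \max|R|)$ and is relaxed tenfold if the active-set solver stalls
numerically (the relaxation changes the solution by at most the residual
divided by the squared weight, far below the reporting precision). Exact
mixtures are recovered exactly; tests compare noisy recoveries against an
exhaustive grid search over the simplex at step 0.01.

## 2. Methylation–expression integration

### Differential testing

Per-feature **Welch two-sample tests** are used on log2 expression and on
beta values, with Benjamini–Hochberg adjustment across features. This is a
deliberate, declared substitute for moderated linear models: it is exact
under the generator's Gaussian noise, has no hyperparameters, and keeps
the package self-contained. No equivalence with empirical-Bayes moderated
statistics is claimed; what is preserved exactly is the *selection rule*:

* DEG: raw $p < 0.05$ and $|\log_2 FC| > 0$;
* DMP: **adjusted** $p < 0.05$ and $|\Delta\beta| > 0$.

The asymmetry (raw p for genes, adjusted p for probes) is intentional and
kept as the analysis family defines it. Methylation effect size is always
reported as $\Delta\beta$ (difference of group means on the beta scale);
`useMValues = TRUE` runs the test on logit-transformed beta (M-values,
variance-stabilized) while still reporting $\Delta\beta$. Zero-variance
features get $p = 1$ (equal means) so they can never be selected, rather
than being dropped and silently changing the BH denominator.

### The mIMg screen

`selectMimg()` computes three Spearman correlations per candidate pair —
probe vs gene, probe vs IMpS, gene vs IMpS — with tie-corrected ranks and
t-approximation p-values, and flags a pair when **all three** pass
$|r| > 0.5$ (strict inequality) and $p < 0.05$. The boundary $|r| = 0.5$
is excluded; with continuous data the boundary has probability zero, so
the choice is documentation rather than behaviour.

`classifyRegulation()` assigns cis/trans from the **sign of the Spearman
correlation** instead of comparing fold-change signs: the correlation is
the continuous version of the same co-trend, is invariant to monotone
transforms of either variable, and does not depend on how the contrast
groups were drawn. $r = 0$ is `undetermined`; a strict mode additionally
demands significance.

`regionEnrichmentTest()` builds the 2×2 table (promoter = TSS200, TSS1500,
1stExon, 5'UTR vs the rest; or CGI shore vs island with other probes
excluded) against trans vs cis and applies the chi-squared test **with
Yates continuity correction** by default, matching the default of the
statistical environment this analysis family uses; the uncorrected
statistic is one argument away, and both closed forms are asserted in the
tests.

## 3. Survival machinery

Standard estimators are delegated to the `survival` package behind the
package's own surface: Kaplan–Meier (`survfit`), log-rank (`survdiff`),
Cox partial likelihood with **Efron ties** (`coxph`; Breslow optional) and
Harrell's C (`concordance`, higher risk = earlier failure, risk ties
0.5). Tests verify each against hand-tabulated risk sets, a brute-force
partial-likelihood grid search and $O(n^2)$ pair enumeration, so the
delegation is checked, not assumed.

The pieces specific to this analysis are implemented here:

* `optimalCutpoint()` — the maximally selected standardized log-rank
  statistic over every admissible split leaving at least
  $\lceil \text{minprop} \cdot n \rceil$ samples per side (minprop
  defaults to 0.1). The scan uses a precomputed risk-set engine, ties
  break deterministically toward the smallest threshold, and the result
  equals exhaustive enumeration on every tested instance.
* `timeDependentAuc()` — cumulative/dynamic AUC at fixed horizons with
  inverse-probability-of-censoring weights from the Kaplan–Meier estimate
  of the censoring distribution (cases weighted by $1/G(T^-)$, controls by
  $1/G(t)$). Without censoring before the horizon it reduces exactly to
  the Mann–Whitney statistic, which the tests exploit as an oracle.
* `decisionCurve()` — net benefit
  $NB(p_t) = TP/n - (FP/n)\, p_t/(1-p_t)$ with treat-all and treat-none
  references. Subjects censored before the horizon are excluded
  (complete-case), a documented simplification of survival decision-curve
  analysis.

### The prognostic screen and selection bias

`prognosticScreen()` dichotomizes each marker at its optimal cutpoint
(reference level = low marker, so HR is high vs low; the reference level
is explicit because conventions differ) and fits a Cox model with the
marker factor plus age, gender and stage. Stage enters as a single ordinal
covariate (I < II < III < IV as 1..4) by default — the most parsimonious
encoding when stage effects are monotone — with dummy coding available.

Testing a marker *at its own optimal cutpoint* is strongly
anti-conservative: in null simulations the uncorrected covariate-adjusted
Cox p flags roughly 40% of independent markers at the 0.05 level, because
the cutpoint was chosen to maximize group separation. The screen therefore
also computes the improved-Bonferroni (Miller–Siegmund) approximation to
the null distribution of the maximal statistic over the
$[\text{minprop}, 1-\text{minprop}]$ quantile range,

$$p \approx \frac{4\varphi(b)}{b} +
  \varphi(b)\Big(b - \tfrac1b\Big)
  \log\frac{\varepsilon_2(1-\varepsilon_1)}{\varepsilon_1(1-\varepsilon_2)},$$

and by default (`selectionAdjust = TRUE`) requires *both* the adjusted Cox
p and this selection-corrected p to fall below the threshold. Under the
null this brings the flag rate to ≈5–6% (measured over 600 simulations);
power against a planted log-hazard of 0.7 per SD at $n = 400$ remains
essentially 1. Setting `selectionAdjust = FALSE` reproduces the
uncorrected behaviour of dichotomize-then-test workflows. The
approximation is only meaningful for statistics above 1, so smaller
statistics report $p = 1$ — they are never near significance anyway.
Per-marker failures (constant markers, inestimable models) are recorded in
the report's `error` column without aborting the screen, and sample
subsets (e.g. mutation-status strata) are supported via `subset`.

## 4. The synthetic-cohort generator

`generateCohort()` is first-class, tested code, not a fixture. It plants
exactly the structure the pipeline is supposed to find, with defaults that
describe one fixed set of study conditions:

* **Clusters.** 300 samples in proportions (0.30, 0.35, 0.35) for
  hot/medium/cold, assigned by largest-remainder counts and a random
  permutation so no cluster is ever degenerate. A latent immune axis $a$
  takes values $+e/2$, $0$, $-e/2$ (with $e$ = `effectSizeExpr`, default
  1.5 log2 units).
* **Immune expression.** Eleven gene sets (30 genes each by default —
  the size of typical curated immune signatures) respond to the axis;
  positive categories with amplitude 1, negative categories (suppressors,
  Th2, co-inhibitors) with amplitude 0.45 plus independent category-level
  noise of SD $0.12e$. The attenuation is what keeps
  $\mathrm{IMpS} = \sum \pm \mathrm{IMaS}$ — four positive minus three
  sign-flipped negative categories — a faithful readout of the axis
  instead of cancelling itself; biologically it reflects that suppressive
  programs track inflammation loosely. Medium-cluster samples additionally
  get per-category heterogeneity of SD $e/6$, making the medium phenotype
  a mixed blob rather than a sharp midpoint.
* **Planted pairs.** Each of the 40 planted pairs (70% trans by default)
  is built from an explicit three-way correlation target: probe latent vs
  axis $\pm 0.8$, gene latent vs axis $0.78$, probe vs gene at the
  configured coupling converted from the Spearman to the Pearson scale via
  the Gaussian-copula relation $\rho_P = 2\sin(\pi \rho_S/6)$. Trans pairs
  flip the probe's sign (beta high where immune activity is low) and the
  probe–gene coupling. Betas are inverse-logit transforms of Gaussian
  latents (logit-normal), so they lie in $[0,1]$ with no truncation
  artifacts; the logit slope is calibrated so the hot-vs-cold beta
  separation matches `effectSizeBeta` (default 0.25).
* **Global methylation drift.** All background probes share a drift of
  0.15 logit units per SD of immune activity, planting the
  inflamed-tumors-are-globally-hyper-methylated trend that the per-sample
  average beta is expected to show (C2 > C1 > C3). A side effect is that
  most probes are weakly differential between C3 and C2 — the realistic
  situation in which the triple Spearman screen, not the DMP filter, does
  the selective work.
* **Deconvolution markers.** Sixty marker probes are convex mixtures of
  two stored reference methylomes (immune-like, epithelial-like) with the
  immune weight rising from ~0.15 (cold) to ~0.45 (hot) plus jitter, and
  beta-scale noise of $0.02 \times$ `noiseSd`; at `noiseSd = 0` the
  mixtures are exact and the true fractions are recovered to machine
  precision.
* **Survival.** Times are exponential with log-hazard linear in the
  standardized *observed* expression of the first `length(hazardCoefficients)`
  planted genes (default a single coefficient of 0.7), so Cox recovery is
  unbiased by construction; the exponential baseline (median ≈ 36 months)
  is the simplest model whose Cox log-hazard is exactly linear.
  Censoring is uniform and independent, with the upper bound solved
  numerically so the expected censoring fraction matches
  `censoringRate` (default 0.3).
* **Annotation.** Planted trans probes are promoter-annotated with
  probability 0.8, cis probes 0.4, background 0.5; CGI-shore enrichment
  for trans probes follows the same pattern. These probabilities are what
  the probe-location enrichment tests are expected to detect.

What the generator does **not** emulate: array chemistry and type-I/II
probe bias, co-methylation block structure, batch effects,
library-size/normalization artifacts, multi-gene probes, non-exponential
baseline hazards, or informative censoring. Consequently a green test
suite demonstrates that the algorithms recover what was planted under
clean, well-specified noise — it does not certify performance on real
450K/RNA-seq data, where the upstream normalization the package leaves
out-of-scope does substantial work.

## 5. Numerical choices and problem sizes

All tie-breaks are deterministic: average ranks in ssGSEA, smallest
threshold in the cutpoint search, canonical IMpS-ordered cluster names.
The pipeline is bit-reproducible for identical input and seed; each
stage failure aborts with the stage name. Validity methods on the S4
containers reject beta values outside $[0,1]$, mismatched sample ids,
out-of-vocabulary annotation labels and non-positive survival times at
construction, so downstream code can assume clean inputs.

The test suite and the acceptance script run cohorts of 300–500 samples
with ~2000 background features, 10–20 seed replicates for stochastic
properties, and 200–600 replicates for calibration rates — sizes chosen so
that the Monte-Carlo error of each checked quantity is several times
smaller than the band it is checked against, while a full run stays in the
minutes range on one core.

## 6. Known limitations

* The Welch substitution loses the variance-shrinkage power advantage of
  moderated statistics at small sample sizes; with the default cohort
  sizes this is immaterial, but for n per group below ~10 real analyses
  should use a moderated model upstream and feed the results in.
* The Miller–Siegmund correction is an upper-tail approximation; it is
  mildly conservative for moderate n and ignores the discreteness of the
  candidate-split set.
* The decision-curve implementation is complete-case at the horizon and
  therefore biased when censoring before the horizon is heavy.
* Cross-cohort intersection matches pairs by identifier; it does not
  attempt cross-cohort cluster-label transfer beyond the canonical IMpS
  ordering applied within each cohort.
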