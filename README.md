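# epiImmune

Integrative analysis of tumor immunophenotype and DNA methylation for
matched expression/methylation cohorts (lung adenocarcinoma being the
motivating setting), aimed at epigenomics and tumor-immunology analysts who
want the whole chain — immune scoring, immunophenotype clustering,
methylation–expression integration and prognostic evaluation — as tested,
reusable R functions rather than a pile of scripts.

## The model

**Immune scoring.** For each sample, every immune gene set is scored by
single-sample gene-set enrichment (ssGSEA). With genes ranked by decreasing
expression (ranks 1..N, average ranks for ties) and rank weight
v<sub>i</sub> = (N − rank<sub>i</sub> + 1)<sup>α</sup>,

> ES = Σ<sub>i=1..N</sub> [ P<sub>in</sub>(i) − P<sub>out</sub>(i) ],  
> P<sub>in</sub>(i) = Σ<sub>j≤i, j∈S</sub> v<sub>j</sub> / Σ<sub>j∈S</sub> v<sub>j</sub>,  P<sub>out</sub>(i) = #{j ≤ i, j∉S} / (N − |S|).

Seven immune feature categories (effectors aCD4+T/aCD8+T/CD4+Tem/CD8+Tem,
suppressors Treg/MDSC, Th1, Th2, MHC, co-stimulators, co-inhibitors) carry
sign weights w ∈ {+1, −1}; the signed per-category mean of (z-standardized)
ssGSEA scores is the immune activity score **IMaS**, and the
**immunophenotype score IMpS = Σ<sub>f</sub> IMaS<sub>f</sub>**. Cytolytic
activity is **CYT = √(GZMA · PRF1)** on the linear expression scale.
Hierarchical clustering (Euclidean/Ward) of the sample × 7 IMaS matrix cut
at k = 3 gives the immunophenotypes, renamed canonically so that mean IMpS
satisfies **C2 (hot) > C1 (medium) > C3 (cold)**. Immune and epithelial
cell fractions are estimated from methylation by reference-based
constrained least squares (f ≥ 0, Σf ≤ 1).

**Methylation integration.** Differential genes (Welch test on log2
expression, DEG: raw p < 0.05 and |log2FC| > 0) and differential probes
(Welch on beta, DMP: BH-adjusted p < 0.05 and |Δβ| > 0) between the
noninflamed (C3) and inflamed (C2) clusters are overlapped via the probe
annotation into candidate pairs (mDEGs). A pair is an immune-related
methylation-regulated pair (**mIMg**) when all three Spearman screens pass
|r| > 0.5 and p < 0.05: probe↔gene, probe↔IMpS, gene↔IMpS. The sign of the
probe–gene correlation classifies the pair as **cis** (same-direction
co-trend) or **trans** (opposite; e.g. promoter hyper-methylation silencing
the gene), and 2×2 chi-squared tests (Yates) ask whether promoter or
CGI-shore probes are enriched among trans pairs.

**Prognosis.** Each mIMg probe and gene is dichotomized at the maximally
selected log-rank cutpoint (minprop = 0.1) and entered into a Cox model
adjusted for age, gender and stage; a marker is called prognostic when both
the adjusted Cox p and the selection-corrected p of the maximal statistic
are < 0.05. Kaplan–Meier/log-rank, Harrell's C, IPCW time-dependent AUC and
decision-curve net benefit complete the toolkit.

A synthetic-cohort generator (`generateCohort`) plants all of this
structure — three latent clusters, coupled probe/gene pairs with a target
Spearman correlation, promoter-biased annotation, reference-mixture
methylomes, exponential survival with known log-hazards — and exposes the
ground truth, so every stage can be validated against a recoverable target.

## Worked example

```r
library(epiImmune)

cohort <- generateCohort(cohortConfig(seed = 42))  # 300 samples, 40 planted pairs
report <- runPipeline(cohort)
report
#> MimgReport
#>   funnel: genes=2372, probes=2100, deg=462, dmp=2098, mdegPairs=133,
#>           mimgPairs=40, prognosticPairs=40
#>   prognostic screen: 80 markers, 80 significant

sc <- scoreTable(report)
round(tapply(sc$IMpS, sc$cluster, mean), 2)
#>    C1    C2    C3
#>  0.20  2.57 -2.38
```

The funnel line is the filter chain: 2098 probes differ between C3 and C2
(the planted global methylation drift makes most probes weakly
differential), 133 candidate probe/gene pairs survive the DEG∩DMP overlap,
and exactly the 40 planted pairs pass the triple Spearman screen. Mean IMpS
orders the canonical clusters hot > medium > cold.

```r
hits <- subset(mimgPairs(report), isMIMg)
head(hits[, c("probe", "gene", "rPG", "rPI", "rGI", "regulationClass")], 3)
#>        probe    gene    rPG    rPI   rGI regulationClass
#> 94 cgS002001 G002331 -0.812 -0.668 0.651           trans
#> 95 cgS002002 G002332 -0.822 -0.641 0.583           trans
#> 96 cgS002003 G002333 -0.845 -0.679 0.656           trans
table(hits$regulationClass)
#>   cis trans
#>    12    28
```

Negative rPG with positive rGI is the trans pattern: the probe is
hyper-methylated exactly where the gene is silenced and immune activity is
low. The 28/12 split recovers the configured 70% trans fraction.

```r
scr <- screenTable(report)
head(scr[scr$significant, c("id", "type", "HR", "lower95", "upper95", "coxP")], 3)
#>        id type   HR lower95 upper95     coxP
#> 1 G002331 gene 3.94    2.91    5.33 5.68e-19
#> 2 G002332 gene 2.99    2.23    4.02 3.28e-13
#> 3 G002333 gene 2.28    1.71    3.04 1.80e-08
```

HR > 1 for the high-expression group of the planted hazard gene (true
log-hazard 0.7 per SD) and of the genes correlated with it through the
immune axis, with age/gender/stage-adjusted confidence intervals.

File-based runs use the same formats throughout: `writeCohort()` writes
TSV matrices, a GMT panel and a clinical table that `runPipelineConfig()`
(YAML) or the thin CLI wrapper `inst/scripts/run_pipeline.R` consume; a
synthetic cohort's ground truth goes to a `truth.json` sidecar the pipeline
never reads.

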