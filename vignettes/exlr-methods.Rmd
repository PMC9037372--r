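---
title: "Methods: building and validating exLR diagnostic signatures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building and validating exLR diagnostic signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exlr)
```

# The problem

Plasma extracellular vesicles carry long RNAs (mRNA and lncRNA, "exLR")
whose abundance profiles differ between colorectal cancer (CRC) patients,
colorectal adenoma (CRA) patients, and healthy individuals. Given a
gene-level read-count matrix from exLR sequencing of the three cohorts,
the package builds a diagnostic gene signature ("d-signature"): a small
ordered gene panel plus a frozen SVM classifier that scores a new plasma
sample's probability of coming from a cancer patient. Around that core it
provides the supporting analyses such a study needs: quantification and
sample QC, differential expression, gene-set enrichment scoring across
cohorts, and survival screening of per-sample scores.

Because no public count matrix accompanies the study design this package
targets, a first-class synthetic cohort generator (`simulate_cohort()`)
produces data with the statistical structure the analysis assumes, plus a
ground-truth manifest, so every stage is testable end to end.

# Pipeline stages and their models

## TPM quantification over long-RNA genes

Counts are converted to transcripts per million restricted to the long-RNA
fraction:

$$\mathrm{TPM}_i \;=\; \frac{RC_i / L_i}{\sum_{j \in \mathrm{LR}} RC_j / L_j}
\times 10^6,$$

where $RC_i$ is the read count, $L_i$ the gene length in bp, and LR the set
of protein-coding and lncRNA genes. The denominator choice matters: TPM is
abundance *relative to the retained gene set*, so the biotype restriction is
applied before normalization (`compute_tpm(..., biotypes =)`), and every
column of a TPM matrix sums to $10^6$ by construction (enforced at
`exlr_matrix()` construction with relative tolerance 1e-9). TPM is
compositional; absolute fold changes are identified only up to the
renormalization constant, which is why the simulator tests compare planted
effects against an internal median-ratio control.

## Sample QC

For each sample we compute the median of its correlation coefficients with
all other samples and drop samples below 0.9. The correlation scale is a
judgment call the upstream description leaves open; the default is Pearson
on $\log_2(\mathrm{TPM}+1)$, because on the raw TPM scale a handful of
very highly expressed genes dominate the covariance. Spearman and raw-scale
options are exposed (`sample_qc(method =, log =)`). QC runs on all samples
jointly, before any train/validation split, mirroring the order of the
study design.

## Moderated-t differential expression

Per gene, the contrast is the difference of group means of
$\log_2(\mathrm{TPM}+1)$ (so `log2fc` is a difference of log means, *not*
the log of the ratio of mean TPMs — the two disagree, and mean-TPM columns
are reported alongside for transparency). Gene-wise residual variances
$s_g^2$ (pooled, $d_g = n-2$) are shrunk toward a scaled inverse chi-square
prior with parameters $(d_0, s_0^2)$ estimated by matching the first two
moments of $\log s_g^2$, which under the model follows a log-F
distribution; the variance-matching equation is inverted through the
trigamma function (Newton iteration). When the observed log-variance
spread does not exceed its sampling component, the moment equation has no
positive root and $d_0 = \infty$ (complete shrinkage) is the correct
degenerate limit. The moderated statistic
$\tilde t_g = \Delta_g / (\tilde s_g \sqrt{1/n_1 + 1/n_2})$ is referred to
$t_{d_0 + d_g}$ and BH-adjusted. `d0_override` exposes the two analytic
limits ($0$: ordinary pooled t; $\infty$: fully shared variance), which the
tests use as oracles; on heterogeneous-variance simulations the estimates
agree with the independent limma implementation to machine precision.
Zero-variance genes are floored at machine epsilon with a warning.

## Candidate filtering

Signature candidates are upregulated long-RNA genes passing
`log2fc > 0.59`, BH-adjusted `p < 0.05` and expression frequency `> 0.5`.
Two small decisions are worth flagging:

* The published cut 0.59 is used verbatim rather than
  $\log_2 1.5 = 0.585$; both are just arguments to `select_candidates()`.
* "Expression frequency" is implemented as the detection fraction — the
  share of samples with TPM above a threshold whose default is 0 (any
  nonzero expression counts). The threshold is configurable because the
  notion is not standardized.

Candidates are ordered by descending log2 fold change with gene ID as a
deterministic tiebreak.

## mRMR-MIQ ranking

Expression is first discretized per gene into three states against
$\mu \pm \alpha\sigma$ ($\alpha = 1$, population $\sigma$) — the classic
mRMR preprocessing; a deterministic discrete coding was preferred over
continuous mutual-information estimators for reproducibility. Plug-in
mutual information (bits) then drives a greedy ranking: the first gene
maximizes relevance $I(f;c)$; each later step maximizes the
mutual-information quotient $I(f;c) / \bar I(f;S)$, relevance over mean
redundancy with the already-selected set, with the denominator floored at
1e-12 and ties broken by gene ID. The ranking is therefore invariant to
candidate input order, and the test suite checks it against an exhaustive
per-step brute-force oracle.

A caveat stated rather than hidden: the MIQ quotient can inflate scores of
near-irrelevant features (tiny relevance over tiny redundancy), and when
the top feature separates the classes perfectly, a duplicate of it ties
rather than loses. These are properties of the criterion itself, visible
in the oracle tests.

## Incremental feature selection with LOOCV-scored SVMs

Panels grow along the ranking: top-1, top-2, ... top-$K$ genes. Each panel
is scored by the AUC of leave-one-out cross-validated SVM decision values:
for each training sample, an SVM is fit on the remaining samples (features
z-scaled with fold statistics — constant features map to exactly zero) and
the held-out decision value recorded. The selected panel is the smallest
$k$ attaining the maximal AUC (parsimony on ties). Defaults: linear
kernel, $C = 1$, inverse-frequency class weights (the cohorts are
imbalanced roughly 1:2); an RBF kernel is available. The kernel choice is
ours — unspecified upstream — and linear is the reproducible default for
small-$n$, small-$p$ gene panels.

The final signature object freezes everything inference needs: feature
list, scaling statistics, the SVM fit, a logistic (Platt-style) score
calibration fitted on the *held-out* LOOCV scores, and a Youden-J decision
threshold chosen on those same held-out scores (ties resolved to the lower
threshold). Validation, independent-cohort and subgroup evaluation reuse
the frozen model verbatim; nothing refits. This is the only leakage-free
reading of training-then-applying a model, and a dedicated test asserts
that shuffling evaluation labels cannot change predictions.

## Evaluation

`evaluate_classifier()` reports sensitivity TP/(TP+FN), specificity
TN/(TN+FP), accuracy, rank-statistic AUC (ties get half credit), and a 95%
CI by DeLong's placement-value variance (default) or a seeded stratified
bootstrap. Subgroup evaluation (`evaluate_subgroups()`) takes filter
expressions over the design table (stage, CEA status, cohort), requires
case/control disjointness, skips empty subgroups with a warning, and pools
samples across splits by default. The CRA-vs-healthy signature is the same
pipeline invoked with `case = "CRA", control = "healthy"` — no separate
code path.

## ssGSEA scoring, ORA, and group comparisons

`ssgsea_score()` implements the single-sample enrichment walk: genes
ranked per sample (midranks for ties; gene ID breaks exact ties in the
walk order, making scores deterministic), in-set genes accumulate weight
$r^\alpha$ ($\alpha = 0.25$), and the score is the summed difference
between the weighted in-set ECDF and the uniform out-of-set ECDF. Scores
are rank-based, hence invariant to any strictly monotone within-sample
transform — TPM versus log-TPM input is irrelevant, which the tests
verify. Cell-type scoring uses exactly this machinery over user-supplied
gene sets: the spillover compensation and calibrated reference signatures
of the full xCell method are intentionally out of scope, so scores are
comparable across samples within a run, not across studies.

Pathway over-representation is the upper-tail hypergeometric test
(`phyper`) of a DE gene list against a universe, BH-adjusted. Cohort
comparisons per score set use Wilcoxon rank-sum for each pair (exact for
groups of at most 10, normal approximation with tie correction otherwise)
and one-way ANOVA across the three cohorts, plus a monotone-trend flag set
when the three group *medians* are strictly ordered. Medians make the flag
robust to outliers at the cost of a few percent of detection power
relative to means at small $n$; the choice is deliberate.

## Survival screening

Kaplan–Meier estimation and the two-group log-rank test are delegated to
the survival package (the standard tools), wrapped to return tidy tibbles
and checked in the tests against hand-computed product-limit and
$(O-E)^2/V$ tables. `screen_scores()` dichotomizes CRC samples — only CRC
samples; the prognostic question is CRC-specific — at the median of each
score set (ties to the low arm), runs the log-rank test, and reports a
direction: positive when the high-score arm survives longer by KM median,
falling back to the curve ordering at the last shared event time when
medians are undefined under heavy censoring. The test is named log-rank
explicitly because the upstream description names only the KM machinery;
log-rank is the standard companion and the assumption is flagged here.

# The synthetic cohort generator

`simulate_cohort()` draws, per study: gene annotations (~70%
protein-coding, 25% lncRNA, 5% pseudogene/other; lengths uniform on
200–10,000 bp), log-normal baseline abundances, per-sample library sizes
(1–2 million long-RNA reads), and negative-binomial counts with
$\mathrm{Var} = \mu + \phi\mu^2$, $\phi = 0.2$ — typical bulk-RNA
overdispersion. Expected counts are proportional to abundance times gene
length, so TPM downstream recovers abundance ratios. Planted
CRC-upregulated genes (default 20, log2 fold changes uniform on [1, 2])
receive half their log-effect in CRA, producing the monotone
healthy < CRA < CRC ordering the three-cohort analyses look for; the
half-effect is an assumption recorded in the truth manifest. Default
cohort sizes mirror a 72/42/80 CRC/CRA/healthy study and scale down for
tests.

Two generator parameters were calibrated to the *described behavior* of
real exLR data rather than to any printed number: the baseline log-normal
spread (sdlog 2.2, giving log-TPM profiles spanning several orders of
magnitude) and a small random dropout rate (0.5% of entries zeroed),
chosen so that typical simulated samples show median inter-sample
correlations of ~0.91–0.95 on the log scale — data in which the 0.9 QC
filter removes occasional poor samples instead of everything or nothing.
Higher dropout rates make log-scale correlations collapse and the QC
filter reject entire cohorts, which real studies of this design do not
show.

Survival endpoints for CRC samples are exponential with log-hazard linear
in a standardized latent score (default HR 2.0 per SD for OS, 1.5× that
hazard for DFS), with independent uniform censoring whose upper bound is
solved numerically so the expected censoring fraction hits the target
(default 30%). `make_gene_sets()` builds gene-set fixtures with a recorded
signal/background manifest for the enrichment and survival screens.

What the generator does *not* emulate — and therefore what passing tests
do not establish about real plasma data: batch and center effects,
library-preparation biases correlated with biology, expression-dependent
(rather than uniform) dropout, correlated gene modules beyond the planted
effects, and non-proportional hazards. Results on synthetic cohorts
validate the machinery, not clinical performance.

# Numerical and design choices collected

* Pseudocount: $\log_2(\mathrm{TPM}+1)$ everywhere downstream;
  configurable.
* Versioned gene IDs are matched on the full versioned string by default;
  `strip_versions = TRUE` matches stems for cross-annotation reuse.
* Zero-variance genes: variance floored at machine epsilon (DE), all-zero
  discretization (mRMR), zero contribution after scaling (SVM).
* Trigamma inversion: Newton iteration with asymptotic guards
  ($1/\sqrt y$ for large $y$, $1/y$ for small).
* Degenerate Platt fits (perfect separation) fall back to a steep finite
  sigmoid anchored at the score-gap midpoint.
* IFS ties: smallest panel; Youden ties: lowest threshold; mRMR and
  candidate-order ties: gene ID.
* The train/validation split is stratified by cohort (2:1 by default) and
  is a pure function of the seed and the sorted sample list.
* Every stochastic step funnels through a single seed; rerunning a
  pipeline config reproduces the model bit for bit.

# Problem sizes used in the shipped checks

The packaged tests and the acceptance script run on scaled cohorts —
typically 400–2,000 genes and 36/21/40 samples per cohort (half the
reference design), with 10 replicate seeds for recovery and null
calibration, 100 replicates for survival power, and 5 seeds of 5,000
genes for variance-prior recovery. These sizes were chosen as the
smallest at which the estimators' asymptotics visibly hold; the pipeline
itself has no size-dependent code paths.

# Known limitations

* The mRMR discretization and SVM kernel are reasoned defaults, not
  reconstructions of unpublished settings; different choices reorder
  borderline candidates.
* No between-sample normalization beyond TPM, no covariate adjustment, no
  nested cross-validation, no Cox modeling — all deliberately out of
  scope to match the target workflow.
* DeLong CIs clip at [0, 1] and degenerate when AUC = 1 exactly; the
  bootstrap option behaves better near the boundary.
* ssGSEA scores are comparable within a matrix; the range normalization
  is matrix-wide, so adding samples rescales scores.
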