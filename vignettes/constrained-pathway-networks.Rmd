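---
title: "Pathway-constrained multimodal classification: model, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-constrained multimodal classification: model, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadnet)
```

## The model

`triadnet` classifies participants as cognitively normal (CN), mildly
cognitively impaired (MCI) or Alzheimer's disease (AD) from three aligned
blocks: per-gene aggregated genotypes, gene expression, and clinical
features. Its core assumption is that the informative structure of the two
omics blocks is *known in advance*: genes act through curated pathways, and
pathways nest hierarchically. Rather than asking a dense network to
rediscover that structure from a few hundred samples, the gene-to-pathway
and pathway-to-pathway relations are frozen into binary masks and used as
fixed subnetwork weights. Under the default identity activation a
subnetwork is the cumulative masked product `x M1 M2 M3`, so every hidden
node is a named pathway whose activation is the (signed) sum of its
constrained inputs — which is what makes the intermediate-layer analysis
interpretable. A `tanh` option exists for users who want bounded
activations; identity is the default because it preserves the signed-sum
reading of a node and makes truncated forward passes exactly linear.

The trainable part is deliberately small: batch normalization over the
concatenation (snp top pathways ‖ expression top pathways ‖ clinical),
dense(19, linear), dropout, dense(8, ReLU), dense(3, softmax). With frozen
subnetworks, gradients exist only for the batch-norm scale/shift and the
three head layers; the optimizer never sees the masks, and the test suite
asserts the masks are bit-identical before and after training.

## Hyperparameters

All defaults in `triadem_config()` follow the published configuration of
this architecture and are not re-tuned here:

| parameter | default | meaning |
|---|---|---|
| `depth` | 3 | pathway levels per subnetwork |
| `hidden1_size` / `hidden2_size` | 19 / 8 | fusion head widths (linear, then ReLU) |
| `dropout_rate` | 0.597 | between the two head layers |
| `l2` | 0.01 | kernel regularization on both head hidden layers; the regularization type and strength were not printed, so L2 at 0.01 is this package's choice and is configurable |
| `learning_rate`, `decay_rate`, `decay_steps` | 0.008, 0.96, 17 | staircase schedule `0.008 * 0.96^floor(t/17)` over update steps |
| `batch_size` / `max_epochs` | 32 / 120 | training loop bounds |
| `patience` | 10 | early stopping on validation loss with best-weight restoration (the callback was described without a patience value; 10 is this package's default) |

Two numerical choices deserve a note. The decay is *staircase*
(integer-divided steps) because a drop "every 17 steps" describes discrete
events. And the batch-norm moving statistics are stored as exponential
moving averages that are **bias-corrected** by the number of updates at
inference time. Without that correction, short training runs (few update
steps relative to the 0.99 momentum) normalize inference inputs with
near-initialization statistics, validation loss rises while training loss
falls, and early stopping then restores a spurious "best" model. The
correction makes inference statistics track the running average of batch
statistics from the first step and changes nothing asymptotically.

## Preprocessing order and leakage control

The pipeline order is fixed: encode → drop sparse clinical features
(≥ 60% missing on *training* rows) → kNN-impute (k = 5, fitted on the
training table and reused for validation/test) → stratified 56/14/30 split
→ SMOTE on the concatenated training block → min-max scaling fitted on
training rows → one-hot targets. The 56/14/30 split is realised as a
stratified 70/30 carve-out followed by an 80/20 carve-out of the 70, which
reproduces both stated stages of the original split. SMOTE runs on the
single concatenated matrix so synthetic samples stay aligned across
modalities, after imputation (it needs complete data) and before scaling
(so training features end in [0, 1]).

kNN distances ignore features missing in either row and rescale by the
fraction observed (the standard partial-distance convention); continuous
features are standardised internally with training moments before the
distance, continuous imputations use the inverse-distance-weighted
neighbour mean, categorical ones the weighted mode. Additive genotype
aggregation is an unweighted sum of 0/1/2 codes per gene — the additive
genetic model — with a mean option; missing codes contribute 0, a
conservative no-signal default.

## Shapley attributions

The estimator is model-agnostic permutation sampling: each draw picks a
random feature permutation and a random background row, switches features
from background to target in permutation order, and credits each feature
with the change in class probability when it switches. Averaged over draws
this is an unbiased estimate of the Shapley value against the background
distribution; with `exact = TRUE` all coalitions are enumerated with their
combinatorial weights, which the tests compare against an independent
brute-force enumeration. The background defaults to 100 training rows and
attributions are computed on the test split; both are configurable, and the
split choice is genuinely open (the original analysis does not state which
samples its summaries use). Local-accuracy residuals (model output minus
base value minus attribution sum) are reported per sample; they shrink with
the per-feature budget as background-sampling noise averages out. Rankings
use mean absolute attribution with lexicographic tie-breaks. One ambiguity
is inherited and configurable rather than resolved: the source analysis
attributes one gene to expression in one section and to SNPs in another, so
modality is a tag supplied by the caller, not an intrinsic property.

## What the synthetic generator does and does not emulate

`synthetic_config()` defaults to the study conditions: 212/317/97 CN/MCI/AD
participants, 45 clinical columns, and (as a desk-scale stand-in for the
10,151-gene inputs) 300 genes per omic block. Genotype aggregates are sums
of binomial(2, MAF) variant draws with 1–8 variants per gene and MAF in
0.05–0.5; expression is Gaussian with per-gene means in 5–9 and SDs in
0.4–1.2 (log-microarray-like); the clinical schema mirrors the published
tables (neuropsychological scores, brain volumes, PET/CSF biomarkers,
demographics), with cognitive-score-like features monotone in disease stage
and 10% missingness on the columns that are missingness-prone in real
cohorts. Planted class effects shift 10 genes per modality by 2 pooled SDs
per class step; clinical gradients scale as half the configured effect per
step so a zero effect size yields a completely signal-free cohort (used for
the null calibrations). The hierarchy generator emits a three-tier DAG with
multi-parent pathways whose gene-to-top-node compression (~40:1) matches
the ratio implied by the published layer widths.

The generator does **not** emulate linkage disequilibrium, expression
covariance, array normalization artefacts, informative missingness, or
label noise. Passing tests therefore show that the pipeline recovers the
structure it assumes under clean conditions — not that it would perform
equivalently on real cohort data.

A known limitation follows directly from these conditions: planted effects
are perfectly collinear across genes (all shift with class by
construction), and the regularized head only needs a subset of the
redundant pathway directions to separate the classes. Interventional
Shapley values follow the *model's* dependence, so planted genes the model
ends up not using receive near-zero attribution and can rank below noise
genes that share a weighted pathway node. The test suite's end-to-end
recovery check quantifies this: a substantial fraction of planted features
is recovered in the per-modality top-20, but not all of them. On real data,
where associated genes carry partially independent signal, attribution
dilution of this specific kind is expected to be milder.

## Metrics and statistics

Per-class contingency counts use the one-vs-rest convention; precision is
TP/(TP+FP). (The source prints a precision formula with TN in the
numerator, which is not precision; the standard definition is used and the
discrepancy noted here.) AUC is one-vs-rest from softmax scores, macro
averages run over classes present in the data, and per-class values are
always reported alongside. The published trainable-parameter count cannot
be reconciled from the printed widths alone, so parameter counting is
verified against a layer-walk enumeration rather than a printed constant;
counts are reported per subnetwork and combined. Cohort summary tables
reproduce the published analysis style: chi-square without continuity
correction (required to match the printed sex-proportion p-value from
counts), one-way ANOVA reconstructable from printed means/SDs/sizes
(exactly equivalent to raw-data ANOVA, which a constructive test checks),
Kruskal–Wallis elsewhere, p-values formatted to three significant figures
with a `<0.001` floor. Kruskal–Wallis on activation nodes reports raw
per-node p-values by default, matching how the pathway-activation analysis
is usually presented; a Benjamini–Hochberg flag exists for users who probe
many nodes. Degenerate cases are explicit: constant nodes get H = 0, p = 1
and a flag; single-point classes in the kernel-density summary produce a
flagged unit-mass spike; KS preservation uses the asymptotic two-sample
test with ties tolerated.

## Perturbation-based validation

`perturb_features()` implements the simulated-robustness procedure:
selected features are multiplied by `1 − u` with `u` uniform in a
feature-specific range, for exactly `round(fraction × pool)` subjects drawn
without replacement from the control class by default. The uniform factor
is redrawn *per subject* (the stronger-noise reading of a per-feature
alternative). `simulated_validation_run()` trains on the original and the
perturbed cohort with identical seeds and splits and reports metric deltas
plus Kolmogorov–Smirnov preservation flags. The direction property checked
in the tests perturbs planted omics features in the control pool — those
rise with disease stage, so reducing them in controls widens class
separation, the "amplified association" direction under which performance
should not degrade.

## Problem sizes

The test suite and acceptance script run the default-scale generator
(626 participants, 300 genes per omic) for the planted-signal and
perturbation checks, 600-participant signal-free cohorts across five seeds
for the null calibration, and 90 × 200 null matrices for the Kruskal–Wallis
rate; Shapley recovery uses the full test split with a per-feature budget
of 32 against 100 background rows. These sizes keep every check
well-powered while the whole suite completes in a few minutes on one CPU;
the full-scale 10,151-gene setting is exercised only for width accounting.
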