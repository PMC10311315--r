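---
title: "Group-wise self-attention on omics profiles: model, choices and limitations"
author: "attomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-wise self-attention on omics profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attomics)
```

## The model

An omics profile is a vector $X \in \mathbb{R}^p$ with $p$ in the tens of
thousands. attomics implements the AttOmics architecture: the profile is cut
into $k$ feature groups, each group is compressed by its own fully connected
network into a shared $s$-dimensional embedding, multi-head self-attention
mixes the $k$ embeddings, and a prediction head maps the flattened result to
class probabilities or a Cox log-risk.

**Grouped FCN.** Every layer is $\mathrm{FCL}(x) = \max(0, Wx + b)$. A group
of size $p_i$ is reduced to $s$ dimensions over
$d_i = \max(1, \lceil \log_r (p_i/s) \rceil)$ layers with geometrically
interpolated widths, where $r$ is the reduction ratio (default 2). This
equalizes the per-layer compression across groups of different sizes, which
matters for gene-set groupings whose sizes vary by orders of magnitude.
Because each group has its own weights, the gradient of one group's
embedding with respect to another group's features is exactly zero — the
test suite checks this by finite differences.

**Self-attention.** With $h$ heads and $l = s/h$ (enforced at construction),
head $j$ projects each embedding to queries, keys and values in
$\mathbb{R}^l$ and forms row-stochastic attention weights by a softmax over
scaled dot products. The default score scaling divides by $s$; the
conventional $\sqrt{l}$ scaling is available as
`attentionScale = "sqrt_l"`. Both are supported because the two conventions
genuinely differ and the choice changes the softmax temperature; the
package default is the former, and nothing else in the architecture depends
on it. Attention weights are kept per sample, per block and per head for
interpretation.

**Residual and normalization.** Each encoder block computes
$Z_{g_i} = \mathrm{Norm}(X'_{g_i} + U_{g_i})$; the residual can be disabled,
and `norm` selects layer normalization (default, per group vector,
population variance, $\varepsilon = 10^{-5}$) or batch normalization (per
group-channel over the batch, with running statistics used in evaluation
mode). Layer normalization is the default because it is batch-size
independent and empirically the more stable choice for this architecture.
For blocks after the first, the per-group FCN is a single $s \to s$ FCL:
deeper in the encoder all groups already live in the same space, so there is
no size imbalance left to equalize.

**Prediction head.** Hidden FCLs (each followed by the configured
normalization) end in a linear layer: $M$ neurons and a numerically stable
softmax for classification, one linear neuron for survival whose output
$\hat{Y}$ is the log-risk, $\eta = e^{\hat{Y}}$. The output layer itself is
never normalized, since normalizing logits would constrain their scale and,
for the survival head, destroy the meaning of the risk score.

## Losses and training

Classification minimizes a weighted cross-entropy with
$w_c = n / (M\,n_c)$: inversely proportional to class size and normalized
so balanced data gives unit weights. Predicted probabilities are clamped at
$10^{-12}$ inside the loss so that a confident wrong prediction produces a
large finite loss rather than NaN.

Survival minimizes the negated mean Cox partial log-likelihood over each
minibatch's risk sets, computed with log-sum-exp stabilization. The risk set
is $R(T_i) = \{j : T_j \ge T_i\}$ — the Breslow convention used by DeepSurv,
under which a patient belongs to its own risk set and each term is
non-positive. The strict variant $\{j : T_j > T_i\}$ is available as
`riskSet = "printed"` for comparison; under it an event with an empty risk
set contributes an infinite term, which is the main reason it is not the
default. The loss is shift-invariant in the scores (tested to $10^{-6}$),
so only risk differences are identified. Minibatches that contain no event
carry no information for the partial likelihood and are skipped.

Training uses Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$,
$\varepsilon = 10^{-8}$). Defaults follow the published protocol: learning
rate $10^{-4}$, batch size 512, at most 100 epochs, early stopping with
patience 8 and minimum improvement delta 0.001 on the validation metric —
validation error for classification, validation concordance index for
survival (`monitor` can select the validation loss instead). An improvement
must exceed the delta *strictly* to reset the patience counter. The
best-validation weights are restored at the end. All randomness (weight
initialization, shuffling, splitting, grouping, generators) flows through
per-component seeds derived deterministically from one global seed, so any
run is bit-reproducible.

Weight initialization is uniform Kaiming-style fan-in
($W \sim U(\pm\sqrt{6/\text{fan-in}})$), a standard choice for ReLU stacks;
the architecture description itself does not prescribe one.

## Data handling

Tables are read samples-in-rows with feature IDs in the header; label, time
and event columns are routed to annotations by name. Standardization
statistics (mean and population standard deviation per feature) are fitted
on the **training split only** and applied to all splits; the description of
the original protocol states only that data were standardized, but its
treatment of other train-derived structures follows the leakage-free
convention, so standardizing before splitting would be the only
inconsistent reading. Features constant on the training rows have no usable
scale and are dropped (with a warning) rather than zero-filled. Survival
records with missing time, non-positive time, or missing event flag are
removed, which operationalizes "incorrect survival information".

The stratified split allocates each class over train/validation/test by
largest-remainder rounding (ties resolved in split order), so each class's
train share is within one sample of its target; member assignment is a
seeded shuffle. Classes with fewer members than splits go to training with
a warning.

## Grouping strategies

*Random*: a seeded permutation cut into groups whose sizes differ by at most
one.

*Constrained K-means*: features are clustered by their standardized
training-split expression vectors (Euclidean distance, k-means++
initialization, several seeded restarts keeping the lowest objective). The
assignment step is solved exactly as a linear sum assignment problem in
which every cluster owns `minSize` mandatory slots plus capacity-bounded
optional slots; dummy objects absorb the surplus. Because the assignment is
optimal given the centroids and the centroid update is a mean, the
within-cluster sum of squares is non-increasing across iterations. The
default `minSize` is $\lfloor 0.5\,p/k \rfloor$ — half of the equal-share
size — which keeps groups comparable without forcing exact equality; the
original description fixes no value. Iteration stops when the assignment is
stable, the largest centroid shift falls below `tol`, or `maxIter` is
reached. The exact assignment is $O(N^3)$ in the expanded slot count, which
is practical up to a few thousand features; for larger profiles the random
strategy is the intended default.

*Gene sets*: one group per GMT set, restricted to the features present.
Groups may overlap (shared features are copied into every containing group,
with no weight sharing) and features in no set are dropped — an implicit
feature selection that is reported as coverage. Sets below `minGroupSize`
are dropped with a warning; an optional `rest` group collects uncovered
features. Ontology structure is deliberately not interpreted: any GMT file
works.

## Metrics

The concordance index is computed exactly as the pairwise ratio
$\sum_{i,j} 1[T_j < T_i]\,1[\eta_j > \eta_i]\,\delta_j \big/
 \sum_{i,j} 1[T_j < T_i]\,\delta_j$: a pair is comparable when the earlier
patient experienced the event, and tied risks receive no credit. This
follows the printed formula literally; `ties = "half"` switches to the
half-credit convention of much C-index software (and is what matches
`survival::concordance`). Macro (unweighted) F1 is reported alongside the
error rate; a class absent from both predictions and truth contributes an
F1 of zero with a warning, a conservative choice.

## Attention maps

For interpretation, the per-sample attention matrices of one encoder block
are averaged over all samples with the same phenotype. The mean of
row-stochastic matrices is row-stochastic, so maps remain probability
distributions per row, with element $(i, m)$ read as "group $i$ attends to
group $m$". The default reads the **last** encoder block with heads
averaged — the deepest representation is the one feeding the predictor —
but both block and head are selectable and are recorded in the exported
output. Rankings of the largest off-diagonal cells use a stable index-based
tie-break.

## Synthetic data

The generators produce what the architecture assumes its inputs look like:
standardized continuous features with block-correlation structure (one
shared Gaussian latent factor per block, within-block correlation exactly
the requested $\rho$), class signal as a mean shift of `effectSize` feature
standard deviations concentrated in one designated block per class
(balanced classes, within one sample), and survival times that are
exponential with rate proportional to $e^{r}$ where the log-risk $r$ is
linear in the planted block means — proportional hazards by construction —
with independent uniform censoring whose upper bound is calibrated by
bisection to the requested censoring fraction. Ground truth (block
membership, informative blocks, per-sample log-risk) is returned and
serialized alongside the data so tests never re-derive it.

What the generators do **not** emulate: count-like or beta-value marginal
distributions, batch effects, heavy tails, feature-feature correlation
across blocks, or informative censoring. Tests passing on this synthetic
family therefore demonstrate that the implementation is correct and that
the architecture can recover planted signal; they say nothing about
performance on real tumor profiles.

## Problem sizes used in the checks

The end-to-end checks run at desk scale, chosen so the full suite completes
in minutes on one CPU: classification learnability uses $n = 2000$,
$p = 1000$, 20 planted blocks, 4 classes with a 3-sd shift (and an
effect-size-0 control that must stay at chance); survival recovery uses
$n = 2000$, $p = 500$, 5 blocks with per-block coefficient 5 and 20%
censoring (planted risk concordance $\ge 0.9$); constrained K-means
recovery uses $p = 400$, $k = 4$, within-block correlation 0.9. Model sizes
in these checks ($s$ = 8–16, $h$ = 2, one block) are correspondingly small;
the implementation itself has no architectural limits beyond memory.

## Known limitations

* The exact constrained assignment makes clustering-based grouping cubic in
  the expanded slot count; very large $p$ should use random or gene-set
  grouping, or a larger `minSize`/smaller `k`.
* Pure-R training is practical into the low millions of parameters and
  thousands of samples; it is not a GPU replacement.
* Attention weights are an interpretation aid, not a causal attribution
  method; maps should be compared across phenotypes rather than read in
  isolation.
* Batch normalization uses minibatch statistics during training; with very
  small batches the layer-norm default is strongly preferred.
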