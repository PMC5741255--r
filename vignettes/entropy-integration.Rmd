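---
title: "Entropy-based integration of weighted gene association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based integration of weighted gene association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Genome-scale weighted gene association networks (WGANs) — protein
interaction compendia, functional association networks built by Bayesian or
log-likelihood scoring, and similar resources — assign each gene pair a
confidence score that the two genes are functionally coupled. Different
resources share most of their genes but remarkably few of their edges, and
they disagree about the weights of the edges they do share. `entnet`
implements a data-source-agnostic way of merging m such networks into one:
the integrated network keeps the union of all nodes and edges, and rescores
every edge from the m component weights using only the *inherent
uncertainty* of each component's score, with no reference to the biology
behind any source.

## The model

Every weight $W_k^{(ij)} \in (0,1]$ of source $k$ is read as the probability
that the edge $(i,j)$ exists according to that source. The uncertainty of
that Bernoulli variable is its binary entropy (in bits)

$$H(W) = -W \log_2 W - (1-W)\log_2(1-W),$$

maximal (1 bit) at $W = 0.5$ and vanishing as $W \to 0$ or $W \to 1$. A
source is taken to be trustworthy about an edge when it is *certain* about
it, in either direction, so entropy is converted into a confidence

$$C(W) = 1 - e^{-H(W)^{-\theta}}, \qquad \theta > 0,$$

which is strictly decreasing in $H$ and confined to $(0,1)$. The mixing
coefficients of edge $(i,j)$ are the normalized confidences
$\alpha_k = C_k / \sum_s C_s$ (positive, summing to 1), and the integrated
weight is the convex combination

$$W^{(ij)} = \sum_{k=1}^m \alpha_k\, W_k^{(ij)},$$

which therefore always lies between the smallest and largest component
weight.

Edges absent from a source (including edges with an endpoint the source does
not contain at all — the two cases are not distinguishable from the source's
point of view) are imputed at a small weight $\varepsilon$, and weights of
exactly 1 are clipped to $1-\varepsilon$, so entropy is defined everywhere.
Note the deliberate consequence: an imputed $\varepsilon$ entry has *low*
entropy, hence *high* confidence — a source that lacks an edge confidently
pulls the integrated weight down. Integration is not a vote count; a
single-source edge is strongly shrunk toward $\varepsilon$ when the other
sources are many.

## Parameters

* `epsilon` (default **0.001**, dimensionless): the imputation weight.
  It only needs to be far below any genuine normalized edge weight; clipping
  is generalized so that any stored value lands in
  $[\varepsilon, 1-\varepsilon]$.
* `theta` (default **0.3**, dimensionless exponent): controls how sharply
  entropy penalizes a source. For $\theta > 1$ the confidence saturates near
  1 for small $H$ and stops discriminating; the range $[0.2, 0.6]$ is where
  $C$ responds appreciably to $H$, so tuning is confined there.
* `thetaGrid` (default 0.2–0.6, step **0.01**): the tuning grid. The
  objective is cheap and possibly non-convex, so `tuneTheta()` does an
  exhaustive sweep; 0.01 resolves the default optimum 0.3 from its
  neighbors. Ties break toward the smaller $\theta$ for determinism.

$\theta$ is tuned by minimizing
$f(\theta) = \sum (W_\theta - W_\mathrm{ref})^2$ over the edges the
integrated network shares with an independent reference network (in
practice a functional-annotation network whose weights are normalized
shared-term counts). Reference edges absent from the union do not
contribute: the sum runs over common edges only.

## Weight normalization and I/O conventions

Source weights are normalized by dividing by the network maximum — the
simplest rule that preserves weight ratios and lands every positive weight
in $(0,1]$. On reading an edge list, self-loops are dropped (the model is
defined on pairs of distinct genes), and duplicate records of the same pair
in either orientation are collapsed to the **maximum** weight, the
conservative choice toward association evidence; both events are reported.
Networks are undirected throughout: edges are stored with the
lexicographically smaller gene first, and edge iteration follows that sorted
order, so all outputs are byte-reproducible. Written weights carry 6 decimal
places, three orders finer than $\varepsilon$.

## Disease-gene prioritization and its evaluation

A candidate gene is scored by the summed weights of its direct links to the
seed genes ($S_i = \sum_{j \in \mathrm{seed}} W_{ij}$; genes with no seed
links score exactly 0). Candidates are all network genes outside the current
seed set. Tied scores — above all the large plateau of zero-scoring genes —
all receive the **worst** rank of their tie group, so a gene that cannot be
distinguished from a thousand others is not flattered by an optimistic rank.

Leave-one-out cross-validation holds out each member of each disease set in
turn (sets need at least 3 genes present in the network; smaller ones are
skipped with a warning) and records the held-out gene's rank and the
candidate-pool size. Records are pooled across diseases through *normalized*
ranks $r/n$, which makes pools of different sizes commensurable; for a fixed
background network, where pool sizes are all but identical, this coincides
with pooling raw ranks. The pooled ROC curve places vertices just before and
at every positive's normalized rank, so trapezoidal integration is exact:
for a single record the area reduces to the Mann–Whitney statistic
$(n-r)/(n-1)$, uniformly random ranking gives 0.5 in expectation, and
perfect ranking approaches 1 as the pool grows. The top-$k$ curve reports
the percentage of pooled test cases at or under each rank cutoff in the
window $[0, 100]$.

## What the synthetic generator emulates — and what it does not

`generateComponentNetworks()` draws one latent network (edge probability
`edgeDensity`, weights uniform in $(0,1]$) and m observed sources, each an
incomplete, noisy view of it: every latent edge is dropped independently
with probability `missingness`, and surviving weights get additive Gaussian
noise, re-clipped to $(0,1]$ with floor 0.001. The defaults — 50 genes,
4 sources, density 0.1, missingness 0.5, noise sd 0.15 — describe a small
compendium in which any two sources share only a modest fraction of their
edges and agree only moderately about shared weights (shared-edge
correlation around 0.8 at noise 0.15, versus near-perfect agreement at 0.05
— real association databases correlate far more weakly still, so the noise
errs on the charitable side). One master seed fans out to per-source child
seeds, so adding a fifth source never perturbs the first four.

The generator does **not** emulate scale-free degree distributions, the
heavy-tailed weight distributions of real scoring schemes, or correlated
errors between sources (real databases share upstream evidence; here noise
is independent across sources). Passing tests on these fixtures therefore
demonstrates the algebraic and statistical correctness of the machinery and
the qualitative benefit of integration under the model's own assumptions —
not performance on any particular real compendium.

`generateReferenceNetwork()` mimics a shared-annotation-term reference:
a random 60% of latent edges get integer term counts
$3 + \mathrm{Binomial}(\texttt{maxTerms}-3,\ w_\mathrm{latent})$ — counts
below 3 never occur, matching the usual inclusion rule for such references —
normalized by the maximum count. `plantDiseaseModules()` raises
within-module edge weights by a fixed boost (creating missing within-module
edges at the boost weight), emulating the clustering of disease genes that
guilt-by-association scoring relies on.

## Numerical choices and degenerate inputs

* Arithmetic in double precision; base-2 logarithms throughout (entropies in
  bits). $\alpha$ normalization is checked to $10^{-12}$.
* `confidenceWeight()` returns values mathematically inside $(0,1)$; for
  entropies at or above the $\varepsilon$-clip floor ($H \geq 0.0114$ bits)
  the computed value is also strictly below 1 in floating point.
* Integrated outputs are left unclipped — convexity already keeps them
  strictly inside $(0,1)$.
* Degenerate cases: a single-point tuning grid returns that point with a
  warning; an empty network normalizes to itself; correlation on fewer than
  2 shared edges, zero-variance vectors, seed sets with no gene in the
  network, and seed/test overlap are all rejected with specific errors.

## Problem sizes used in the shipped checks

The test-suite and acceptance computations run at desk scale, chosen so the
whole suite completes in well under a minute while estimates remain stable:
oracle-equivalence on 100 random networks of up to 10 nodes; the random-
ranking null at 2000 background genes × 100 test genes × 200 replicates;
θ-recovery on 20 replicates of 10-node, 3-source fixtures; the integration-
benefit comparison on 50 replicates of the default 50-gene spec.

## Known limitations

* The confidence transform treats an imputed absence exactly like a
  confidently observed near-zero weight; sources with very different
  coverage therefore systematically shrink single-source edges. That is the
  model's intended behavior, but it means the integrated weight of an edge
  observed in one of many sources is not an estimate of that source's score.
* Pooled ROC treats other test genes as negatives in the prediction
  protocol, slightly deflating AUC when many test genes rank highly.
* Normalization by the maximum is sensitive to a single outlier weight in a
  source; robust alternatives (quantile scaling) are out of scope.
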