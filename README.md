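# entnet

Entropy-based integration of weighted gene association networks (WGANs).

Genome-scale gene association resources assign each gene pair a confidence
score, but different resources share most of their *genes* and very few of
their *edges*, and disagree about the weights of the edges they share.
`entnet` merges m such networks into one: the integrated network keeps the
union of all nodes and edges, and rescores every edge from its m component
weights using only the inherent uncertainty of each score — no knowledge of
the biology behind any source is needed.

## The model

Each weight W<sub>k</sub> ∈ (0,1] of source k is read as the probability
that the edge exists. Its uncertainty is the binary entropy

> H(W) = −W log₂W − (1−W) log₂(1−W)   (bits)

and the source's confidence about that edge is

> C(W) = 1 − exp(−H(W)<sup>−θ</sup>),  θ > 0,

strictly decreasing in H and confined to (0, 1). The integrated weight is
the convex combination W = Σ<sub>k</sub> α<sub>k</sub> W<sub>k</sub> with
mixing coefficients α<sub>k</sub> = C<sub>k</sub> / Σ<sub>s</sub> C<sub>s</sub>
(positive, summing to 1). Edges absent from a source are imputed at
ε = 0.001 (weights of exactly 1 are clipped to 1 − ε) so entropy is defined
everywhere; an imputed absence has low entropy, hence high confidence, so a
source that lacks an edge confidently pulls the integrated weight down.
The exponent θ (default 0.3) is tuned on a grid over [0.2, 0.6] by
minimizing Σ (W<sub>θ</sub> − W<sub>ref</sub>)² over edges shared with an
independent reference network.

Downstream, the package evaluates any background network by
guilt-by-association disease-gene prioritization: candidates are scored by
the summed weights of their direct links to seed genes
(S<sub>i</sub> = Σ<sub>j∈seed</sub> W<sub>ij</sub>), evaluated by
leave-one-out cross-validation and pooled ROC/AUC and top-k curves.
Deterministic synthetic generators supply latent-truth fixtures, GO-like
reference networks and planted disease modules, so the whole pipeline runs
and tests without any download.

## Worked example

```r
library(entnet)

spec <- fixtureSpec(nGenes = 50, mNetworks = 4, seed = 11)  # defaults: density 0.1,
comp <- generateComponentNetworks(spec)                     # missingness 0.5, noise 0.15
inet <- integrateNetworks(comp$observed)
inet
#> WeightedNetwork with 50 nodes and 104 edges
#>   weight range: [0.00701944, 0.865984]

ref <- generateReferenceNetwork(comp$latent, seed = 11)
tuneTheta(comp$observed, ref)
#> ThetaFit over [0.2, 0.6] (41 points, 76 shared edges)
#>   best theta = 0.2 (objective = 17.3595)

res <- weightCorrelation(inet, ref)
sprintf("r = %.4f, p = %.3g on %d shared edges", res$r, res$p, res$n)
#> "r = 0.4899, p = 7.05e-06 on 76 shared edges"

planted <- plantDiseaseModules(comp$latent, nDiseases = 4, genesPer = 6,
                               boost = 0.8, seed = 11)
pooled <- leaveOneOut(planted$network, planted$collection)
rocCurve(pooled)
#> RocCurve: 3 points, AUC = 1.0000

c(integrated  = meanAbsoluteWeightError(inet, comp$latent),
  worstSource = max(sapply(comp$observed, meanAbsoluteWeightError,
                           truth = comp$latent)))
#>  integrated worstSource
#>      0.3255      0.3525
```

The 104 integrated edges are exactly the union of the four sources' edges.
The reference network correlates positively and significantly with the
integrated weights (it was built to track the latent truth). The planted
disease modules are recovered perfectly by leave-one-out validation
(AUC = 1: every held-out module gene ranks first among 45 candidates), and
the integrated network recovers the latent weights better than the worst of
its four sources.

A thin command-line wrapper over the same functions is installed as
`exec/entnet`, with subcommands `integrate`, `tune-theta`, `compare`,
`corr`, `loocv`, `predict` and `simulate`.

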