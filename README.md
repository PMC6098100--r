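# NetNetML

Entropy-based screening of neural-network topologies for ecological link
prediction ("Net-Net AutoML").

## The problem

Biological ecosystem networks (BENs) — food webs, plant–pollinator webs,
host–parasite webs — are graphs of species linked by trophic or mutualistic
interactions. Confirming every possible interaction experimentally is
infeasible, so unobserved links `A_ij` are predicted with machine-learning
classifiers, typically artificial neural networks (ANNs) fed with
topological descriptors of the web. But which ANN topology to train is
itself an expensive trial-and-error search.

The Net-Net idea removes that search: both the ecological web *and* each
candidate ANN topology are networks, so both can be described by the same
family of descriptors, and a *meta*-classifier can learn to predict —
before any ANN is trained — whether a given topology will classify a given
species pair correctly.

## The descriptors and the model

For any graph with adjacency **A**, the Markov matrix **Π** has entries
`p_ij = w_ij / Σ_m w_im`. With a uniform initial vector `⁰p`, the k-step
walk occupancy is

    ᵏP = ⁰P · Πᵏ        (k = 0..5)

and the Markov–Shannon entropy centrality of node j at order k is its
contribution to the walk-distribution entropy,

    Sh_kj = − ᵏp_j · log₂ ᵏp_j,   Sh_k(G) = Σ_j Sh_kj ≤ log₂ n.

A species pair (i, j) is described by 18 features — `Sh_ki`, `Sh_kj` and
the differences `ΔSh_kij = Sh_ki − Sh_kj` for k = 0..5 (the **bsi** table,
label `A_ij`). An ANN topology is described by the mean of `Sh_k` over all
its neurons, `ᴬᴺᴺSh_k` (layered graph, complete bipartite between
consecutive layers, no bias nodes). Scoring every bsi pair with every
trained base ANN gives the **mt** table: 24 features and the meta-label
`P(ᴬᴺᴺA_ij) = 1` iff that topology classified the pair correctly. The
baseline meta-classifier is a two-group linear discriminant

    S = Σ_k a_k·Sh_ki + Σ_k b_k·Sh_kj + Σ_k c_k·ΔSh_kij + Σ_k d_k·ᴬᴺᴺSh_k + e₀

with classification 1 iff S ≥ 0; a menu of nonlinear meta-classifiers
(naive Bayes, trees, random forest, bagging, boosting, MLPs, a deep
fully-connected net) is provided through a common fit/predict contract.
The five-feature published discriminant is available frozen as
`referenceNetNetModel()`, and the ten published base topologies (with
their published descriptor values as fixtures) as `annRegistry()`.

## Worked example

```r
library(NetNetML)

webs <- lapply(1:4, function(w)
  generateBipartiteBen(10, 12, 0.3, heterogeneity = 0.5, seed = 100 + w))
names(webs) <- paste0("web", 1:4)

bsi  <- buildBsi(webs, nPos = 20, nNeg = 20, seed = 1)   # 160 pairs x 18
pool <- trainBasePool(bsi, annRegistry(), seed = 1, epochs = 15)
mt   <- buildMt(bsi, pool)                               # 1600 meta-records
sp   <- splitDataset(mt, 0.75, seed = 1)
model <- fitLda(sp$train)
evaluateModel(model, sp$train, sp$test)
```

```
Net-Net evaluation report
  positive class: topology classified the pair correctly (meta-label 1)
  training series: Sp = 74.8  Sn = 61.9  Ac = 65.5  AUROC = 0.753
    tn = 249  fp = 84  fn = 330  tp = 537
  test series: Sp = 70.3  Sn = 63.0  Ac = 65.0  AUROC = 0.736
    tn = 78  fp = 33  fn = 107  tp = 182
```

So on held-out meta-records the linear screen tells apart
"this topology will get this pair right" from "it will not" with 65%
accuracy and AUROC 0.74 — well above the chance it is tested against —
using nothing but entropy descriptors of the web and of the untrained
topology. `fitLda` warns that the within-class covariance is singular
(the ΔSh columns are exact differences of the Sh columns) and ridges it;
that is expected on any full mt table.

A shell driver mirroring the pipeline stages is installed at
`inst/scripts/netnet`:

```sh
Rscript inst/scripts/netnet synth --rows 10 --cols 12 --connectance 0.3 \
    --seed 1 --out web.net
Rscript inst/scripts/netnet descriptors --in web.net --out sh.csv
```

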