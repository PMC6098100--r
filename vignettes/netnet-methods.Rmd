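---
title: "Methods: Markov-Shannon entropy screening of ANN topologies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Markov-Shannon entropy screening of ANN topologies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NetNetML)
```

## The model

Link prediction in ecological webs is usually framed per species pair:
given topological descriptors of nodes $i$ and $j$, predict the adjacency
entry $A_{ij} \in \{0, 1\}$. This package implements the meta-level version
of that task. Because a feed-forward neural network is itself a graph, the
same node descriptors that characterize species can characterize neurons,
and a meta-classifier can be trained to predict whether a *candidate ANN
topology* will classify a *given species pair* correctly — before the ANN
is ever trained. The payoff is algorithm screening: topologies unlikely to
work are discarded without spending compute on them.

Three ingredients:

1. **Markov–Shannon entropy centralities.** For a graph with adjacency
   $A$, the Markov matrix $\Pi$ has entries $p_{ij} = w_{ij} / \sum_m
   w_{im}$. With initial vector $^0p$ the $k$-step occupancy is
   $^kP = {^0P}\,\Pi^k$, and node $j$'s entropy centrality of order $k$ is
   its contribution $Sh_{kj} = -\,{^kp_j}\log_2 {^kp_j}$ to the entropy of
   that distribution, so that $Sh_k(G) = \sum_j Sh_{kj} \le \log_2 n$
   decomposes exactly over nodes. $Sh_0$ reflects only the initial
   distribution; $Sh_1$ the direct neighbourhood; higher $k$ reaches
   progressively further.
2. **The bsi and mt tables.** A species pair contributes 18 features
   ($Sh_{ki}$, $Sh_{kj}$, $\Delta Sh_{kij} = Sh_{ki} - Sh_{kj}$, $k =
   0..5$) and the label $A_{ij}$ (bsi). Each of a pool of base ANN
   classifiers — trained on the bsi features — is summarized by the mean
   node entropy of its neuron graph, $^{ANN}Sh_k$. Crossing every pair
   with every pool member yields the mt table: 24 features and the
   meta-label $P(^{ANN}A_{ij}) = 1$ iff that classifier's thresholded
   prediction equals the observed $A_{ij}$. By construction the mt row
   count is always `nrow(bsi) * length(pool)`.
3. **The meta-classifier.** The baseline is a two-group linear
   discriminant over the 24 features with the decision boundary at score
   zero; `classifierMenu()` supplies nonlinear alternatives (naive Bayes,
   trees, random forest, bagging, gradient boosting, one/two-hidden-layer
   perceptrons, and a deep fully-connected net with hidden shape
   $n$–$2n$–$n$) behind one fit/predict contract.

## Conventions the entropy engine fixes

The walk-entropy framework leaves several small choices open; this package
fixes them as follows and exposes the alternatives where they are useful.

* **Initial vector $^0p$: uniform $1/n$.** The minimal-assumption choice.
  It matters: published descriptor values for the ten reference topologies
  (computed with the original MI-NODES software) follow a different,
  undocumented initial-probability convention and are **not** reproduced
  by any uniform-initial, base-2 or base-e evaluation of the formulas
  above. We therefore ship those published values verbatim as fixtures
  (`printedDescriptors` in `annRegistry()`, backed by
  `inst/extdata/ann_registry.csv`) and never recompute them; the package's
  own convention fills the `descriptors` slot, and `buildMt()` can use
  either via `useDescriptors`. The frozen published discriminant
  (`referenceNetNetModel()`) belongs to the published convention and is
  kept as a scorer, not refitted.
* **Log base: 2 (bits).** Entropies are conventionally reported in bits;
  all downstream features are base-consistent, so the base only rescales
  features and a natural-log option is provided.
* **Isolated nodes: absorbing self-loop row** ($p_{ii} = 1$) so $\Pi$
  stays row-stochastic without dropping nodes — web node counts must be
  stable. A single isolated node has $Sh_0 = 0$ (certainty).
* **Node entropy reading.** $Sh_{kj}$ is the node's *contribution* to the
  graph entropy (default), which makes the sum decomposition exact. The
  alternative reading — the entropy of row $j$ of $\Pi^k$, i.e. the
  uncertainty of a walker leaving $j$ — is available as
  `nodeEntropies(method = "row")` but is not used by the pipeline.
* **k range 0..5**, fixed; six orders per node.
* **ANN graphs**: undirected, unweighted, complete bipartite between
  consecutive layers, no bias neurons, no skip connections. Feed-forward
  direction is ignored because the entropy machinery is walk-based on a
  symmetric adjacency. Published layer annotations of the form
  `in:l1-...-lm:out` are validated against their own prefix/suffix; the
  hidden-layer notation (`n-n*2-n` etc.) is evaluated with integer
  arithmetic, `n:2` meaning `floor(n/2)`.

## Dataset construction choices

* **Negative sampling 1:1** with positives by default: the near-balanced
  class totals of the reference confusion tables imply roughly balanced
  classes, and balance keeps accuracy interpretable.
* **Pair orientation.** In bipartite webs $i$ is always drawn from the
  first guild (rows) and $j$ from the second, fixing the sign of
  $\Delta Sh$; in unipartite webs $i$ is the lower node index, so mirrored
  duplicates cannot occur.
* **Meta-label threshold 0.5** on base-classifier scores; "correctly
  predicts" is read as thresholded score equal to the observed label.
* **Base pool training**: each topology trains on the full bsi table by
  default (a `trainFraction` argument exposes held-out training). LNN
  topologies map to logistic regression, one-hidden-layer topologies to
  `nnet`, deeper ones to the in-package MLP (below).
* **Split 75/25**, stratified on label within network, floor-allocated
  per stratum and topped up by largest fractional remainder so the global
  train share is exact to one row.

## Numerical choices

* **Linear discriminant.** Fitted from class means and the pooled
  within-class covariance with equal priors; boundary at $S = 0$. The
  $\Delta Sh$ columns are exact differences of other columns, so the
  pooled covariance of a genuine mt table is singular: the fit then adds
  an escalating ridge ($10^{-8}$ of the mean diagonal, growing tenfold
  until solvable) and warns. The reported $\chi^2$ is Bartlett's
  approximation $-(n - 1 - (p + g)/2)\ln\Lambda$ from Wilks' $\Lambda$.
  `MASS::lda` is used as an independent cross-check in the test suite,
  never as the implementation, so the Eq-layout coefficients, the zero
  boundary and the ridge path stay under the package's control.
* **In-package MLP.** No installed package trains feed-forward networks
  with two or more hidden layers, so `mlpTrain()` implements one: tanh
  hidden units, sigmoid output, binary cross-entropy, Adam
  ($\beta_1 = 0.9$, $\beta_2 = 0.999$), glorot-normal initialization,
  inverted dropout, standardized inputs, all deterministic under a seed.
  The deep menu entry defaults to the reference deep configuration
  (hidden $n$–$2n$–$n$ with $n = 200$, dropout 0.5, batch 4096) with
  epochs defaulting to 50 for desk-scale runs.
* **Boosting** maps to gradient-boosted trees (`xgboost`, 10 rounds by
  default, mirroring the reference boosting iteration count); **bagging**
  is a bootstrap bag of `rpart` trees. Behavioural equivalence with the
  original Weka implementations is explicitly not promised — the menu
  reproduces the families and their key hyperparameters, not the tools.
* **AUROC** uses the Mann–Whitney rank formulation with midranks, so ties
  count half; it equals exhaustive pairwise concordance (tested).
  Percentages (Sp/Sn/Ac) print to one decimal; raw fractions are kept
  internally.
* **Degenerate inputs.** Empty networks round-trip through the Pajek
  writer/reader; single nodes have zero entropy; zero-length layers,
  self-loops, negative weights, contradictory duplicate edge weights and
  out-of-range Pajek vertex ids are rejected with the offending line
  named.

## The synthetic web generator

`generateBipartiteBen()` emulates the bipartite interaction webs
(plant–pollinator, host–parasite) that the method targets: two guilds,
link probability proportional to $u_i v_j$ with log-normal propensities
(log-sd = `heterogeneity`), rescaled to a target connectance, redrawn
until no species is isolated (error after `maxRetries`). Heterogeneity 0
is the bipartite Erdős–Rényi case, against which the generator is tested
(binomial degree variance); positive heterogeneity produces the
right-skewed degree distributions typical of real webs. It does **not**
emulate nestedness beyond what propensity products induce, modularity,
phylogenetic signal, sampling bias, or weighted interaction strengths —
so green tests show the pipeline's mechanics and statistical sanity on
controllable webs, not field performance on real ecosystems.

Default study-scale conditions used by the test suite and acceptance
script: ten webs of 10×12 species at connectance 0.35 and heterogeneity
0.5, 25 positive + 25 negative pairs per web (500 pairs), the ten-topology
registry pool (5,000 meta-records), a 75/25 split. These sizes exercise
every stage at desk scale; the full-scale published row counts (33,805
pairs × 10 topologies = 338,050) are checked arithmetically and by the
row-count invariant.

## What is and is not reproduced

Reproduced exactly: the published confusion-table percentages from their
printed counts; the frozen five-feature discriminant's scores (free term
−0.8263); the published topology registry; the dataset shape contracts
(18/24 features, pairs × pool rows).

Not reproducible at desk scale: the published nonlinear-classifier
accuracies and the deep net's 0.866/0.935 test results, which depend on
the original 69-web dataset and trained weights. Their substitutes here:
parameter recovery (the discriminant direction of a known linear rule is
recovered with cosine > 0.95 at n = 10,000), meta-learning sanity (with a
deliberately strong and a deliberately weak base classifier the linear
meta-model beats the majority-class baseline by well over 5 accuracy
points across seeds), and a permutation null (every menu classifier stays
within 3 standard errors of chance when meta-labels are shuffled).

## Known limitations

* The published descriptor convention is unrecoverable, so
  package-computed and published descriptors are on different scales;
  models fitted on one must not be scored on the other. The registry keeps
  both explicitly separate.
* Entropy centralities of the package's convention approach the uniform
  stationary distribution quickly on dense graphs, compressing descriptor
  variance for large $k$ (visible in the registry's constant printed
  values for $k \ge 1$ on linear topologies only under *their*
  convention — under ours this exact constancy holds only for regular
  graphs).
* The generator's no-isolated-species constraint truncates the degree
  distribution slightly at low connectance and high heterogeneity, and
  makes extreme configurations infeasible (a clean error).
* Directed (arc-preserving) analysis is carried through the container but
  the pipeline treats interactions as undirected presence/absence.
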