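---
title: "Random neural network clusters for connectome classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random neural network clusters for connectome classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnnclust)
```

## The problem

Functional connectivity studies compare two groups of subjects — patients
and controls — through the correlation structure of their regional fMRI
time series. A single classifier trained on thousands of connectome features
with fewer than a hundred subjects is unstable; `rnnclust` implements a
random-subspace ensemble (the *random neural network cluster*) in which many
small neural networks each see only a random subset of subjects and
features, and the ensemble both classifies by majority vote and yields an
interpretable feature-frequency importance measure.

## From time series to features

Each subject is a T×R matrix of ROI time series (the default protocol uses
T = 110 retained timepoints on the R = 90 AAL parcellation). The pipeline
is:

1. `correlation_matrix()`: Pearson correlation of every pair of columns.
   A constant column makes the correlation undefined and is reported as an
   error naming the region rather than silently propagating `NaN`.
2. `binarize()`: an edge joins regions i and j iff |r_ij| > θ. The
   inequality is **strict**, so a correlation exactly at the threshold is
   not an edge; θ defaults to 0.25 and must lie in [0, 1). The absolute
   value means strong negative coupling also forms an edge.
3. `graph_metrics()` on the binary graph:
   * degree `N_i` — row sums of the adjacency;
   * clustering coefficient `C_i = 2e / (N_i (N_i − 1))`, `e` counting
     edges among the neighbours of i;
   * shortest-path hop counts `d_ij` (the graph is unweighted by
     construction, so paths are hop counts, not correlation-weighted
     lengths);
   * local efficiency
     `E(i) = (1 / (N_i (N_i − 1))) * sum_{j != l in V_i} 1 / d_jl`,
     with the distances `d_jl` measured inside the subgraph induced by the
     neighbourhood `V_i` (the Latora–Marchiori convention). A
     `local_distances = "global"` switch measures them on the full graph
     instead, since the nodal formula alone does not pin the convention
     down.
4. `assemble_features()`: the vector
   `[degree (R) | clustering (R) | upper-triangle d_ij, row-major (R(R−1)/2)
   | local efficiency (R)]` — 4275 features at R = 90. The layout is
   versioned metadata (`feature_layout()`) emitted with every table, and is
   the bijection that later maps selected features back to regions.

**Degenerate cases.** Nodes with fewer than two neighbours have an undefined
clustering/local-efficiency denominator and are assigned 0. Disconnected
pairs have no finite hop distance; their feature value is the sentinel R
(one more than the largest possible hop count, keeping features finite and
monotone in "farness") and they contribute 0 to local efficiency. These
conventions are exercised against an independent brute-force oracle
(Floyd–Warshall plus explicit neighbour loops) exhaustively on every graph
with up to 7 vertices and on random 30-node graphs.

## The five base classifiers

All five networks are implemented from first principles with a uniform
`fit_*`/`predict`/`accuracy()` contract, online (per-sample) training loops
in C++, and 1-of-K class coding with argmax decisions (ties to the lowest
class index). Features are standardised to training-set mean 0 / SD 1 by
default — the sigmoid units otherwise saturate on raw graph features such as
sentinel distances. Weights initialise uniform(−0.5, 0.5) from the seeded
RNG; samples are presented in fixed order each epoch so that a fitted model
is a pure function of (data, config, seed).

* **BP**: one sigmoid hidden layer, linear outputs, gradient descent on the
  per-sample squared error `E = Σ_j (c_j − t_j)² / 2`.
* **PNN**: stores the training patterns; a query is scored per class by the
  mean Gaussian kernel `exp(−‖s − s_ij‖² / σ²)`. Scores are evaluated in
  log space (log-sum-exp), which preserves the exact argmax while avoiding
  the underflow a literal kernel sum hits at small σ; the shared
  normalising constant cancels and is dropped.
* **Competitive**: unsupervised winner-take-all prototypes under the
  inner-star rule `Δw = η (p − w)`; after training each prototype takes the
  majority label of the samples it wins (prototypes winning nothing inherit
  the overall majority class). This label bolt-on is our choice — the
  competitive network itself has no supervision mechanism.
* **LVQ1**: prototypes with fixed class labels; the winner moves toward a
  matching sample and away from a mismatched one.
* **Elman**: hidden state
  `h(f) = sigmoid(W_xh e(f) + W_hh · α q(f−1))` with a linear read-out of
  the final state; trained by full backpropagation through time. The
  context decay α is fixed (default 1), not trained.

### Presenting a static vector to a recurrent network

A connectome feature vector has no temporal order, so the Elman network
needs a sequencing convention. Splitting the vector into S contiguous
chunks fed stepwise was evaluated first: because the single input weight
matrix is shared across steps, features occupying the same within-chunk
offset become indistinguishable up to recurrent dynamics, and on planted
synthetic cohorts member generalisation collapsed (mean held-out accuracy
0.46–0.56 versus 0.85 for a feed-forward pass). The default is therefore
`presentation = "repeat"`: the full vector is presented at every one of
`chunks` steps (default 3) and the recurrent state settles over repeated
exposures. Accuracy is insensitive to the step count (0.845 for 2–4 steps)
and with α = 0 the network reduces exactly to a feed-forward sigmoid
network. The chunked variant remains available as
`presentation = "chunk"`.

### Defaults

`train_config()` defaults — hidden_units = 10, η = 0.01, epochs = 500,
σ = 0.1 (on standardised features), α = 1 — are deliberately modest:
networks of this size train in ~0.1 s on 70×120 inputs, and the ensemble,
not any single member, carries the performance. Fan-in-scaled
initialisations were evaluated and did not improve member generalisation
here, so the simple uniform init stands.

## The ensemble

`cluster_config()` mirrors the reference protocol: k = 1000 members, each
trained on n_sub = 70 subjects and m_feat = 120 features sampled without
replacement from the training side of a stratified 8:2 split (for 92
subjects split 50/42 this gives 73 train / 19 test; stratification uses
per-class floor rounding with the remainder going to test). Member seeds
derive deterministically from the cluster seed (`derive_seed()`, a
multiplicative-congruential mix modulo 2³¹ − 1), so members are independent
of execution order and the whole run is reproducible bit for bit — ties in
the majority vote break toward the first listed class and are flagged in
the output rather than silently resolved. Members whose training fails are
excluded from voting and counted.

Significant members are those whose *individual* held-out accuracy strictly
exceeds `sig_threshold` (default 0.6); `feature_frequencies()` counts how
often each feature was sampled by significant members (the counts always
sum to `#significant × m_feat` — a conservation identity asserted on every
randomised test run), and `top_features()` takes the m highest counts with
ascending-index tie-breaks. `optimal_feature_count()` rebuilds the cluster
restricted to the top-m features for each candidate m over `reps` derived
seeds and picks the highest mean accuracy, breaking ties toward lower
standard deviation and then smaller m — a stability rule: a smaller feature
set that performs equally well is preferable.

**A note on selection leakage.** The reference protocol scores members on
the same held-out set that later measures ensemble accuracy, which
optimistically biases any accuracy quoted after member selection. The
package implements the protocol as stated; users who need an unbiased
post-selection estimate should hold out a third split themselves.

## Region weights and demographics

Selected features map back through the layout: nodal features add 1 to
their region's weight, pair features add 1 to each endpoint (so total
weight = nodal + 2×pair — also asserted as an identity). `rank_regions()`
filters at an **inclusive** minimum weight, matching how reported region
tables list the boundary weight itself. Cohort demographics use the plain
Pearson chi-square on the 2×2 sex table — without the Yates continuity
correction, which is what reproduces the reference cohort's printed
p = 0.528 (with correction it would be ≈ 0.76) — and a pooled-variance
two-sample t test from summary statistics for age (the reference cohort's
13.34 ± 2.41 vs 13.05 ± 1.82 gives p = 0.523, matching the printed 0.520 to
the precision that rounded summary statistics allow).

## The synthetic cohort generator

`generate_cohort()` draws each subject's T×R matrix from a multivariate
normal whose correlation matrix is `base_rho` everywhere off-diagonal, with
planted pairs shifted to `base_rho + delta_rho` in the case group. The
`noise_sd` parameter scales the marginal SD of every series; rescaling
leaves correlations untouched, so the population correlation of each pair
is exactly its target. Candidate matrices are checked for positive
semi-definiteness (smallest eigenvalue ≥ −1e−10); an inconsistent planting
(e.g. two near-unit correlations sharing a region with an uncorrelated
third pair) is rejected with a diagnostic naming the planted pairs, unless
the caller opts into eigenvalue-clipping repair. `generate_feature_table()`
is the fast path for ensemble tests: unit-variance Gaussian features with a
±effect_size/2 mean split on planted columns.

What the generator emulates is the *output* of an fMRI preprocessing chain:
stationary Gaussian series with a controlled inter-regional correlation
structure. It does not emulate autocorrelated BOLD dynamics, head motion,
physiological noise, site effects, or nonstationarity — so passing tests
demonstrate that the pipeline recovers planted correlation differences
under ideal noise, not that it would perform comparably on real multi-site
data.

## Problem sizes used in validation

The shipped tests run the full pipeline at reduced scale, chosen so the
suite exercises every stage in minutes: planted cohorts of 92 subjects with
R = 20 regions and k = 100 Elman members (ensemble accuracy and
member-mean comparisons over 10 seeds), and importance recovery with 10
planted among 200 features at k = 200 (top-20 recall over 10 seeds,
chance = 0.1). The defaults in the API remain the full protocol values
(R = 90, k = 1000, n = 70, m = 120).

## Known limitations

* The five networks are faithful to their classical formulations, not to
  any particular toolbox's refinements (no momentum, adaptive rates,
  Nguyen–Widrow init, or early stopping).
* Shortest paths are computed on the binary graph; a correlation-weighted
  variant is deliberately out of scope.
* Accuracy figures from cohorts of ~90 subjects carry wide confidence
  intervals (a 19-subject test set quantises accuracy in steps of 1/19),
  and the member-selection leakage above inflates post-selection numbers.
* The competitive network's prototype labelling is a pragmatic bolt-on;
  with unlucky initialisation prototypes can die (win nothing), which is
  why it is the weakest base classifier here, as expected.
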