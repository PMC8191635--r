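---
title: "Predicting m6A sites from sequence features and graph embeddings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting m6A sites from sequence features and graph embeddings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6ager)
```

## The problem

N6-methyladenosine (m6A) is deposited on adenosines that sit in a loose
sequence context — in many species the RRACH consensus (R = A/G, H = A/C/U)
with the methylated A at the center — but the consensus alone is far from
sufficient: most RRACH adenosines are unmethylated. `m6ager` scores a
candidate site from a fixed-length RNA segment centered on it, using two
complementary sources of information: engineered sequence features of the
segment itself, and *graph embeddings* that place each segment in the
context of all other segments of the dataset via a learned sample-similarity
network. The design premise is that sequence encoders capture local context
while the network contributes dataset-level geometry (which samples cluster
with which), and that a gradient-boosted tree model can exploit both.

## Sequence encoders

Seven encoders transform a segment of length L over {A,C,G,U} into numeric
features. Four are *unsupervised* functions of the sequence alone:

* **CTD** — global composition (4), adjacent-pair transition frequencies for
  the 6 unordered distinct pairs (count in either order / (L−1)), and, per
  nucleotide, the relative positions (position/L) of its 1st,
  ⌈0.25n⌉-th, ⌈0.5n⌉-th, ⌈0.75n⌉-th and n-th occurrence, zeros if absent.
  The transition descriptor in the literature is often stated ambiguously;
  we implement the standard unordered-adjacent-pair form and document it on
  the function.
* **PseKNC** — normalized k-mer frequencies augmented with λ correlation
  tiers θ_j, where θ_j averages the mean squared difference of six
  standardized RNA dinucleotide properties (Rise, Roll, Shift, Slide, Tilt,
  Twist) between dinucleotides j positions apart. Components are divided by
  1 + wΣθ so the vector always sums to 1. Defaults k = 3, λ = 2, w = 0.1 —
  values in the range customary for pseudo-composition encoders; the
  property table ships as a CSV (`inst/extdata/`) and is user-replaceable.
  Standardization is a population z-score over the 16 dinucleotides.
* **NPS** — frequencies of ordered nucleotide pairs with k intervening
  bases (positions i and i+k+1), k = 1..d_max, denominator L−k−1;
  d_max = 3 giving 48 features.
* **EIIP, NCP-ND** — fixed per-nucleotide electron-ion interaction
  pseudopotentials, and chemical-property bits plus the cumulative density
  (count of the position's nucleotide among positions 1..i, divided by i).

Two are *class-conditional* and are fitted on the training split only:

* **BPB** — positional nucleotide frequencies estimated separately from
  positive and negative training sequences; a sample is encoded by the
  interleaved (f⁺, f⁻) values of its observed nucleotides (2L features).
* **NPPS** — positional single-nucleotide (Fs) and k-spaced-pair (Fd)
  frequency tables per class; the feature at output position j is
  p⁺ − p⁻ with p^± = Fd^±(n1 n2, j−k−1)/Fs^±(n2, j), the conditional
  probability of the first pair member given the second. We use the
  k-intervening-bases convention throughout (pair at positions i and
  i+k+1, Fd width L−k−1): it is the only convention consistent with the
  stated table widths and output dimension. A frequency ratio with zero
  denominator is defined as 0 — the conditioning event was never observed,
  so the feature carries no information. Both k = 1 and k = 2 blocks are
  produced by default.

All frequency-type features lie in [0,1]; NPPS features lie in [−1,1]
because the pair event is a sub-event of the single-nucleotide event.
Fitting on the training split only is a deliberate leakage-safety choice:
refitting after deleting any held-out sample provably leaves held-out
encodings unchanged (this is asserted in the test suite). A
`fit_on_all` switch reproduces the alternative protocol.

## The similarity network (FLNSA)

Samples are mapped to nodes; edges connect similar samples. Similarity is
learned, not imposed: with X the fused, min–max rescaled sequence features,
FLNSA seeks nonnegative weights W, supported on each sample's c nearest
Euclidean neighbors (indicator C), that reconstruct every sample from its
neighbors:

$$\min_W \tfrac12\lVert X - (C\odot W)X\rVert_F^2
  \quad \text{s.t. } (C\odot W)e = e,\; W \ge 0 .$$

The constraint is handled as a penalty $\tfrac{\mu}{2}\lVert (C\odot W)e -
e\rVert^2$ whose multiplicative update

$$W_{ij} \leftarrow W_{ij}\,
  \frac{(XX^\top + \mu ee^\top)_{ij}}
       {((C\odot W)XX^\top + \mu (C\odot W)ee^\top)_{ij}}$$

keeps W nonnegative and the objective non-increasing (asserted per
iteration in the tests, and the converged objective is checked against an
independent projected-gradient solver on small instances). At convergence
the rows of C⊙W are projected onto the constraint (renormalized to sum
exactly 1). Min–max rescaling to [0,1] is required for the update to
preserve nonnegativity, because NPPS features can be negative.

Numerical choices: random nonnegative initialization (seeded);
convergence when the objective decrease falls below `tol` (1e−6) or after
`max_iter` (200) updates; ties among equidistant neighbors broken by lowest
row index. Defaults c = 10, μ = 1. W is row-oriented; we symmetrize by the
elementwise maximum of W and Wᵀ — preserving strong one-directional
neighbor relations — zero the diagonal, drop edges below the threshold t
(default: the median positive weight, keeping the graph sparse but dense
enough to stay connected at benchmark sizes), and binarize. The embeddings
require connectivity, so a disconnected graph triggers a bounded escalation
c ← min(2c, m−1) with a re-run; at t = 0 the construction cannot stay
disconnected at c = m−1, and a failure there signals an upstream bug.

The network is built over training *and* test samples jointly (transductive,
the protocol of the original study; no labels are involved). Users who
consider this leaky can pass `inductive = TRUE`, which restricts the graph
to training samples and assigns each held-out sample the embedding of its
nearest training neighbor in rescaled feature space.

## Graph embeddings

* **SocDim** — eigenvectors of the d largest eigenvalues of the modularity
  matrix B = A − ddᵀ/2|E|, unit-normalized, signs fixed by making each
  vector's largest-magnitude entry positive. We use the standard edge-count
  normalizer 2|E| (the only choice for which B's rows sum to zero); a
  literal node-count variant is available behind a switch for comparison.
  Dense graphs up to a few hundred nodes use a full symmetric eigensolver;
  larger graphs use an implicitly restarted Lanczos iteration with the
  matrix-free product Bv = Av − d(dᵀv)/2|E|.
* **Node2Vec** — second-order random walks with return parameter p and
  in-out parameter q (at p = q = 1 they reduce to uniform first-order
  walks, a property the tests exploit on a star graph), then skip-gram with
  negative sampling over the walk corpus, implemented in C++ and seeded
  end-to-end. Defaults p = q = 1, walk length 30, 20 walks per node,
  window 5, 5 negative samples, one SGD pass — the corpus already visits
  every node ~600 times, and a single pass is the convention of reference
  implementations.
* **GraRep** — from the row-stochastic transition matrix S, each step
  k = 1..k_max yields the positive log-probability matrix
  max(log(Sᵏ_ij / mean_i Sᵏ_ij), 0), factorized by seeded truncated SVD
  (embedding U√Σ, singular-vector signs fixed as above); the k-step blocks
  are concatenated.

Embedding widths are not prescribed by the method's description; we default
to d = 16 per method (GraRep: per step, k_max = 2, 32 columns) so that the
~100–400 sequence-derived features are supplemented rather than dominated.
Whether all three embeddings are used simultaneously is configurable; the
default fuses all three.

## Classifier and evaluation

The fused block feeds a gradient-boosted decision-tree classifier. The
backend is consumed behind a small interface; the built-in backend is
xgboost with a logistic objective, single-threaded for determinism.
Defaults: 500 rounds, depth 6, learning rate 0.05 — unremarkable GBDT
settings chosen once for the benchmark sizes, not tuned per dataset. Class
imbalance is handled by per-class weights; `"auto"` gives class y the
weight n/(2 n_y), equalizing the total weighted mass of the classes. Block
selection follows the published per-dataset block lists (shipped as the
presets `A101`, `A25`, `S21`, `H41`) or, with `blocks = "auto"`, an
importance-based selection: a preliminary model on all candidate blocks is
trained on an internal stratified split and blocks are ranked by aggregate
gain; an explicit user list always wins.

Evaluation reports ACC, SEN, SPE (percentages), F1, MCC and AUC. MCC is
defined as 0 whenever a denominator factor vanishes, keeping it usable on
degenerate folds. AUC uses the Mann–Whitney rank form with half-credit for
ties and is verified to equal the trapezoidal area under the ROC curve to
1e−12. Percent metrics print to two decimals.

## The synthetic benchmark generator

`generate_dataset()` emulates the published benchmark sets so that the full
pipeline is testable without downloads: fixed-length segments with a center
A; positives carry an IUPAC consensus (default RRACH, anchor A centered)
where each motif position follows the consensus with probability
`motif_strength`, negatives are background with a forced center A. The
background defaults to uniform {A,C,G,U} — chosen to keep analytic
expectations simple in tests — with an optional mildly A/U-rich "mrna"
preset, and positives can receive weak off-center motif copies to give the
spaced-pair encoders signal beyond the center window. At
`motif_strength = 0` the classes are exchangeable by construction, so a
correct pipeline must score at chance (AUC ≈ 0.5); at 0.9 the planted
signal is strong enough that the end-to-end pipeline should exceed 0.90
held-out AUC. What the generator does *not* emulate: positional
autocorrelation of real transcript sequence, composition biases around real
m6A peaks, homology between segments, and label noise from peak-calling —
passing tests demonstrate correctness of the machinery, not performance on
real data, for which the published benchmark FASTA files should be used.

## Problem sizes and reproducibility

The shipped checks run the complete pipeline at 2,000 samples of length 41
(ten seeds for the signal-recovery median, one null control, one 1:4
imbalanced run at L = 21) and the component oracles at small sizes (m ≤ 8
for the projected-gradient comparison, 8–10-node graphs for the spectral
checks); these sizes were chosen so that the whole suite completes in a few
minutes on a single core while still exercising the sparse/iterative code
paths used at larger m. One global seed propagates to the split, the
similarity-matrix initialization, the walks, the skip-gram, and the
booster, so a run manifest replays bit-for-bit (`run_manifest()`); the
manifest also carries a content fingerprint of the dataset and refuses to
replay against different data.

## Known limitations

* The transductive default means adding new samples changes the network and
  hence, slightly, everyone's embeddings; use the inductive mode or refit
  for production scoring. `predict_samples()` on new data transfers
  embeddings from the nearest training sample, an approximation.
* The multiplicative FLNSA update converges to a stationary point of a
  non-convex objective; different seeds can give (slightly) different
  weight matrices. The graph, being thresholded and binarized, is
  insensitive to most of this variation.
* Skip-gram embeddings are stochastic by nature; determinism is per-seed,
  not across BLAS/compiler variations of unrelated stages.
* The built-in boosting backend is xgboost's classic gradient boosting with
  depth-wise trees, not ordered boosting over oblivious trees; alternative
  backends can be slotted in behind the same `train_config(backend = )`
  interface.
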