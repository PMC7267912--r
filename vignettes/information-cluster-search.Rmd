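---
title: "Information cluster search: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Information cluster search: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icsearch)
```

## The problem

Multivoxel pattern analysis asks where in the brain the joint activation of
groups of voxels carries information about a subject-level condition (a
diagnosis, an age group, a task state). The classical searchlight answers
with a fixed-radius sphere slid over every voxel: the discriminability of the
sphere's voxels is assigned to its centre. The radius is a tuning parameter,
the sphere's shape is arbitrary, and a few strongly informative voxels
inflate the apparent extent of an informative region, because every sphere
that touches them scores well.

`icsearch` implements an alternative that removes the geometry parameter: a
data-driven search that grows an *information cluster* from every voxel of
the search space. Voxels join a cluster when they raise its discriminant
score and are pruned away when they become redundant, so the cluster's final
shape is decided by the data alone. Each of the `p` in-space voxels yields
one cluster (clusters may overlap), and each cluster carries a score; the
collection is the information map.

## The discriminant score

Subjects are the statistical units. For an activation matrix `X` (voxels x
subjects, each entry a time-averaged BOLD value) and class labels with
per-class counts `n_l` out of `n` subjects, two subject-affinity graphs are
built:

* between-class affinity `S_b[i,j] = 1/n - 1/n_l` when subjects `i, j` share
  class `l` (including `i = j`), else `1/n`;
* within-class affinity `S_w[i,j] = 1/n_l` for same-class pairs, else `0`.

With row-sum degree matrices these give graph Laplacians `L_b = -S_b` and
`L_w = I - S_w` (rows of `S_b` sum to 0, rows of `S_w` to 1), both positive
semidefinite. The relevance of a voxel set `M` with 0/1 selection matrix `W`
is the trace ratio

    S(M) = tr(W' X L_b X' W) / tr(W' X L_w X' W),

the ratio of between-class to within-class scatter of the selected features
— the group generalization of the per-voxel Fisher score, which is exactly
the trace ratio of a single voxel. When labels are unavailable,
`build_affinity_unsupervised()` substitutes a Laplacian-score construction: a
symmetrized k-nearest-neighbour heat-kernel graph for `S_w` (defaults
`k = 5`, bandwidth = median pairwise subject distance, the conventional
choices) and the uniform complete graph for `S_b`.

Because the trace decomposes over selected voxels, `S(M)` is a ratio of two
sums of per-voxel quadratic forms `b_i = x_i' L_b x_i` and
`w_i = x_i' L_w x_i`. The package computes `b` and `w` once per dataset
(`spectral_cache()`); every score queried during the search afterwards is an
O(1) ratio update. A useful consequence used throughout the tests is the
mediant bound: `S(M)` always lies between the smallest and largest member
ratio `b_i / w_i`.

One degree-matrix subtlety: with the diagonal-of-`S` reading of the degree,
the within Laplacian would not annihilate constant vectors and could be
indefinite; the row-sum degree restores both properties and preserves the
Fisher-criterion interpretation, so that is what the package uses.

## The search

From every origin voxel, expansion and pruning alternate:

1. **Expansion.** Every in-space voxel adjacent to the current cluster is
   tested one at a time against the cluster frozen at the start of the layer:
   candidate `v` passes when `S(M + v) - S(M) > 0`, strictly. All passing
   candidates join together. Joint admission keeps the result independent of
   candidate enumeration order, and because each passing candidate has
   `b_v/w_v` above the current score, the mediant bound guarantees the joint
   score still rises.
2. **Pruning.** Each member's redundancy is its mean pairwise mutual
   information with the rest of the cluster. Members are scanned in
   decreasing-redundancy order (ties to the lowest linear index) and one is
   removed when (a) it is neither the origin nor admitted by the immediately
   preceding expansion, (b) at least two members remain, and (c) removal does
   not lower the cluster score. After every removal the scan restarts with
   fresh redundancies; pruning stops when no removal qualifies. There is no
   redundancy threshold to tune — the relevance gate decides.
3. Repeat until an expansion admits nothing.

Two one-phase exclusion windows prevent oscillation: voxels removed by a
prune are not re-tested by the immediately following expansion, and voxels
admitted by an expansion are protected from the immediately following prune.
The windows last exactly one phase — permanent bans would change the method.
The origin is protected permanently, preserving the identity "the cluster
originating at `v`" that the per-voxel output map relies on. Expansion
strictly increases the score and pruning never lowers it, so the score is
strictly monotone across phases and the search terminates; a safety cap of
`4p` steps per origin is enforced and flagged (`capped`) but is never reached
in practice. The search contains no randomness: ties everywhere break on the
geometric linear index, and repeated runs are identical.

Pruning may disconnect a cluster. The member set is kept as-is (candidate
neighbourhoods are computed for the whole set) and the `connected` flag
records it, since nothing in the model requires connectivity after pruning.

### Memoization

Two caches make whole-region runs practical: the spectral cache above, and a
lazily-filled hash table of pairwise mutual information, shared across all
origins of a run. Pairs are computed only when a prune actually needs them,
so the fraction of computed pairs stays well below `p(p-1)/2` and
concentrates among spatially nearby voxels. `run_ics(memoize = FALSE)`
recomputes every quantity on demand; it exists to demonstrate that the
caches are numerically neutral (the test suite checks member-set identity),
and a pure-R reference implementation of the search rules
(`grow_cluster(engine = "r")`) provides an independent cross-check of the
compiled engine.

## Mutual information estimator

Voxel pairs are discretized by equal-frequency (quantile) binning, default 8
levels, and MI is the plug-in estimate on the joint histogram in nats
(`0 log 0 := 0`). Quantile binning is scale-free, which matters because
voxels are compared after per-voxel standardization anyway. Tied values may
merge bins; a constant voxel occupies one bin and has MI 0 with anything.
With fewer than 16 subjects the bin count is lowered to `n/2` (minimum 2) so
each bin can hold at least two observations. The estimator is deliberately
simple: the search only ranks redundancy within small clusters, where the
plug-in bias is common to all members being compared.

## Synthetic data generator

`generate_dataset()` emulates a two-condition population:

* per subject, a voxels x time Gaussian noise matrix (default `T = 120` time
  points, unit per-timepoint SD, baseline level 1 in arbitrary BOLD units);
* spatial structure: each voxel's series is mixed with the mean of its
  6-connected neighbours' series, `z_i = x_i + lambda * mean(x_N(i))`. For an
  edge with degrees `k_i, k_j` the induced correlation is
  `lambda (1/k_i + 1/k_j) / sqrt((1 + lambda^2/k_i)(1 + lambda^2/k_j))`;
  `lambda` is solved so the mean over the grid's actual edges equals the
  target `spatial_rho` (default 0.3, a realistic adjacent-voxel correlation),
  which keeps low-degree boundary voxels from inflating the average;
* condition effect: for case subjects, `amplitude x envelope(t)` (in
  baseline-SD units) is added to the planted voxels. The envelope is a
  peak-normalized double-gamma hemodynamic response sampled over a 32 s
  window — the simulated acquisition covers a single evoked response — so an
  amplitude of 1 SD yields a time-averaged mean shift of
  `mean(envelope) ~ 0.15` SD units before averaging gains;
* the subject's feature vector is the time average; the planted voxel set is
  returned as ground truth.

Defaults mirror the benchmark population: 1,000 subjects split evenly, and
preset search spaces of 100 / 500 / 10,000 / 30,000 voxels
(`synthetic_preset()`). The generator does **not** model physiological noise
spectra, scanner drift, motion, or multi-site batch effects; passing tests
on it shows the search behaves as designed under Gaussian spatially
correlated noise, not that it is robust to every artefact of real fMRI.
`simulate_atrophy()` scales the case group's signal in a chosen region by
`1 - fraction` (e.g. 25% signal loss), giving a proportional-effect
detection target; the nonzero baseline level exists precisely so that
proportional loss is expressible.

## Evaluation protocol

The reported *information* of a voxel set is the stratified 5-fold
cross-validated AUC of a linear max-margin classifier (SVM) using only those
voxels as features — AUC because the above-chance (> 0.5) selection rule
needs the chance anchor. The decision-value orientation is fixed by the
training labels (positive class = second factor level), never flipped after
seeing performance, so null AUCs stay centred at 0.5.

Feature sets are discovered on a stratified 80% training split and scored on
the held-out 20% (`train_test_split()`): clusters are selected using the
labels, so scoring them on the same subjects is optimistically biased — on
pure-noise data the in-sample bias reaches ~0.15 AUC, while held-out scoring
is centred at chance. The cost is variance: with 200 subjects the held-out
set has 40, and a null cluster's AUC then has a standard deviation near 0.09,
so individual null clusters exceed 0.6 about one time in seven even though
the mean is calibrated. Calibration claims about the *mean* information are
therefore tight, while tail fractions at 0.6 are not — a limitation of the
evaluation-set size, not of the estimator.

Method comparisons use matched-size detection: each method ranks voxels by
its own map — ICS by the relevance overlay (each voxel scored by the best
cluster containing it, the overlap-resolution rule of the output maps),
searchlight by the sphere score, the L1 baseline by `|coefficient|`
restricted to its nonzero selection — and the top `|truth|` voxels are the
detected set. Comparing at equal detected-set size isolates ranking quality
from threshold choice; the L1 baseline may detect fewer (it cannot rank
beyond its selected set), which is its characteristic failure mode.

`best_cluster()` ranks clusters by information, then size, then origin
index. The size tie-break matters whenever the AUC saturates at 1: among
equally informative clusters, the most extensive one is the most complete
map of the informative region, which is what a mapping method should report.
The `select_features()` rules (`above_chance`, `top_k` with default
`k = 50`) break ties by origin linear index only, keeping the
feature-selection path free of any extent preference.

## Numerical choices

* Degenerate within-class scatter (`sum(w) < 1e-12`, e.g. a cluster constant
  within every class) scores `+Inf` with a warning — treated as maximally
  informative rather than an error; it arises only on pathological input.
* Admission is strict (`dif > 0`): ties reject, so score-neutral growth is
  impossible.
* Prune removals tolerate a relative score slack of `1e-12`, so removing an
  exact duplicate (mathematically score-neutral, but summed in floating
  point) qualifies.
* Per-voxel standardization (zero mean, unit variance across subjects) is on
  by default and toggleable; the trace ratio is scale-sensitive per voxel and
  standardization makes scores comparable across voxels.
* `b` and `w` are quadratic forms of PSD matrices; negative numerical dust is
  clamped to zero.

## Problem sizes

The shipped tests and the acceptance script exercise: oracle equivalences on
50-voxel/40-subject matrices; memoization neutrality on a 5^3 grid with 30
subjects; recovery, null-calibration and atrophy experiments on a 10^3-voxel
grid with 100+100 subjects across 20-50 generator seeds; and sparsity checks
on the 100-voxel preset. These sizes were chosen so the full synthetic
benchmark reproduces the method's qualitative claims — planted-block
recovery, chance-level calibration on null data, searchlight
over-detection and L1 under-detection around an atrophied region — at
desk scale.

## Known limitations

* The spectral score is a two-or-more-class criterion; continuous targets
  are out of scope.
* The per-origin loop is serial; results are defined to be identical to
  serial order, so any future parallelism must preserve it.
* Mutual information uses plug-in histogram estimation, not k-NN/Kraskov
  estimators; fine for ranking redundancy, not for unbiased MI values.
* Subject-level (single-subject) mapping and temporal-dynamics extensions
  are not addressed; the unit of analysis is the subject's time-averaged
  activation.
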