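---
title: "Methods: oncogenetic tree models for copy number alteration cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oncogenetic tree models for copy number alteration cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncotreefit)
```

## The inference problem

The input is an n × k binary matrix: n tumors scored for the
presence/absence of k genetic events (here, gene-level copy number
alterations). The goal is a rooted tree over the events — the root being
the normal, alteration-free state — whose structure summarizes the typical
order in which the events accumulate during progression. Two standard
model families are implemented; they make different structural assumptions
and are intended to be used together, as mutual cross-checks.

Both share one generative core: each tree edge e carries a *firing
probability* `p_e`; per tumor, edges fire independently, traversed from
the root downward, a child edge being reachable only if its parent edge
fired; an event is present iff every edge on its root path fired. The only
patterns possible under this model are *downward-closed* event sets (an
event never appears without its tree ancestors); everything else is
attributed to observation error or model misfit.

## Branching tree

The branching model puts every event at a tree node with exactly one
parent. Fitting is a two-stage procedure:

1. **Weights.** From smoothed marginal and joint probabilities we score
   every ordered pair,
   `w(i→j) = 2 log p_ij − log(p_i + p_j) − log p_i − log p_j`,
   the sum of a *nesting* term `log[p_ij/(p_i+p_j)]` (is j contained in
   i's tumors?) and a *correlation* term `log[p_ij/(p_i p_j)]`. Treating
   the root as an always-present pseudo-event (`p_root = 1`,
   `p_root,j = p_j`) gives `w(root→j) = log(p_j/(1+p_j))`, so every event
   always has a finite fallback parent.
2. **Topology.** The fitted tree is the maximum-weight arborescence rooted
   at the normal state, computed by the Chu–Liu/Edmonds optimum-branching
   algorithm (greedy best-incoming-edge selection with cycle
   contraction). For two identical events the weight is exactly 0 and for
   independent events it is `log p_ij < 0`, so strongly nested/correlated
   pairs attract parent–child edges.

Each edge then carries the moment estimate `cond_prob(j) = p_ij / p_i`
(the marginal `p_j` for root children).

**Observation error.** Real call sets contain false positives and false
negatives. The package models a single shared error pair: an observed
indicator flips 0→1 with `eps_plus` and 1→0 with `eps_minus`,
independently per event. The pattern likelihood sums over all
downward-closed true-event sets T,
`P(obs) = Σ_T P(T) · Π_j error-term(T_j, obs_j)`, with
`P(T) = Π_{j reachable} (π_j if j∈T else 1−π_j)`; edges below a non-fired
edge contribute no factor. `fit_error_model()` maximizes the cohort
log-likelihood over all `π_e ∈ [1e−6, 1−1e−6]` and `eps_± ∈ [0, 0.3]`.
A shared error pair is the simplest model that is identifiable from
six-event data; per-event error rates are a deliberate non-goal.

## Distance-based tree

Here events are *leaves* and internal nodes are hidden (unobserved)
events. With branch lengths `−log p_e`, the generative core implies an
additive metric: two leaves whose root paths separate at a meeting point m
with root-path probability `P_m = p_i p_j / p_ij` are at path distance

```
D_ij = r_i + r_j − 2·(−log P_m) = log p_i + log p_j − 2 log p_ij,
r_i  = −log p_i .
```

(The derivation is three lines of algebra from the path-product law
`p_i = Π_{e ∈ path(i)} p_e` and is the reason `D_ij ≥ 0` needs
`p_ij ≤ min(p_i, p_j)`, which the smoothing enforces.) Because the metric
is exactly additive when the data follow the model, neighbor joining over
the k events plus a root pseudo-leaf at distances `r_i` recovers the
generating topology exactly — the round-trip identity is asserted in the
test suite on 100 seeded random trees. Topology search is therefore NJ
rather than exhaustive ML search: it matches the distance-based character
of the model and is instant at k = 6. An exhaustive ML topology search
over all unrooted binary shapes is exposed (`exhaustive_ml_topology()`,
k ≤ 5) purely as a cross-check.

Branch lengths can be re-fit by exact maximum likelihood
(`ml_edge_probabilities()`), enumerating all downward-closed edge-firing
states (bounded at 16 edges, which keeps a k = 6 panel — about 11
edges — well under a second per evaluation).

The distance model has *no* observation-error layer; error handling lives
entirely in the branching model. This keeps the two models structurally
independent verifications of each other.

## Bootstrap

`bootstrap()` draws B resamples of the n tumors with replacement and
refits the chosen model on each. Branching topologies are canonicalized
as the sorted list of `child<parent` pairs; distance topologies as the
sorted set of leaf bipartitions with the root pseudo-leaf included.
`consensus_report()` lists splits with support strictly greater than the
threshold (default 0.10 — the conventional ">10% of bootstrap datasets"
display rule; a split at exactly 10% is excluded). Replicate b derives
its seed as `master seed + b`, so results are independent of execution
order and bit-reproducible.

Two deliberate choices:

* Events with zero occurrences in a resample are retained — the
  probability clamping keeps all weights finite — so topologies remain
  comparable across replicates; replicates are never dropped.
* The distance-model bootstrap refits the NJ topology only (not the ML
  branch lengths): support is a topology statistic and the lengths do not
  affect it, while an ML refit per replicate would dominate the runtime.
* `modal_parent_tree()` implements the "most frequent parent" consensus:
  per event, its modal bootstrap parent. This map need not be an
  arborescence; when the majority parents form a cycle the function
  reports the failure rather than silently repairing it.

## Synthetic data: what it does and does not establish

`simulate_cohort()` draws cohorts from the generative core plus the error
layer; `paper_tree_fixture()` is the built-in six-gene breast-carcinoma
reference: CCND1, PTEN, AKT2 and ErbB2 on root branches, KRAS and PIK3CA
under ErbB2, with edge probabilities chosen so the model marginals equal
the published cohort frequencies exactly (ErbB2 edge 121/963, KRAS edge
25/121, PIK3CA edge 51/121, and so on), n = 963, no observation error.
These defaults are the stated world of the analysis; they are not tuning
knobs.

KRAS and PIK3CA are *siblings* under ErbB2 in the default fixture: a
KRAS→PIK3CA chain is incompatible with the observed marginals (PIK3CA,
51/963, is more frequent than KRAS, 25/963, and a descendant can never be
more frequent than its ancestor under the model). The chain variant is
still provided (`variant = "chain"`) with the PIK3CA edge probability
capped at 1, i.e. a model marginal of 25/963 rather than 51/963 — the cap
and the mismatch are intentional and documented rather than hidden.

`fixture_from_counts()` builds a deterministic matrix with exact column
sums (and, optionally, an exact number of altered rows) by a greedy
layout: the altered rows receive one event each, largest-count events
first, then the remaining 1s are stacked column by column into
already-altered rows. It reproduces marginal structure *only*: its joint
co-occurrence pattern is an artifact of the layout (maximally stacked),
so it is suitable for frequency-level checks, not for validating fitted
topologies. Cohorts simulated from the reference tree carry a
model-faithful joint structure but, by construction, cannot reproduce
whatever co-occurrence the real tumors had beyond the tree assumption —
a green recovery test establishes that the fitters invert the model, not
that the model is true of any particular cohort.

## Numerical choices

* **Smoothing.** All probabilities are clamped into
  `[1/(2n), 1 − 1/(2n)]`, then joints are re-capped at
  `min(p_i, p_j)`. Clamping (rather than pseudocounts) keeps the joint
  cap enforceable, guarantees finite log-weights, and is recorded in the
  estimates (`pseudo_floor`) for reproducibility.
* **Percent rounding.** Integer percentages round half away from zero —
  the only rule consistent with the published cohort values
  (342/963 = 35.51 → 36; 12.5 → 13).
* **GISTIC binarization.** Default `|call| ≥ 2` (high-level
  amplification / deep deletion), configurable down to `≥ 1`; the
  threshold is a stated input, not something inferred. Missing values are
  rejected — the model has no missing-data mechanism.
* **Tie-breaks.** In the arborescence fit, equal-weight incoming edges
  resolve to the lexicographically smaller parent name, making results
  bit-reproducible.
* **Optimization.** Both ML fits use bounded L-BFGS-B with 5 starts: the
  moment estimate (with `eps = 0.01` where applicable) plus deterministic
  logit-offset perturbations (±0.75, ±1.5, alternating sign per
  coordinate). Deterministic offsets, not random restarts, keep fits
  reproducible without touching the global RNG. The returned optimum is
  contractually never worse than the moment start.
* **Neighbor joining.** Negative inferred branch lengths are clamped to 0
  with a warning; internal edges shorter than 1e−9 are collapsed, which
  restores polytomies and direct root attachments that binary NJ would
  otherwise represent with zero-length edges.
* **Enumeration bounds.** Exact likelihoods enumerate downward-closed
  sets: at most 20 events (branching) / 16 edges (distance); beyond that
  the functions refuse rather than approximate.

## Known limitations

* Single tree per cohort: no mixture-of-trees, no per-event error rates,
  no continuous-time ordering.
* The branching-vs-distance comparison is qualitative; the two
  likelihoods are not on a common parameter space, so no formal model
  selection is offered.
* The additive-distance triangle inequality through the root
  (`D_ij ≤ r_i + r_j`) is a *model* property, equivalent to
  `p_ij ≥ p_i p_j`; finite-sample estimates of independent or mutually
  exclusive event pairs can violate it slightly, and the distance model
  cannot represent negative association at all — that limitation is the
  main reason the branching model (where exclusivity shows up as low
  conditional probabilities) is fit alongside it.
* Bootstrap support is split/topology frequency only; no BCa or
  percentile intervals on edge probabilities.
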