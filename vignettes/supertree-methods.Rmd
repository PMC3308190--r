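---
title: "Supertree estimation with matrix representation and SCM refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supertree estimation with matrix representation and SCM refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(superfine)
```

## The problem

A supertree method combines a *profile* of source trees — unrooted
phylogenies on overlapping subsets of a taxon set S — into one tree on all
of S. Source trees typically come from separate gene or marker analyses
with very different taxon sampling: a handful of densely sampled clades
plus one sparser tree that spans the whole group. This package implements
a family of matrix-representation supertree methods and the divide-and-
conquer strategy that refines a strict consensus merger (SCM) tree, along
with the error metrics and simulation machinery needed to study them.

## The MRP matrix

Every internal edge e of every source tree t induces a bipartition of
t's leaf set. The Baum–Ragan coding (`encode_baum_ragan()`) turns the
profile into a taxa × edges matrix over {0, 1, ?}: taxa on one side of e
get 1, taxa on the other side 0, and taxa absent from t get '?'. Under
reversible (unordered, equal-cost) parsimony on two states the choice of
polarity has no effect on tree scores, so the package fixes it
deterministically: state 1 goes to the canonical side of the bipartition,
the side that excludes the byte-order smallest taxon of t's leaf set.
This makes the encoding reproducible and testable without changing any
score.

## MRP: matrix representation with parsimony

`mp_score()` evaluates the minimum number of 0↔1 changes per column by
Fitch's set recursion, generalized to polytomies and missing states by
Hartigan's rule: at each node the state counts over the children's
optimal sets are tallied, the majority states are kept, and the deficit
(children minus maximum count) is added to the score. The recursion runs
on an arbitrary rooting; because the root state is free, the score is a
property of the unrooted topology. The whole matrix is scored in one
vectorized postorder pass.

`mp_search()` is a standard heuristic: random-addition starting trees
(each taxon inserted at its locally best edge), hill climbing under NNI
(optionally SPR) with deterministic first-best tie-breaking, and an
optional parsimony-ratchet perturbation that temporarily upweights a
random fraction of columns (default 25%, weight 3). The search is a
faithful stand-in for the large-scale MP heuristics used in practice
(ratchet, sectorial searches), not a re-implementation of any particular
program. All equally best topologies found are retained up to a cap
(default 100, deduplicated by canonical bipartition set), and the MRP
tree reported by the pipeline is their greedy consensus — mirroring how
MP analyses are summarized in practice.

## MRL: matrix representation with likelihood

MRL scores the same matrix under the symmetric two-state (CFN) model:
stationary frequencies (½, ½) and equal exchange rates, so the
probability that a site changes across a branch of length t (expected
substitutions/site) at relative rate r is (1 − e^(−2rt))/2. Missing
entries contribute the partial (1, 1) and an all-'?' column contributes
exactly zero log-likelihood. Rate variation across sites uses a mean-one
discrete gamma with k equal-probability categories represented by their
class means (k = 4 by default; k = 1 reduces exactly to equal rates).
The number of categories used for reported scores is a convention, not a
fitted quantity, and is exposed as a parameter.

The pruning recursion and the branch-length optimizer are implemented in
compiled code. Branch lengths are optimized coordinate-wise: one
postorder pass per sweep fixes the subtree ("down") partial likelihoods,
and a root-down traversal maintains the complementary ("up") partials
with already-updated lengths above, so each golden-section search sees
the exact likelihood and the log-likelihood is non-decreasing across
sweeps. Bounds are [1e−8, 20] substitutions/site; the gamma shape is
optimized on the log scale within [0.02, 100], and an estimate within 5%
of a bound is flagged. `ml_search()` climbs NNI neighborhoods from an MP
start (the default; cheap and good), scoring candidates at the current
lengths and shape and re-optimizing both after each accepted move.

The **MRL score** of *any* topology — whatever method produced it — is
the S2+Γ log-likelihood after optimizing branch lengths and shape on the
fixed topology (`mrl_score()`). Unresolved trees are scored as-is (the
pruning handles polytomies) and flagged, so strict- and greedy-consensus
summaries remain comparable.

## The strict consensus merger

`scm_tree()` merges two trees at a time, always picking the pair of
current trees with the largest shared taxon set (ties: larger resulting
union, then lowest index — the plan depends only on the leaf sets and is
deterministic). A pairwise merge (`pairwise_scm()`):

1. restricts both trees to the shared taxa X and takes the strict
   consensus as the *backbone* (edges on which the trees disagree are
   thereby contracted);
2. re-attaches each maximal subtree of tree-exclusive taxa at the
   backbone point corresponding to its attachment in its own tree — a
   node of the backbone, or a point subdividing a backbone edge;
3. contracts any *internal* backbone edge that receives attachments from
   both trees (a **collision**): the edge's bipartition cannot be
   reconciled with an ordering of the two trees' attachment points, so
   all colliding subtrees join the resulting polytomy.

Two interpretation points were left open by the method's description and
are fixed here as follows. Attachments by both trees to the same backbone
*node* are not collisions. Attachments by both trees along the same
*pendant* edge of the backbone merge at a single new attachment point on
that edge rather than contracting into the adjacent node: a pendant edge
carries no bipartition that could be lost, and this choice preserves the
grouping of the leaf with both sets of newcomers (merging a|bc-style
inputs into ab|c-free polytomies otherwise destroys information that both
trees agree on). Within one tree, multiple attachment points along one
backbone edge keep their original order.

The SCM tree contains all of S but is generally unresolved; its
resolution (internal edges as a fraction of the n−3 possible) is
reported. On mutually compatible profiles it never contains a false edge,
which the test suite checks over dozens of random profiles.

## SuperFine refinement

Each polytomy v of degree d partitions S into the d components of
SCM − v. `label_taxa()` records that partition; `reduce_source_tree()`
relabels each source tree's leaves by their block and collapses
same-label sibling leaves until every label occurs at most once (at most
d leaves remain). The base method (MRP or MRL) runs on the reduced
profile, and the resulting tree on labels replaces the polytomy, each
component re-attaching at its label's position. Refinements only ever add
bipartitions, so bipartitions(SuperFine output) ⊇ bipartitions(SCM) on
every input — the structural reason the SCM's low false-positive rate is
inherited.

Because a polytomy's reduced profile depends only on the SCM tree and the
sources, the refinements are independent; the package additionally
derives each polytomy's RNG stream from the global seed and a hash of its
taxon partition, so the processing order cannot influence the output even
with stochastic base searches (this is tested by shuffling the order).
Two degenerate cases are handled conservatively: if no reduced source
tree is informative the polytomy is kept, and a label absent from every
reduced tree (hence unplaceable by the base method) is re-attached at the
highest-degree internal node of the resolution — a deterministic hub;
such labels are rare because every taxon occurs in some source tree.

## Error metrics and the correlation protocol

`fn_rate()` (missing branch rate) and `fp_rate()` are the percentage of
true-tree edges missing from the estimate and of estimate edges absent
from the truth; they coincide for binary pairs, and FP ≤ FN whenever the
reference is binary. `rf_distance()` is the symmetric difference count,
and `sum_fn()` totals source-tree edges missing from the supertree's
restrictions (proportional to summed RF when everything is binary).

`correlation_experiment()` reproduces the score-versus-error protocol:
each estimated supertree spawns p-ECR neighbors (contract p random
internal edges, then refine at random) with p uniform on
[0, ⌈0.25·(n−3)⌉] per input tree, 100 neighbors per supertree by default;
originals and neighbors are then scored by MP score, MRL score and
Sum-FN, and each score's Spearman rank correlation with the FN rate is
reported. Signs are oriented so that positive correlation always means
"worse score, larger error" (the MRL log-likelihood is negated).
Unresolved input supertrees are randomly refined first (seeded) so that
error rates are comparable; `keep_polytomies = TRUE` retains them
instead. MRL scoring inside the experiment caps the branch-length
optimization at a few sweeps per tree; ranks are insensitive to the tail
of that optimization and this keeps the 606-tree protocol fast.

`random_refinement()` resolves each polytomy by recursively splitting its
neighbor set into two random parts of size ≥ 2. This is not uniform over
all resolutions of a polytomy; the protocol only requires a random
refinement, and the scheme is simple, seeded and degree-agnostic.

## The synthetic generator

`make_profile()` emulates the simulated study design: a binary model tree
(random topology via random addition, i.i.d. exponential branch lengths
with mean 0.1 substitutions/site), `n_clade_trees` clade-based source
trees — the model restricted to *all* taxa of a clade whose size falls in
a range — plus one scaffold tree on ⌈density·n⌉ taxa sampled uniformly.
The scaffold density is the central experimental dial (the study used
20/50/75/100%). Estimation error is optional and comes in two forms:
`characters` simulates a stated number of binary characters on the source
tree under the CFN model and re-estimates the topology by heuristic MP,
so error arises organically and shrinks with the number of sites (default
250, chosen so that source-tree error is clearly visible at n ≤ 64); or
`nni`, which applies Poisson(rate·(n−3)) random NNI moves — cheaper, and
used where many replicates are needed.

What the generator does *not* emulate: DNA-level simulation (the original
datasets evolved sequences under realistic models and re-estimated trees
with a full ML pipeline), alignment error, indels, or the taxon-sampling
biases of real systematic studies. Passing tests therefore demonstrate
the algorithms' correctness and the study's qualitative trends at desk
scale, not the original publication's numerical error rates, which depend
on 500/1000-taxon benchmark datasets and third-party search programs.

The clade-size distribution was left open by the study design; the
generator defaults to sizes in [max(4, n/20), max(8, n/4)]. At the scaled
size used throughout the tests (n = 32) that range produces mostly
disconnected profiles — clades too small to overlap — so the experiment
drivers use [n/4, 5n/8] (8–20 taxa at n = 32), which keeps roughly 80% of
replicates connected; disconnected replicates are skipped, exactly as
low-overlap replicates were excluded in the original study. Profile
connectivity under ≥2-taxon overlaps is always checked and warned about.

## Numerical and design choices

* Bipartitions are stored canonically as the side *not* containing the
  byte-order smallest taxon of the universe, making hashing, consensus
  and RF computations polarity- and anchor-independent. All label
  ordering uses byte (radix) order so results do not depend on the
  locale.
* Greedy-consensus frequency ties are broken by the canonical ordering of
  the bipartition keys; MP tie-breaking takes the first best move in
  enumeration order. Both make otherwise arbitrary outcomes
  deterministic.
* Likelihood partials are rescaled per pseudo-site whenever they fall
  below 1e−240, with per-category log-scale bookkeeping, so mixtures stay
  exact on large trees.
* Degenerate inputs: trees with fewer than 4 leaves carry no unrooted
  topology and are rejected at profile load; matrix rows that are all-'?'
  are unplaceable and dropped from searches with a warning; merges with a
  2- or 3-taxon overlap are legal but warn, since they convey no
  topology.
* Scaled problem sizes: the test suite and the acceptance script run the
  full pipelines at n = 8–32 taxa with 4–7 source trees per profile.
  These sizes were chosen so that every stochastic check rests on
  dozens of replicates while the whole suite stays fast; they are the
  package's reference conditions, and all seeds are explicit.

## Known limitations

* The MP and ML searches are NNI/SPR hill climbers with random restarts;
  on large, conflict-rich matrices they will not match dedicated
  programs' search quality (that is exactly the gap SuperFine-style
  refinement narrows, since its subproblems are small).
* The CAT-style speedup of per-site rate assignment is not implemented;
  scores are always gamma-mixture scores, the standard scale for
  reporting discrete-gamma log-likelihoods.
* `random_refinement()` is non-uniform over resolutions (documented
  above).
* The SCM collision semantics at pendant edges is this package's
  committed interpretation of an under-specified step; it is documented
  above and covered by unit tests.
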