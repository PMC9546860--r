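---
title: "Greedy decision forests for network module detection: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Greedy decision forests for network module detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In systems biology, prior knowledge often comes as a graph: a
protein–protein interaction network connects genes whose products are known
to function together. Each node additionally carries one feature vector per
data modality (say, mRNA expression and DNA methylation across the same
patients), and each sample has a binary outcome. The goal of `gdforest` is
not merely to classify, but to *select*: find small connected subnetworks
("modules") whose joint features predict the outcome, and rank them so a
domain expert can read the decision rules off a handful of genes. Features
that act jointly need not be marginally correlated with the outcome (the
canonical hard case is an XOR of two AND pairs), which is why community
detection and co-expression clustering miss such modules and why univariate
feature selection does too.

## The model

A decision forest is restricted by the graph: the feature set of each tree
is produced by a uniform random walk. A walk of depth $d$ visits $d$ nodes
(repeats allowed); the tree may split on any modality of any visited node.
The initial depth is $\lfloor\sqrt{|V|}\rfloor$ — the usual `mtry`
heuristic, here interpreted as a walk length — clamped to at least
`min_depth = 2` so every surviving module can contain an edge.

Trees are CART: binary splits at midpoint thresholds maximizing the Gini
gain, grown until pure or until no split has strictly positive gain
(`min_leaf = 1` by default, no depth cap — the walk already bounds the
feature count). Leaves store class-1 proportions, so out-of-bag (OOB)
ROC-AUC is informative even for tiny trees. Each tree is fitted on a
bootstrap sample and scored on its OOB complement.

The greedy loop evolves `ntree` such trees for `niter` iterations. Per slot
and iteration:

1. **Propose.** A walk of `max(depth - 1, min_depth)` visits, seeded at a
   uniformly chosen node of the slot's current node set, yields a candidate
   feature set; a tree is fitted on a fresh bootstrap.
2. **Accept.** The incumbent tree is re-scored on the proposal's OOB
   samples; the proposal replaces the incumbent iff its OOB AUC on that
   common set is at least the incumbent's. Otherwise the incumbent stays
   (keeping its tree, nodes and depth) and records the refreshed
   performance estimate.
3. **Resample.** After all slots are updated, `ntree` slots are redrawn
   with replacement with probability proportional to performance.

Because acceptance requires non-decreasing performance at decreasing walk
depth, lineages shrink toward minimal feature sets; because resampling
favours performant slots, the population concentrates on a few modules.

### Ranking

Every iteration, each slot's performance is credited to every graph edge
whose two endpoints are both in the slot's node set. A module's
mean edge importance is the sum of its induced edges' credits divided by
the number of those edges *and* by `niter * ntree`, so a module whose edges
persist in every slot of every iteration at perfect performance scores
exactly 1. The ranking key is

$$\mathrm{IMP}_m = \overline{\mathrm{IMP}_e} + \mathrm{Perf}(T_m),$$

with $\mathrm{Perf}(T_m)$ the best OOB AUC among the final population's
trees sharing that node set. Performance alone cannot punish redundant
nodes (a tree simply ignores them); the edge term can, because a superset's
extra edges are rarer in the population and dilute the mean. Gini-gain
importances per (node, modality) and TreeSHAP attributions provide the
feature-level view; both aggregate across modalities per node by summation.

### Why the per-slot normalization of edge importance

As printed, the module edge score divides the cumulative credit only by the
module's edge count, which grows without bound in `niter * ntree`. The
reported values (a perfect module with mean edge importance 0.67, module
score 1.67, maximum 2) are only attainable with an additional
`1/(niter*ntree)` factor, exactly parallel to the explicit normalization of
the feature importances. We adopt that reading; the raw cumulative tally
remains available (`accumulate_edge_importance`).

## Design choices where the design was open

**Proposal walks are seeded at the current module but walk on the full
graph.** A literal reading would confine the walk to the subgraph induced
by the current node set, making node sets monotonically shrinking — the
target module could then be found only if one of the `ntree` initial walks
already covered all of it. On the 50-node planted-XOR benchmark we measured
that probability at 0.03%–1.4% per walk depending on topology; no
population size in reasonable reach makes exact recovery reliable that
way, and monotone shrinkage also cannot produce the observed phenomenon of
lower-ranked modules being supersets of the top module. Seeding at the
module keeps proposals local (a bounded walk rarely strays far) while
allowing a lineage to complete a partial module with a neighbouring node.
Measured effect at the benchmark settings (`ntree = 100`, `niter = 50`, 10
replicates): exact-recovery coverage 1.0 versus ~0.4 under confinement.

**Paired acceptance with incumbent re-scoring.** Comparing a fresh
proposal's OOB AUC against a *stored* incumbent value creates a ratchet:
lineages lock in lucky draws (AUC is noisy at OOB sizes of ~370), then
reject everything, freezing inflated scores into the final ranking.
Re-scoring the incumbent tree on the proposal's OOB draw makes acceptance a
paired, low-noise comparison and keeps every stored performance an honest,
current estimate. It also slows depth collapse: equal-quality shrink
proposals are accepted (minimality), genuinely worse ones are not.

**Acceptance on ties.** Equality is accepted: the loop aims for a minimal
feature set while not decreasing performance, and a tie at smaller depth is
progress toward minimality.

**Preferential attachment with a unit zero-appeal.** The benchmark graphs
are grown one edge per arriving node with attachment probability
proportional to `degree^power + 1`. The additive term follows the igraph
generator convention; with the superlinear power 1.2 used throughout, the
bare power law condenses most edges onto a single hub, and a planted
module of a hub plus three of its ~20 leaves is essentially unreachable by
bounded random walks (each hub-to-leaf step picks the right leaf with
probability ~1/20, three times in a row). The tempered generator matches
what one gets from standard tooling and keeps the benchmark solvable — the
parameter is exposed (`zero_appeal`) for anyone wanting the bare law.

**Degenerate OOB sets.** If an OOB draw contains a single class, AUC is
undefined; the record scores chance level 0.5 (logged when
`options(gdforest.verbose = TRUE)`).

**Tie-breaking in trees.** Equal-gain splits resolve to the
lexicographically first (node, modality) and the smallest threshold, making
fitting deterministic; all other randomness flows from one seed through R's
RNG stream.

**SHAP conditioning.** Attributions are path-dependent (cover-weighted)
TreeSHAP; the baseline is the cover-weighted expected prediction, i.e. the
mean prediction over each tree's in-bag training samples, which makes
`prediction = baseline + sum(attributions)` exact to machine precision.
Forest attributions are means of per-tree attributions (valid by linearity
of the Shapley value in the model). Interaction values are computed exactly
by subset enumeration under the same conditioning, which is exponential in
the tree's feature count — acceptable precisely because the greedy loop
makes trees small; the implementation refuses trees above `max_features`
(default 15). Like all SHAP variants, correlated features may split credit
that is jointly additive; the network-restricted feature sets mitigate but
do not remove this.

## What the synthetic generator does and does not emulate

The generator plants a connected 4-node module (collected by random-walk
accretion, so stars and paths both occur) on a scale-free tree of 30–50
nodes, draws independent Bernoulli(0.5) features per node — and per
modality in the cross-modal layout — for 1000 samples, and labels samples
by `(x1 & x2) XOR/OR/AND (x3 & x4)`; the cross-modal layout reads modality
a of the 1st/3rd planted nodes and modality b of the 2nd/4th. XOR label
prevalence is exactly 6/16 in expectation (truth-table enumeration), so
classes are approximately balanced.

This emulates the *logical* difficulty of module detection: marginally
weak, jointly decisive features placed on a known graph. It does not
emulate real multi-omics data in several ways: features are binary and
independent outside the module (no correlation structure, no batch
effects), the graph is a tree (real interaction networks have cycles and
confidence-weighted edges), labels are noise-free functions of the module,
and sample sizes are generous relative to dimensionality. A green
benchmark therefore establishes that the search-and-ranking machinery
works as specified — not that modules of comparable subtlety are
recoverable from noisy, correlated clinical data.

## Numerical choices

* AUC is the Mann–Whitney concordance with ties counted 0.5 (rank-based,
  exact).
* Tree gain tallies store in-bag-fraction-weighted Gini gains, so a tree's
  tally sums to its total impurity decrease (conservation is tested).
* Acceptance comparisons use `>=` on doubles; no tolerance is injected.
* Equality of SHAP implementations against the exhaustive oracle is
  asserted at 1e-6; additivity at 1e-6.
* Stratified splitting uses `round(fraction * n_class)` clamped so both
  sides keep at least one sample per class.

## Known limitations

* No stopping criterion: `niter` must be chosen by the user (the unique-
  module count and the OOB curve are reported per iteration to help).
* Single-threaded by design; a fixed worker count keeps seeded runs
  bit-reproducible.
* Binary outcomes only; survival times are out of scope.
* Edge confidences are carried as metadata and used for filtering on load,
  but walks are unweighted.
* The interaction explainer is exponential in tree feature count and meant
  for the small trees this method produces, not for arbitrary forests.
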