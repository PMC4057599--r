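---
title: "Gateway nodes in two-state co-expression networks: model and methods"
author: "gatewaynet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gateway nodes in two-state co-expression networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatewaynet)
```

# The model

`gatewaynet` analyses one expression matrix per biological state (two
states), typically RMA-normalised log2 microarray intensities with probes
in rows. The analysis has four layers.

**Correlation networks.** Within each state, every probe pair is scored
by the sample Pearson coefficient; an edge is kept when ρ ≥ `rhoMin`
(default 0.85) and the two-sided p-value of t = ρ√((n−2)/(1−ρ²)) on n−2
degrees of freedom is below `pMax` (default 0.005). The default band
0.85 ≤ ρ ≤ 1.00 means every retained edge explains at least
ρ² = 72.25% of one partner's variance; a common softer convention is
|ρ| ≥ 0.70 (at least 49%), available by lowering `rhoMin` and setting
`signMode = "absolute"`. The default is positive-only because the target
band is literally 0.85 to 1.00; strong anticorrelations are excluded
there by design. No multiple-testing correction is applied at this stage
— the hard ρ threshold is the dominant filter and the p-value acts as a
small-sample guard. Probes are kept verbatim, including redundant probes
for one gene; zero-variance probes are skipped pairwise with a warning.
The all-pairs computation holds a probe-by-probe correlation matrix, so
memory grows quadratically in the probe count.

**Dense clusters.** Clusters are found by a reimplementation of the
MCODE vertex-weighting procedure: each node is weighted by the k-core
number of the densest core of its closed neighbourhood times that core's
density (0 below the degree cutoff); complexes grow greedily from unseen
seeds in descending weight, admitting neighbours within
`1 − nodeScoreCutoff` (default 0.8×) of the seed weight; complexes are
haircut to their 2-core and discarded unless they contain a `kCore`-core.
The defaults (degree cutoff 4, k-core 4, score cutoff 0.2, haircut on,
fluff off) make 5 nodes the minimum reportable cluster and exclude
triangles categorically. Equal weights are broken lexicographically by
node name, so results are deterministic and independent of storage
order. Clusters are then screened by density 2e/(k(k−1)) at 65%, 75% and
85% — increasing screens give nested cluster sets, and downstream gateway
sets shrink accordingly.

A property of this algorithm family worth knowing: two 5-cliques joined
by a single bridge edge form a single maximal 4-core (every node keeps
degree ≥ 4), and because all node weights tie, growth crosses the bridge
and reports one 10-node complex rather than two cliques. This is the
documented tendency of MCODE-style clustering to over-predict cluster
size; the density screen removes such merged, sparse complexes (the
example's density is 21/45 ≈ 0.47 < 0.65). Disjoint cliques are always
recovered exactly.

**The integrated graph and gatewayness.** Retained clusters of both
states are merged into G′ = (V, E₁ ∪ E₂); each edge is labelled with the
state(s) containing it. For every cross-state cluster pair (X, Y) the
gateway set is S = V(X) ∩ V(Y), accepted when nonempty and
|S| ≤ min(|V(X)|, |V(Y)|)/2. We read the size restriction as ≤ (not
strictly less than) half, following the inequality form of the rule; the
restriction exists to keep S small relative to the clusters and to
exclude the degenerate V(X) = V(Y) = S case, and the ≤ reading preserves
both purposes while admitting boundary cases such as |S| = 2 with a
4-node cluster. Each s ∈ S is scored
e(s) / Σ_{s′∈S} e(s′), where e(s) counts integrated-graph edges from s
to (V(X) ∪ V(Y)) \\ S; edges between two gateways are excluded because
they do not connect cluster interior to gateway. The denominator is the
sum of the per-gateway counts — the only convention under which a sole
gateway scores exactly 1.00, which we treat as the metric's defining
identity. Scores over S sum to 1, S is a vertex cut separating X-only
from Y-only nodes, and the metric is invariant under node relabelling;
all three are enforced by tests. A node appearing in several qualifying
cluster pairs gets one record per pair; the wide per-node table reports
its maximum per threshold. Gateways all of whose edges run to other
gateways (e(s) = 0) are reported with score 0 rather than dropped, which
keeps the sum-to-1 identity intact.

**Null models and significance.** Two null families are provided,
matched to the real networks' size: Erdős–Rényi G(n, p) pairs (default
n = 12300, p = 10/10000) and static power-law scale-free pairs (default
exponent 2.5, edge count matched to a real network). Null pairs share a
node set. Under the null convention, density screening is disabled, and
when clustering finds nothing — the expected outcome for G(n, p) at
these settings — each network's full node set becomes one whole-network
cluster with the half-size restriction suspended. Then S = V and there
are no non-gateway nodes, so e(s) as defined would be identically zero;
our convention suspends the gateway–gateway exclusion in exactly this
degenerate case, making e(s) the node's degree in the integrated graph.
Every shared node is then a gateway (12,300 of 12,300 for the default
ER pair) and the null gatewayness is the degree share — tightly
concentrated around 1/n for ER graphs, i.e. near-uniform. The exact
shape of this null is our convention; the gateway *count* does not
depend on it. Observed-versus-null comparison uses the classical
pooled-variance two-sided t-test (two constant equal samples give p = 1),
reported with the conventional markers *** (p < 0.0005) and * (p < 0.05).

# Annotation layers

**Lethality enrichment.** Genes are flagged essential when any phenotype
row in an MGI-style report contains the substring "lethality",
case-insensitive — deliberately generous, catching "embryonic lethality",
"preweaning lethality", etc. Which report columns hold the symbol and
the phenotype text varies by report version, so both indices are
configurable (defaults 7 and 11). Enrichment of a gene set is
log₂((b/n)/(B/N)) with a hypergeometric tail p-value in the observed
direction; b = 0 reports −Inf with a valid p. Per-term enrichment uses
the same machinery over a gene→term table with **no multiple-testing
correction** — this mirrors simple uncorrected set enrichment at
p < 0.05 and is validated by a null-fixture test expecting ≈ 5% false
positive terms; users wanting corrected lists should adjust the returned
p-values themselves.

**Ontology edge annotation.** The ontology is built from OBO `is_a`
links only by default (`part_of` behind a flag, off because mixing
relation semantics changes depths silently); obsolete terms are dropped
and cycles are fatal. For an edge (u, v), among all common ancestors of
the two endpoints' term sets the *deepest common parent* is the ancestor
maximising score = depth − breadth, where depth is the longest
root-to-term path (the usual term-depth convention; shortest-path depth
available via `depthMode`) and breadth is the sum over the two endpoints
of the minimum hop count from the endpoint's terms up to the ancestor.
Sum rather than maximum is the default because it penalises *total*
annotation distance, keeping the score an additive depth-minus-hops
quantity; `breadthMode = "max"` is provided. Maximising the final score
(rather than raw depth) makes the reported score the best achievable for
the edge; ties break toward the deeper term, then lexicographic id.
Edges with an unannotated endpoint or no common ancestor are dropped,
not scored. Per gateway, the mean of incident annotated-edge scores
(which can be negative — shallow, distant ancestors) ranks functional
candidates, alongside the annotated degree.

# The synthetic-data generator

`plantedDesign()` / `generateTwoState()` emulate exactly the structure
the method assumes: per-state dense co-expression modules sharing a few
designated genes. Each module's members are one standard-normal latent
signal plus independent Gaussian noise; the signal amplitude is set from
the variance-ratio identity r = σ²ₛ/(σ²ₛ + σ²ₙ), so the expected pairwise
correlation of module members is `withinModuleR` exactly, and a
Monte-Carlo test confirms the calibration (mean realised r within 0.03
of target at n = 100). Gateway genes load on their host module's signal
in each state; background genes are pure noise; per-gene baselines are
uniform on [6, 12] to mimic RMA log2 intensity locations (baselines are
constant per gene and do not affect correlations). With `noiseSd = 0`
members are pure signal (r = 1); requesting r = 1 with positive noise is
rejected as infeasible.

Defaults, chosen once as a realistic tight-module condition: two modules
of 10 genes per state, one gateway between the first module pair, 30
samples per state (a mid-sized microarray cohort), target r = 0.95 —
comfortably above the 0.85 edge threshold, as befits genes sharing a
latent regulator — noise sd 1, 50 background genes. Under these
conditions the full pipeline recovers exactly the planted gateways with
gatewayness 1.00 and keeps background genes out of every cluster in at
least 95% of seeds (tested over 20 seeds).

What the generator does *not* emulate: probe-level artifacts, batch
effects, heavy-tailed expression, correlated background structure, or
modules of heterogeneous internal correlation. Passing tests on planted
data therefore demonstrate algorithmic correctness, not robustness to
real microarray noise; on real data, cluster boundaries (and hence
gateway counts) are sensitive to the clusterer's exact scoring, and a
different MCODE implementation may draw different boundaries.

# Numerical and design notes

- Edge filters use strict inequality for the p-value (keep iff
  p < `pMax`) and ≥ for the correlation threshold; |ρ| = 1 returns
  p = 0 exactly.
- All graph containers are named `igraph` objects inside S4 classes;
  determinism everywhere comes from lexicographic tie-breaks, never from
  storage order. SIF export sorts endpoints within and across lines.
- The pipeline driver expands one master seed deterministically per
  stage, and its outputs are byte-identical across reruns; the simulated
  nulls take mandatory seeds.
- Degenerate inputs: single-probe matrices give an edgeless network with
  a warning; a gateway pair with no cross edges at all is dropped with a
  warning; an empty network yields no clusters.
- Problem sizes used in the shipped tests are desk-scale (tens to
  hundreds of genes, 12,300-node null graphs), chosen so the full suite
  exercises every stage, including the genome-scale null, in about a
  minute.

# Known limitations

- Exactly two states; multi-state generalisation would need a different
  gateway-set definition.
- The all-pairs correlation step is dense; ~40,000 probes imply ~8×10⁸
  pairs and a correspondingly large correlation matrix — genome-scale
  runs need either chunking (not implemented) or substantial memory.
- The clusterer follows the published MCODE description; other
  implementations' boundary cases (and hence downstream gateway counts
  on real data) can differ legitimately.
- Term enrichment is deliberately uncorrected; lethality matching is a
  substring heuristic over free-text phenotype descriptions.
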