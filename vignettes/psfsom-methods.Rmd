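---
title: "Pathway signal flow portraits: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway signal flow portraits: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psfsom)
```

## The problem

Case/control transcriptome cohorts for related diseases are usually
analysed gene by gene, which obscures the coordinated behaviour of
signaling cascades. `psfsom` takes the opposite, topology-centred view:
gene-level fold changes are propagated through signed pathway graphs
(activation and inhibition edges) down to the pathways' *sink* nodes —
the endpoints of pathway branches, each associated with a downstream
biological outcome. The resulting branch activities are summarized on a
self-organizing map (SOM), co-regulated regions are detected as *spots*,
and diseases are compared and clustered by the spots they share.

## Pathway model

A pathway is a directed graph of gene-group nodes. Edges are classified
only as activation or inhibition. Input nodes (in-degree 0) inject the
measured signal; sink nodes (out-degree 0) report it. The *branch* of a
sink is its reverse-reachability set; branches of one pathway overlap.

Real pathway maps contain feedback loops, but propagation needs an
evaluable order, so cycles are resolved first: a depth-first search from
the canonically sorted input nodes removes every edge that closes a
cycle on the DFS stack. The procedure is deterministic (neighbours are
visited in sorted order), idempotent, only ever removes edges, and
preserves input-to-sink reachability along forward paths. Graphs in
which *every* node lies on a cycle have no defensible entry point and
are rejected with instructions to designate one.

KGML input: entries of type `gene`, `group` (flattened to one node, gene
sets unioned over components) and `compound` (gene-less relay nodes that
pass signal through unchanged) are retained; `map` and other cross-links
are dropped. Relation subtypes map onto the two signs — activation and
expression (also in combination with phosphorylation) to activation;
inhibition and repression (also with dephosphorylation) to inhibition.
Subtypes with no inherent direction (binding/association, indirect
effect) default to activation, since a documented physical interaction
more often transmits than blocks signal; a switch drops them instead.

## Fold changes

Expression input is a gene-by-sample matrix on the log2 scale (the
native scale of RMA output; a flag declares linear-scale input, which is
floored at 1 and log2-transformed first). Probe-level matrices are
collapsed by arithmetic per-gene averaging. The within-dataset control
mean is the reference: `FC(g, s) = 2^(x(g,s) − mean(x(g, controls)))`,
reported per case sample on the linear scale. Because every dataset is
referenced to its own controls, dataset-specific baselines (platform,
lab) cancel; this is what makes multi-cohort comparison possible without
explicit batch correction.

## Signal propagation

Each node aggregates the fold changes of its measured member genes by
geometric mean — fold changes are ratios, and the geometric mean treats
a doubling and a halving symmetrically, so a node with member FCs {2,
0.5} is neutral. Unmeasured genes and gene-less nodes get the neutral
value 1 (no evidence of change). Nodes are then updated in topological
order: an input node's signal is its own value; any other node `v`
computes `S(v) = E(v) · A(v)`, where `A(v)` averages the parent
contributions `S(u)` (activation edge) or `1/S(u)` (inhibition edge).
This is the simplest multiplicative rule with the required qualitative
behaviour: a larger source signal raises an activated target and lowers
an inhibited one, and a neutral fold-change field propagates to sink
values of exactly 1. Both aggregation rules are configurable
(`gene_agg`: geometric/arithmetic; `agg`: mean/sum/product), because the
field uses several variants; the defaults above are the package's
choice, not a claim about any one reference implementation.

Two exact invariants are worth noting. Neutrality (`FC ≡ 1 ⇒ PSF ≡ 1`)
holds for every aggregation rule. Scale duality (replacing every node
value `E` by `1/E` on an all-activation graph maps every sink value `S`
to `1/S`) holds exactly under product aggregation and on single-parent
topologies, but *not* under arithmetic parent averaging at multi-parent
nodes, where the mean of reciprocals exceeds the reciprocal of the mean;
the tests exercise it where it is exact.

## SOM portraits

Sink-by-sample activities are log2-transformed (0 = unchanged, up and
down symmetric — the diverging colour scale of the portraits assumes
this) and fed to a classic online Kohonen SOM. Training runs in two
phases: an ordering phase whose Gaussian neighbourhood radius decays
linearly from `max(rows, cols)/2` to 1 while the learning rate decays
0.1 → 0.01, then a fine-tuning phase at radius 1 with rate 0.01 → 0.001.
Each phase presents every sink `epochs` (default 10) times in seeded
random order; unit weights are initialized from randomly drawn sink
profiles with slight jitter. The seed is a mandatory parameter: SOM
solutions are equivalent up to rotation/reflection, and downstream spot
labels are only reproducible for a fixed seed. No per-sink centering is
applied — activities are already relative to controls.

The default grid is 35×35, appropriate for collections on the order of
a couple of thousand sinks; for the 20-pathway synthetic benchmark
(~70 sinks) the pipeline uses 16×16 so that the unit count stays within
a small factor of the sink count.

A *portrait* maps one sample (or a disease, by element-wise averaging of
its case samples) onto the grid: unit value = mean log2 activity of the
sinks assigned to that unit. Units with no assigned sinks are filled by
nearest-neighbour interpolation and flagged `interpolated`; the
sink-weighted mean over the genuine units reproduces the sample's
overall mean activity exactly (conservation), which the tests assert.

## Spot detection and calls

The global summary map is the element-wise maximum of the disease
portraits on the up side and the minimum on the down side — a max/min
rather than a mean, so that a spot present in a single disease survives
summarization. The up-threshold is the `percentile`-th percentile
(default 98) of summary-up values, the down-threshold the symmetric
percentile of summary-down values. Threshold-passing units are grouped
into 8-connected components; components of at least `min_size` (default
3) units become spots, labelled `A`, `B`, … by decreasing size (ties:
up before down, then lowest unit index, making labels deterministic).
Interpolated units participate by default (`include_interpolated =
TRUE`) — they carry their nearest occupied unit's value and keep
sparsely tiled regions contiguous; the switch exists because on very
sparse grids they can also bridge genuinely distinct regions.

One refinement beyond plain connected components is on by default
(`split_profiles`). A spot is meant to be a cluster of *co-regulated*
units, but the max/min summary map is blind to *which* diseases drive a
unit: two abutting regions that are extreme in different disease
subsets form one plateau with no valley between them, and connected
components alone merge them. Each thresholded unit is therefore
profiled by the set of diseases that push it past half the detection
threshold, and every component is re-partitioned into 8-connected runs
of equal profile before size filtering. When all units of a component
agree (the typical case for an isolated blob), the refinement is a
no-op; with `split_profiles = FALSE` detection reduces to pure
thresholded components.

A spot is called in a disease by the mean portrait value over its units:
above `+call_threshold` (default 0.25 log2 units, i.e. about a 19%
activity change) gives `+`, below the negative threshold `−`, else `0`.

## Disease similarity and communities

Two diseases share a spot when both call it with the same nonzero sign
(a `+/+` or `−/−` match; sign-blind counting is available but the
default is sign-aware, since up- and down-regulation of the same region
are biologically opposite statements). Each disease is connected to
every disease achieving its maximal shared-spot count — ties create
parallel edges, and merged edge multiplicities become edge weights.
Communities are found by the walktrap random-walk algorithm (walk length
4) cut at maximal modularity.

## Enrichment

Spot gene sets (union of member genes of the sinks assigned to a spot's
units) are tested against any GMT collection by the hypergeometric upper
tail, with Benjamini–Hochberg correction, a minimum category size of 5,
and significance at adjusted p < 0.05. The default universe is the union
of all genes in the pathway collection — the population the query was
drawn from; all measured genes can be supplied instead.

## The synthetic benchmark

The generator emulates a multi-cohort case/control compendium with
planted structure, not any particular microarray platform:

* 20 random pathway DAGs (12 nodes, 3 unique genes per node, edge
  probability 0.25 between topologically ordered pairs, 20% inhibition
  edges) — sizes in the range of typical signaling maps while keeping
  the full benchmark fast;
* 12 diseases in two groups of 6, each dataset with 15 cases and 15
  controls — sample counts typical of public case/control series;
* 4 pathways planted up-regulated in *all* diseases (the shared
  inflammatory component), 4 per group (group-specific dysregulation),
  8 null;
* effects of +1.0 log2 unit applied at the *gene* level (so probe→node
  aggregation is genuinely exercised), i.i.d. Normal(0, 0.3) log2 noise,
  and dataset-specific Normal(8, 1) gene baselines that emulate
  cross-platform heterogeneity and must be removed by the
  control-relative design.

What passing on this benchmark does *not* show: robustness to probe-level
artefacts, batch effects within a dataset, partially overlapping gene
panels across platforms, correlated noise, or pathway annotation errors —
real compendia have all of these.

For this benchmark the pipeline runs with grid 16×16, detection
percentile 75, `min_size` 3 and call threshold 0.25. The percentile is
far below the 35×35 default because the planted signal is dense: roughly
60% of sinks belong to perturbed pathways, against a few percent of
extreme meta-sinks on a real 1825-sink map; neighbouring settings (the
same grid at percentile 70, or 12×12 at 70–80) behave similarly.

## Numerical and degenerate-input choices

* Fold changes must be strictly positive and finite; linear input is
  floored at 1 before logging.
* An isolated node is both input and sink; its branch is itself.
* Empty spot maps are valid results, not errors; a disease sharing no
  spot with any other stays isolated with a warning.
* Quantile thresholds use R's default (type 7) interpolation, whose
  reversal symmetry makes spot detection exactly sign-symmetric:
  negating all portraits swaps up- and down-spots.
* All randomness (SOM initialization and presentation order, synthetic
  generation) flows from explicit integer seeds through localized RNG
  scopes, so library users' RNG state is never disturbed.

## Problem sizes exercised by the tests

The automated checks run at sizes chosen to probe each property without
redundancy: exact propagation against an independent recursive
evaluator on 100 random DAGs of up to 10 nodes; monotonicity and
inhibition reversal on 50 random chains; spot recovery on 100 planted
2–5-blob summary maps (35×35, amplitude 1.0, noise 0.1); and the full
pipeline — community recovery and the shared-versus-group spot property
— on 20 independent benchmark realizations. A percentile threshold
always marks a fixed fraction of units, so on the benchmark's quiet
down side the permissive 75th percentile also surfaces weak components;
the per-disease calls (threshold 0.25) screen these, and they do not
affect the community structure.

## Known limitations

* Cycle resolution by DFS back-edge removal is one deterministic choice
  among many valid ones; branch memberships downstream of a removed
  feedback edge depend on it.
* The propagation rule is a modelling choice: only its qualitative
  contract (activation raises, inhibition lowers, neutrality) is
  field-standard; absolute sink values are not comparable across
  different aggregation settings.
* Online SOM training is O(units × samples) per presentation in plain R;
  maps beyond ~40×40 with hundreds of samples get slow.
* Spot labels depend on the SOM seed; only spot *contents* and the
  downstream similarity structure are scientifically meaningful.
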