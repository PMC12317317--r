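---
title: "Graphlets and orbits in mixed regulatory/physical networks: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graphlets and orbits in mixed regulatory/physical networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpigraphlets)
```

This vignette documents the model implemented by `rpigraphlets`, the
conventions and numerical choices it fixes, what the synthetic-data
generator does and does not emulate, and the known limitations.  It
states no empirical result that the test suite or the acceptance script
does not itself compute.

## The multilabel RPI graph

The input is two relations over a common protein/gene namespace:
unordered physical interaction pairs and ordered regulatory
(regulator → target) pairs.  Their union is a multigraph; we collapse
it so every node pair carries exactly one labelled edge from a
five-type alphabet — `P` (physical only), `R` (one regulatory
direction), `PR` (physical plus one regulatory direction), `B` (mutual
regulation), `PB` (physical plus mutual regulation).  The collapse is
lossless: expanding the typed edges reproduces the deduplicated input
records, which the test suite asserts on random inputs.

Each edge end carries an *edge orbit* label in 1..7 determined by the
type; 0 marks a non-edge.  Two of these labels have fixed meaning —
orbit 4 is "physical edge plus outgoing regulatory edge" and orbit 5
its incoming counterpart — while the remaining integer assignments
(`P` → 1, `R` → 2/3 with 2 on the regulator, `B` → 6, `PB` → 7) are a
catalog convention of this package.  All downstream counts are
invariant to that convention; only the integer names of orbits would
change under a different assignment.

**Degenerate inputs.** Self-regulation records (A → A) are dropped at
ingest with a warning and a tally, because graphlets are induced
subgraphs on *distinct* nodes and a self-loop can participate in none.
Identifiers are whitespace-stripped but otherwise taken verbatim
(case-sensitive): silent identifier merging is worse than occasional
duplication.  Empty input files are an error rather than an empty
network, since they almost always indicate a wrong path.

## The graphlet catalog and its two encodings

Over the RPI alphabet there are 5 two-node graphlets (the edge types,
7 orbits) and 98 three-node graphlets (28 lines, 70 triangles; 259
orbits; 83 mixed).  `enumerate_catalog()` derives all of these numbers
at run time by brute force over the 8³ = 512 assignments of pair
states to the three node pairs of a triple — nothing is hard-coded
except the alphabet itself — and the acceptance suite compares them to
their reference values.

Two independent encodings are maintained:

* the **canonical form**: the minimum over all 6 node permutations of
  a fixed serialization of the typed, oriented adjacency.  Equality of
  canonical forms is by construction equivalent to edge-type-preserving
  isomorphism.  This is slow and used as the oracle.
* the **sorted-pair key**: each node's two endpoint codes sorted
  ascending, the three pairs then sorted lexicographically.  This is
  cheap and used for counting.

The key discards which neighbour each half-edge points to, so its
injectivity over the alphabet is not obvious.  Enumeration therefore
*proves* the bijection exhaustively: every labelled connected triple
must map to exactly one key per canonical class and distinct classes
must have distinct keys, else `enumerate_catalog()` aborts with an
internal-consistency error.  The same holds for the orbit shortcut:
counting assigns a node its orbit from its sorted pair alone, which is
only valid if, within every graphlet, the partition of positions by
sorted pair coincides with the automorphism partition.  This is
checked per graphlet at enumeration time.  If a future edge alphabet
broke either property the canonical form would remain authoritative
and the checks would fail loudly rather than miscount.

**Numbering.** Graphlet ids `G1..G98` follow lexicographic order of
the key; orbit ids are global integers, 1–7 for the two-node orbits and
8–266 grouped by graphlet.  Published analyses in this area use their
own `G`/`O` numberings defined by supplementary figures; no attempt is
made to reproduce any external numbering, and the key string — which is
convention-free — is exported alongside every id as the portable
identifier.

## Counting

Connected triples are enumerated center-first: for every node `c` and
every pair `x < y` of its neighbours, `{c, x, y}` is connected; a path
has a unique center and is emitted once, a triangle is kept only when
`c` is the smallest index.  This is `O(Σ_c deg(c)²)`, which on the
sparse networks this package targets is far below the `C(n,3)`
all-triples scan; per-triple work is fully vectorised.  After every
count two conservation identities are asserted: 3-node counts sum to
the number of connected triples, and each orbit's column sum equals its
class size times its graphlet's count.  The test suite additionally
requires exact equality, on seeded random graphs, with an independent
all-triples oracle that classifies triples by canonical form and
assigns orbits through an explicit isomorphism search.

## The switch-randomization null

The graphlet test asks whether a graphlet is more frequent than
expected in networks with the same degree structure.  Replicates are
produced by repeated *switches*: two same-type edges `(a,b)` and
`(c,d)` with four distinct incident nodes are rewired to `(a,d),(c,b)`
(orientation-preserving for `R`/`PR`; for symmetric types one of the
two re-pairings is chosen at random), rejected when the new pair would
be a self-loop or is already occupied by any edge.  This preserves
every node's per-type, per-orientation degree exactly — asserted for
every replicate in the acceptance suite.

Because the exact switch condition used by published implementations
lives in supplementary material that admits two readings, both scopes
are provided.  The default, `collapsed_type_layers`, swaps within each
of the five collapsed types and is the literal reading of "preserves
all degrees of all edge types".  The alternative, `raw_layers`, swaps
the underlying physical layer and the directed regulatory layer
separately and re-collapses; it preserves raw-layer degrees but may
change the collapsed type mix (e.g. a `PR` edge can dissolve into `P`
plus `R` elsewhere).

**Swap budget.** The reference protocol asks for "enough swaps to
saturate the number of new edges" without a number.  The default
budget is `swaps_per_edge = 10` attempts per layer edge, with the
fraction of rewired edges measured every `saturation_window = 100`
attempts and early stop when it changes by less than 0.001 between
windows; the trajectory is kept in `attr(x, "swap_diagnostics")`.

**Test conventions.** The exceedance rule is strict (`>`): a graphlet
is significant when strictly larger counts occur in fewer than
`ceil(alpha · n_replicates)` replicates — with 1000 replicates and
alpha 0.01, fewer than 10.  The orbit test below deliberately uses `≥`
because its reference wording says "equal to or larger"; both
directions are configurable.  No pseudo-count is added by default (the
fewer-than-10 arithmetic is exact); `(exceed+1)/(n+1)` is available as
an option.  Graphlets absent from the observed graph are reported but
flagged `zero_support` and never called significant — enrichment of an
absent pattern is vacuous.  Note also that 2-node graphlet counts are
invariant under the degree-preserving null (edge counts per type are
conserved), so their exceedance is always zero; significance calls are
meaningful for the 3-node rows.

## RWR seed subnetworks

Scores solve `s = (1 − α) T s + α r` with `r` uniform over the seeds
present in the graph and `T` the column-normalized transition matrix
over the traversal edge set; mass at dangling nodes is redirected to
`r`, so `s` stays a probability distribution.  α is implemented
exactly as the reference protocol prints it — *restart probability
0.85* — even though many RWR conventions would call 0.15 the restart;
it is a configuration field, not a constant, so either reading costs
one argument.  With α = 0.85 the iteration contracts by 0.15 per step
and converges to 1e-10 in about a dozen iterations.

Traversal defaults to `symmetric` (every labelled edge walkable both
ways): the purpose of the walk is proximity, and pathway subnetworks
should be able to include the upstream regulators of seed targets,
which a strictly forward walk can never reach.  A `directed_forward`
mode (physical edges both ways, regulatory edges only regulator →
target) is provided for sensitivity analysis.

Extraction ranks nodes by descending score with lexicographic
tie-break (so the prefix is reproducible), and returns the induced
subgraph on the smallest prefix containing
`ceil(coverage · n_present_seeds)` seeds, coverage defaulting to 0.8.
Zero-score nodes are ineligible; seeds listed but absent from the
graph are excluded from both the restart vector and the coverage
denominator.

## The median-sampling orbit test

For a query protein set, each orbit's observed statistic is the
*median* count over the query rows of the node × orbit matrix, compared
against medians of `n_samples` node sets of the same size drawn
uniformly *without replacement from all network nodes* — the reference
wording states no exclusion of the query set, and including it is also
the conservative choice (the null can only get closer to the observed
set).  The median of an even-sized set is the mean of the two central
values, applied identically to observed and null medians.  An orbit is
significant when fewer than `alpha · n_samples` sample medians are
`≥` the observed median.  Member lists (query nodes with a nonzero
count at the orbit) can be exported per orbit, optionally restricted to
significant orbits of mixed graphlets, for use with external
annotation services; ontology enrichment itself is out of scope.

## The synthetic world

`generate_synthetic_network()` emulates the *shape* of curated species
interactomes at simulation scale: an Erdős–Rényi physical layer over
unordered pairs, an independent Erdős–Rényi regulatory layer over
ordered pairs, a reciprocation step (each regulatory edge made mutual
with probability `p_mutual`) so that `B`/`PB` edges occur, and an
optional uniformly drawn seed set standing in for a pathway gene list.
Defaults used across the test suite keep graphs sparse (physical
density a few percent, regulatory about half that, reciprocation
5–30 %), matching the regime where mixed edge types are rare but
present — in real interactomes the mixed 2-node types are well under
2 % of edges, and the generator reproduces that rarity.

What it does **not** emulate: scale-free degree tails, assortativity,
community structure, co-complex cliques, or any correlation between
regulation and physical binding.  A green test therefore establishes
algorithmic correctness (exact agreement with oracles, exact invariant
preservation, correct arithmetic) — not that biological networks
resemble the generator.

`plant_mixed_motifs()` adds disjoint copies of the mixed triangle in
which a regulator targets two physically interacting proteins — a
motif of known biological interest — on chosen nodes.  The
parameter-recovery acceptance test plants eight copies among seed
nodes of a sparse background and requires the planted graphlet's
empirical p from the switch null to be significant and below that of
non-planted graphlets of comparable observed count.  That test, and
only that test, scales the replicate count down to 200 (from the
reference 1000) to stay inside the test-time budget; the significance
arithmetic at 1000 is covered exactly by its own unit test on
constructed null vectors.

## Reproducibility and numerical choices

All stochastic procedures (generator, switch randomization, orbit
sampling) take explicit seeds and restore the caller's RNG state; the
CLI derives per-procedure streams deterministically from one global
`--seed`.  RWR convergence is L1 < 1e-10 (cap 1000 iterations); the
2-node closed form is matched to 1e-8 in tests.  Ranking ties break
lexicographically everywhere a prefix or export order matters, so
repeated runs are byte-identical.

## Limitations

* Graphlets of 4+ nodes are out of scope; the encoding's bijectivity
  proof is specific to 3 nodes and the enumeration would not scale
  unchanged.
* The counter stores the endpoint-code matrix densely; it is intended
  for pathway-scale and simulation-scale graphs (up to a few thousand
  nodes), not for full mammalian interactomes.
* Empirical p-values are lower-bounded by `1/n_replicates`; with the
  default 1000 replicates the smallest reportable p is 0.001 and
  multiple-testing control across 98 graphlets or 266 orbits is left
  to the caller.
* The switch null preserves degrees but not higher-order structure;
  graphlets correlated with degree alone will not appear enriched,
  which is the intended contrast, but graphlets induced by community
  structure may.
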