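---
title: "Deciding supertree compatibility and agreement via display-graph cuts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciding supertree compatibility and agreement via display-graph cuts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(supercut)
```

## The objects

A *profile* is an ordered collection of unrooted phylogenetic trees
`T1, ..., Tk` whose leaves are bijectively labelled; label sets may overlap
arbitrarily.  All trees are unweighted topologies: branch lengths and
internal node labels in Newick input are parsed and discarded, a modelling
choice, since both decision problems depend only on topology.  Trees may be
multifurcating throughout; no binary restriction is assumed anywhere.
Degenerate trees with one or two leaves are admitted (they constrain
nothing, but arise under restriction).

The *display graph* `G(P)` is the union of the input trees with equal-label
leaves identified; internal vertices of different trees are kept disjoint by
namespacing their ids per input index.  The *edge label intersection graph*
`LG(P)` is its line graph.  A supertree `S` *displays* `Ti` when
`Σ(Ti) ⊆ Σ(S|L(Ti))` and *agrees* with it when the two split sets are equal.

## The characterizations and the decision procedure

The package decides both questions through minimal cuts of `G(P)`:

* compatibility holds iff `G(P)` has a complete set of pairwise parallel
  legal minimal cuts;
* an agreement supertree exists iff such a set exists with at most one edge
  of each input tree per cut.

These are existence statements, not algorithms.  The decision procedure this
package contributes is an exact search:

1. **Enumeration.**  All minimal cuts of the (connected) display graph are
   enumerated as boundaries `δ(S)` of vertex bipartitions whose two sides
   both induce connected subgraphs — a bijection for connected graphs.  The
   walk visits every connected vertex set containing a fixed root once,
   keeping those with connected complement.  This is exponential but exact,
   guarded by a vertex-count limit (default 18 vertices; raiseable to 25).
   Exactness is the point: a "no" from the decider is a proof, not a
   failure to find.
2. **Candidates.**  For each internal edge `e` of each input tree, the
   candidate cuts are the legal minimal cuts whose slice with that tree is
   exactly `{e}` — leaf edges count, so a cut containing `e` plus a leaf
   edge of the same tree is *not* a candidate for `e`.  (In the reference
   example this is visible: the cut `{{1,2},{1,c},{4,5}}` contains the
   internal edge `{1,2}` but also the leaf edge `{1,c}` of the same tree,
   so it covers only `{4,5}` solely.)
3. **Search.**  Backtracking assigns one candidate per internal edge,
   most-constrained edge first, pruning whenever a chosen pair of cuts is
   not parallel.  Parallelism results are memoised; the guard counts these
   checks (default 5,000,000) and an overrun yields a first-class
   `"unknown"` outcome, never a silent "no".
4. **Minimisation.**  A found set is thinned greedily, in canonical order,
   to one in which no proper subset is complete.  Minimally complete
   parallel legal sets consist of nice cuts only; the code asserts this
   rather than assuming it.
5. **Construction.**  Each certificate cut induces a split of the label
   universe (the leaves of the two components); the non-trivial induced
   splits plus all trivial splits are pairwise compatible and determine a
   unique tree, built by iterative star refinement ("tree popping").  The
   supertree is verified to display (or agree with) every input before it
   is returned; a failure here is reported as an internal-consistency error
   because the theory rules it out for valid certificates.

Verification is a separate code path from construction: the verifier
re-checks minimality definitionally (removal disconnects, no maximal proper
subset disconnects), re-derives components with igraph rather than the
package's own graph code, and checks parallelism in both directions.  Every
certificate the deciders emit passes it; the command-line `verify`
subcommand applies it to stored certificates.

### Parallelism and its symmetry

The parallel-cut definition is stated one-sidedly (removal of `F` leaves
the edges of `F'` in at most one component).  For minimal cuts it is
symmetric; the implementation computes one side and the test suite asserts
symmetry over enumerated cuts, so an asymmetric case would surface as a
test failure rather than being silently symmetrized.  For non-minimal cuts
parallelism is undefined and the predicate rejects them.

### Disconnected display graphs

The cut machinery requires a connected display graph.  `decide_*` partition
a disconnected profile into the sub-profiles its components induce, decide
each, and chain the component supertrees: one edge of each component tree
is subdivided and the subdividers are joined in a path (isolated single
labels become pendant leaves).  Each input's restriction is untouched by the
chaining, so display and agreement are preserved.  The recombination is the
package's own construction; only the reduction direction is classical.

## The cut function and edge splitting

For an agreement supertree `S`, the cut function `Ψ` maps each edge of `S`
to the set of input-tree edges for which it is the agreement edge; each
value is a cut of `G(P)`, minimal iff its removal leaves exactly two
components.  The splitting surgery (`split_edge_at`) re-attaches, for each
component of `G(P) − Ψ(e)` meeting the far side of `e`, the minimal
connecting subtree directly at the near endpoint; iterating it on a largest
non-minimal value (`normalize_ast`) terminates with all *internal*-edge
values minimal, which is exactly what the certificate extraction needs.

The loop deliberately does not touch leaf edges: the value of the leaf edge
of label `l` is always the set of display edges incident on `l`, so it is a
minimal cut precisely when `l` is not a cut vertex of `G(P)`.  That is a
property of the profile — no supertree surgery changes `G(P)` — so "make
every leaf-edge value minimal" is not in general achievable (two input
trees sharing only the label `l` are the smallest counterexample), while
nothing downstream consumes leaf-edge values.  The test suite pins this
boundary from both sides.

When both endpoints of a pivot edge qualify for splitting, the
lexicographically smaller endpoint is tried first; the choice is
documented, deterministic, and immaterial to the final predicate.

## From cuts to a legal triangulation

An ordered, minimally complete certificate converts into a legal
triangulation of `G(P)` without constructing a supertree: each cut `F`
yields a separator pair `(X_F, Y_F)` by three rules (sole-slice internal
edges not yet differentiated contribute their endpoints to opposite sides;
already-differentiated ones, and sole leaf edges, and multi-edge slices,
contribute a single vertex to both sides), plus the interpolation family
`O_F` that sweeps from `X_F` to `Y_F` one differentiated pair at a time.
Saturating the display graph on all these sets together with each leaf's
open neighbourhood produces a chordal graph in which no clique mixes an
internal display edge with another display edge (LT1) and no fill-in edge
touches a leaf (LT2) — verified, not assumed, on every call.

Two determinism choices close gaps the construction leaves open: the cut
order is canonical (cuts sorted by their sorted edge lists) where any fixed
order is admissible, and the minimisation pass scans that same order.  The
component playing the role of `A_F` is the one containing the smallest
vertex id.  The pair collection depends on the order and is not unique;
only the verified LT1/LT2/chordality outcome matters.

Chordality testing is maximum cardinality search with a fill-in check,
returning a chordless cycle of length ≥ 4 as witness on failure (shortest
path between the two non-adjacent neighbours avoiding the closed
neighbourhood of the failing vertex).  igraph's independent chordality test
serves as the oracle in tests, never as the implementation.  Clique trees
are maximum-weight spanning trees of the clique intersection graph, with
the coherence property verified before return.

## The synthetic generator

`random_profile()` emulates the regime the deciders are meant for: a true
binary supertree on `n_labels` (default labels `a`, `b`, ...), input trees
obtained by restricting it to random label subsets, then contracting each
internal edge independently with probability `contraction_prob`.

* `contraction_prob = 0` produces profiles whose inputs all agree with the
  generating tree — the parameter-recovery surface: the decider must return
  an agreement supertree whose restrictions match the truth's.
* `contraction_prob > 0` produces compatible-but-possibly-non-agreeing
  profiles (display is closed under contraction of inputs; agreement is
  not).
* `perturb = "swap"` exchanges two leaf labels in one input, the standard
  way to manufacture likely-incompatible profiles without changing any
  marginal tree shape.

Defaults in tests use 5–8 labels, 2–3 trees, subsets of 4–6 labels and
contraction 0–0.5 — the scale at which the brute-force oracles
(all `(2n−5)!!` binary topologies for compatibility; all multifurcating
topologies, as deduplicated contraction classes, for agreement) stay
exact and fast.  Random binary trees are drawn by sequential leaf
attachment at a uniformly chosen edge; this is not uniform over labelled
topologies and does not need to be.  All randomness flows through the
recipe seed and the caller's RNG state is restored afterwards; identical
recipes give byte-identical Newick output.

What the generator does not emulate: branch lengths, realistic birth–death
or coalescent shapes, estimation error inside input trees, or rogue taxa
placed adversarially.  Passing tests therefore certify the combinatorics of
the deciders, not robustness to phylogenetic inference noise — the inputs
here are taken as exact topological claims.

## Reference fixtures

`fig1_profile()` (compatible, no agreement supertree) is built from its
published edge list: first tree with internal path 1–2–3 carrying
{a,b,c}, {f}, {d,e}; second with internal path 4–5–6–7 carrying {a,b},
{c}, {d}, {f,g}.  Its four reference cuts and four induced splits are
re-verified at every construction; a mismatch raises a fixture error
demanding re-transcription rather than being patched.

The agreeing example (`fig2_profile()`) has no machine-readable reference
topology, so the fixture is a *synthetic reconstruction* constrained by its
printed three-cut certificate `{{1,2},{4,5}}`,
`{{1,2},{5,6}}`, `{{2,3},{6,d}}`: first tree as above; second tree with
internal path 4–5–6 carrying {a,b,c}, {g}, {d,f}.  The constructor verifies
every printed predicate (each cut nice, minimal, legal, ≤ 1 edge per tree;
the set parallel and complete; an agreement supertree exists).  The printed
cuts constrain but may not uniquely determine the drawn topology; the
reconstruction is the package's fixture, documented as such.

The exhaustive oracle sweep in the acceptance tests is defined as: all
unordered pairs of (multifurcating) topologies on a fixed 4-label and a
fixed 5-label set, plus every 5-label topology against every topology on
each 4-element subset, plus 200 seeded random ≤ 6-label profiles.  These
sizes keep the whole suite in minutes on one CPU while covering every
topology class the oracles can reach.

## Shape of the package

The exported surface is the module functions; `supercut()` is a thin
model-fit-style front end returning a classed object with `print`,
`summary` and `plot` methods, which is how an interactive user will meet
the package.  The classic fitting-function idiom only half-fits a decision
procedure — there are no coefficients, residuals or predictions — so those
methods are deliberately absent rather than forced.

## Limitations

* Exactness costs exponential time: the deciders are for desk-scale
  profiles (display graphs of ≤ ~18–25 vertices, i.e. roughly ≤ 12 labels
  across a handful of trees).  No fixed-parameter or heuristic mode is
  provided; whether the cut characterizations yield practical
  fixed-parameter algorithms is open.
* The triangulation→cut-set direction (recovering a certificate from a
  legal triangulation) is out of scope.
* Guards convert resource overruns into `"unknown"`; correctness claims
  attach only to completed searches.
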