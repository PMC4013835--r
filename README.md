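# supercut

Cut-based compatibility and agreement of unrooted phylogenetic trees.

## The problem

Phylogenetic studies routinely produce several unrooted trees whose leaf
label (taxon) sets overlap only partially.  Two classic questions about such
a *profile* `P = {T1, ..., Tk}` are:

- **Compatibility** — is there a supertree `S` on the union of all labels
  that *displays* every input, i.e. `Σ(Ti) ⊆ Σ(S|L(Ti))` for every `i`,
  where `Σ(T)` is the set of non-trivial splits (bipartitions of the label
  set induced by internal edges) and `S|Y` is the restriction of `S` to the
  labels `Y`?  Displaying allows a supertree to *refine* an input's
  polytomies.
- **Agreement** — is there a supertree that restricts to *exactly* every
  input, `Σ(Ti) = Σ(S|L(Ti))`?  Agreement treats every polytomy as a hard
  fact that must be reproduced.

Both problems are NP-complete for three or more unrooted trees.  This
package implements an exact, certificate-producing decision procedure for
desk-scale profiles, built on a characterization in terms of minimal edge
cuts of the **display graph** `G(P)` — the union of all input trees with
equal-label leaves identified.

## The characterizations

Call an edge set `F` of `G(P)` a *minimal cut* when removing it disconnects
the graph and no proper subset does (equivalently, exactly two components
remain and every edge of `F` joins them).  A cut is *legal* when, for each
input tree, its edges in the cut share a vertex, and *nice* when in addition
every component left behind keeps an edge.  Two minimal cuts are *parallel*
(non-crossing) when removal of one leaves the other inside a single
component.  A set of cuts is *complete* when every internal edge `e` of
every input tree is the **sole** edge of its tree in some member cut.

- `P` is **compatible** iff `G(P)` admits a complete set of pairwise
  parallel legal minimal cuts.
- `P` has an **agreement supertree** iff such a set exists in which every
  cut contains at most one edge per input tree.

Each nice minimal cut `F` induces a split `σ(F)` of the label universe (the
leaves of the two components).  The splits of a certificate are pairwise
compatible, and the unique tree they determine (splits-equivalence /
tree-popping) is the supertree.  The same cuts, viewed as vertices of the
**edge label intersection graph** `LG(P)` (the line graph of the display
graph), are exactly its legal minimal separators; the package also builds a
*legal triangulation* of `G(P)` directly from any ordered certificate, via
the separator pairs `(X_F, Y_F)` and their interpolation families.

Because the characterization is existential, the decider performs an exact
backtracking search: all minimal cuts are enumerated as connected vertex
bipartitions, candidates are attached to the internal edges they solely
cover, and the search assigns one candidate per edge (most constrained
first) pruning on pairwise parallelism.  Certificates are verified on an
independent code path before being returned.

## Worked example

The package ships the two worked example profiles as self-verifying
fixtures.  `fig1_profile()` is a pair of compatible—but not agreeing—trees
on labels `a..g`:

```r
library(supercut)
fit <- supercut(fig1_profile())          # criterion = "compatibility"
summary(fit)
#> supercut: 2 trees on 7 labels -- the profile HAS a compatible supertree
#>   supertree: (a,b,(c,((d,e),(f,g))));
#>   cut 1: 1--2  1--c  4--5
#>   cut 2: 1--2  2--3  6--7
#>   cut 3: 1--2  5--6
#>   cut 4: 2--3  5--6  6--7
#>   internal splits: a,b,c,d,e|f,g  a,b,c,f,g|d,e  a,b,c|d,e,f,g  a,b|c,d,e,f,g
#>   input (a,b,c,((d,e),f));: displayed=TRUE agrees=FALSE
#>   input (a,b,(c,(d,(f,g))));: displayed=TRUE agrees=TRUE

supercut(fig1_profile(), "agreement")
#> supercut: 2 trees on 7 labels -- the profile has NO agreement supertree

supercut(fig2_profile(), "agreement")
#> supercut: 2 trees on 7 labels -- the profile HAS an agreement supertree
#>   supertree: (a,b,c,(((d,e),f),g));
```

The four certificate cuts are edge sets of the display graph (vertices `1-3`
and `4-7` are the internal vertices of the first and second input); each is
a nice legal minimal cut, the set is pairwise parallel and complete, and the
four induced splits `ab|cdefg`, `abc|defg`, `abcfg|de`, `abcde|fg` assemble
into the supertree shown, which displays both inputs.  For the agreeing
profile the analogous three-cut certificate has at most one edge per tree in
every cut, and the supertree restricts to exactly both inputs.

`plot(fit)` draws the supertree (via ape).  Lower-level module functions —
`build_display_graph()`, `build_elig()`, `enumerate_minimal_cuts()`,
`classify_cut()`, `cuts_parallel()`, `cut_to_split()`,
`find_complete_parallel_cutset()`, `cut_function()`, `split_edge_at()`,
`cuts_to_triangulation()`, `verify_certificate()` — are all exported; see
the vignette in `vignettes/` for the method account.

## Command line

A thin CLI ships in `inst/scripts/supercut.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/supercut.R", package="supercut"))')" \
    compat --trees profile.nwk --certificate cert.json --supertree out.nwk
```

Subcommands `compat`, `agree`, `triangulate`, `verify`, `synth`; exit code 0
means yes/verified, 1 no/rejected, 2 unknown or error.

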