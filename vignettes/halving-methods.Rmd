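---
title: "Genome halving under the DCJ-indel model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome halving under the DCJ-indel model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcjhalving)
```

## The problem

A whole-genome duplication (WGD) doubles both the content and the adjacency
structure of a genome. Long after the event, the observable descendant has
been reshaped by rearrangements and by massive gene loss, and gene families
no longer come in tidy pairs. The genome halving problem asks: given a
present-day genome, reconstruct a *structurally doubled* (SD) ancestor — a
genome in which every marker and every adjacency is paired with exactly one
equivalent partner — that is as close as possible to the observation under a
rearrangement model.

`dcjhalving` solves this problem under the DCJ-indel model. The operations
are double-cut-and-join (DCJ) rearrangements, which cut at up to two
adjacencies or telomeres and rejoin the freed extremities (covering
inversions, translocations, fusions, fissions and excisions), and segmental
insertions and deletions. Scenarios are *restricted*: only singular markers
(those without a homolog under the chosen matching) may be deleted, and an
insertion may only supply the single missing homolog of a singular marker.
This restriction is what keeps indels honest — without it, deleting the
entire genome and inserting a doubled one would be optimal.

Two regimes are covered:

* **Resolved homology** (every family has at most two members): the distance
  has a closed form and is computed in near-linear time
  (`halving_distance()`), together with an optimal sorting scenario
  (`sort_halving()`).
* **Natural genomes** (arbitrary family sizes): the problem is NP-hard; the
  package formulates and solves a capping-free integer linear program
  (`build_halving_ilp()`, `solve_halving_ilp()`, `halve_natural()`) that
  searches over *maximum matchings* — pairings leaving at most one singular
  marker per family — for the one minimizing the resolved-case distance.

## The supernatural graph and its census

All computations run on the supernatural graph (SNG): vertices are marker
extremities (a tail and a head per marker), *adjacency edges* are the
genome's adjacencies, and *extremity edges* join equivalent extremities
(tail with tail, head with head, within a family). A matching keeps at most
one extremity edge per vertex, so the decomposed graph consists of simple
alternating paths and cycles.

Components are classified by their endpoints and by the parity of their
extremity-edge count. An endpoint is either a *telomere* (extremity without
an adjacency) or a *lava vertex* (extremity of a singular marker, carrying
no extremity edge); paths ending in two telomeres are *viaducts*, in a
telomere and a lava vertex *piers*, and in two lava vertices *pontoons*.
An isolated vertex that is both telomere and lava counts as one even pier
(this is what makes linear chromosomes of only singular markers cost
operations). Circular chromosomes consisting only of singular markers
(*circular singletons*) are stripped in preprocessing; each costs exactly
one deletion.

With `n` the number of matched pairs, `c°` the even cycles, `p_g|g` the odd
pontoons, `p_G°g`/`p_G|g` the even/odd piers and `p_G|G` the odd viaducts,
the restricted halving distance of a genome with `l` circular singletons is

```
d = l + n - c° + ceil((q + delta) / 2),
q = p_g|g + max(p_G°g, p_G|g) - p_G|G,
```

with `delta = 1` exactly when `p_g|g` is odd and the two pier counts are
equal. An SD genome has every adjacency doubled into an even 2-cycle and
every telomere paired into an odd viaduct, so `d = 0` if and only if the
genome is SD.

**The ceiling.** The half-sum `(q + delta)/2` is taken as a ceiling. The
census parity allows odd `q` (exactly when the number of odd cycles is
odd), where a literal half would be fractional; the ceiling always yields
an integer, reduces to the classical DCJ halving form
`n - c° - floor(p_G|G / 2)` when no singular markers exist, and is
confirmed against an independent brute-force search on the exhaustive set
of all genomes with up to four markers, several hundred canonical
instances (`tests/testthat/test-acceptance.R`).

```{r}
g <- new_genome(list(c("1", "2", "4", "3")), circular = TRUE)
h <- homology(list(c("1", "3"), c("2", "4")))
halving_distance(g, h)
```

## Sorting

`sort_halving()` emits a scenario of DCJs and singular-segment deletions
whose length equals the distance. Rather than mirroring a fixed step list,
it generates candidate operations from the component structure — circular
singleton deletions, even-cycle extraction (doubling one adjacency at a
time), merges and closures of lava path-ends, deletions of maximal singular
runs, pier cuts — and accepts a candidate only if the recomputed distance
drops by exactly one. An exhaustive fallback over all legal operations
guarantees totality; in practice the structured candidates always contain a
decreasing move. Correctness is therefore enforced by the post-condition
(scenario length = formula, final genome SD, verified by
`verify_scenario()`), not by step numbering; tie-breaks follow vertex order,
so scenarios are reproducible. Deletions are emitted as maximal contiguous
singular segments, one operation per segment. Insertions are never needed
to attain the bound, so emitted scenarios consist of DCJs and deletions
only; `verify_scenario()` nonetheless checks restricted-legal insertions so
externally produced scenarios can be validated too.

A candidate DCJ that would close a circular chromosome of only singular
markers is rejected by the distance check (the new circular singleton costs
its gain back) and the corresponding segment deletion takes its place —
reproducing the classical guard against creating circular singletons.

## The ILP for natural genomes

For arbitrary family sizes the package builds a mixed-integer program whose
size is linear in markers plus telomeres. One artificial *pseudo-cap*
vertex is attached to every telomere (indices below all regular vertices),
so every component contains an adjacency edge; no pairwise capping edges
are added, which keeps the model linear in the number of linear
chromosomes.

The main variable groups:

* `x_p` — one binary per candidate sibling pair of markers; activating a
  pair activates both its tail–tail and head–head extremity edges
  (consistency). Per marker, active pairs plus the deletion indicator `d_m`
  sum to one; per family, the `d_m` sum equals the family size mod 2
  (maximum matching).
* `y_v, z_v` — component labelling: `y` is constant over a component and at
  most the minimum vertex index; `z_v = 1` marks that minimum as the
  component's *reporting vertex*. Components containing a lava vertex force
  `y = 0` and so never obtain one.
* `a_v` — 0 at pseudo-caps, 1 at lava vertices, constant along a component
  except across an adjacency edge reporting a pier — and there it *must*
  flip. Every pier therefore forces exactly one pier report at its
  pseudo-cap edge. (Merely allowing the flip is not enough: a path ending
  in two telomeres could then pose as a pier at one end and an odd viaduct
  at the other, biasing the objective downward. Forcing the flip is the
  canonization adopted here.)
* `b_v` — parity: 0 at pseudo-caps and lava vertices, flips across every
  active extremity edge, equal across adjacency edges unless an odd type is
  reported there (then forced unequal). Odd components thus force exactly
  one odd report.
* `r^R_e` — per adjacency edge, report indicators for the six census
  classes (odd viaducts, even/odd piers, odd pontoons, even/odd cycles), at
  most one per edge. Negative or neutral classes (cycles, odd viaducts) may
  only be reported at a reporting vertex, so at most once per component and
  never in components with lava vertices; cycle reports are banned from
  pseudo-cap edges (no telomeres in cycles); viaduct and pier reports are
  restricted to pseudo-cap edges, pontoon reports to edges at lava
  vertices.
* `s_D` — one binary per circular chromosome, forced to 1 when all its
  markers are deleted (circular singleton, one deletion each).

The objective is `n - c° + (p_g|g + T - p_G|G + delta)/2 + s` with
`T >= max` of the pier counts and `delta` tied to the pontoon parity `O`
and pier-imbalance indicator `NE`. The solver may trade `delta` against a
spurious unit of `q`; both have the same objective value, so the optimum is
unaffected. The objective can be half-integral when the optimal census has
odd `q`; the reported distance is `ceiling(objective - 1e-6)`, matching the
closed form's ceiling.

Misreporting is either infeasible (parity or `a`-propagation) or priced at
least as high as honest reporting; this is validated behaviorally: on
random natural genomes with small families the ILP optimum equals the
minimum of the closed form over *all* maximum matchings by explicit
enumeration, and on resolved genomes it equals the closed form directly.
The decoded matching is re-scored through the independent census code, so a
decoding inconsistency would be caught at solution time.

Solving uses the HiGHS mixed-integer solver through
`scipy.optimize.milp` (single-threaded and deterministic; `threads` and
`seed` are accepted for interface stability and forwarded where the backend
supports them). `write_lp()` exports any model as a deterministic CPLEX-LP
file for use with other solvers.

## The evolution simulator

`evolve()` emulates a WGD history: a root genome of `root_markers` singular
markers on one linear chromosome evolves along a lineage (default
`(((G)D)S)R;`, read by a small newick walker because the tree has unary
internal nodes). Each non-WGD branch applies `ops_per_branch` DCJs plus
`round(rate * ops_per_branch)` insertions (rate 0.2), tandem duplications
(rate 0.3) and deletions (rate 1.0 after the WGD, 0 before — deletions
before the duplication would not contribute to the halving scenario), all
interleaved by one uniform shuffle per branch; the WGD branch duplicates
every chromosome and performs no other operation. Segment lengths follow a
Zipf law `p(l) = l^(-a)/zeta(a)` with shapes 6 (duplications) and 4
(indels), truncated where the remaining mass drops below 1e-12 and
renormalized.

Choices the protocol leaves open, fixed here and recorded in the truth log:
DCJs pick two distinct cut sites uniformly among adjacencies and telomeres
and rejoin uniformly among the legal outcomes; duplications are tandem;
insertions introduce novel families; deletions remove a uniform contiguous
segment (clamped so the genome never empties). The truth log records exact
per-branch operation counts and marker-count bookkeeping, so simulated
distances can be compared against computed ones.

What passing simulator-based tests shows — and what it does not: the
generator produces genuinely rearranged, duplicated and gapped genomes with
exact ground truth, but real data additionally carry assembly artifacts,
family-inference errors, and non-uniform rearrangement and loss processes.
The computed halving distance is a parsimony bound: on simulations with few
post-WGD events it recovers most of the true count (the low-rearrangement
regime asserted in the acceptance suite at 200 markers and 20 post-WGD
operations per branch), and it falls below the true count as events
accumulate, exactly as an edit distance saturates.

## Numerical and degenerate-input choices

* Orientation: a `+` marker contributes (tail, head) in reading order; the
  adjacency joins the right extremity of one marker to the left extremity
  of the next. Occurrence numbers are assignment order in the file and
  never affect homology.
* `write_genomes()` canonicalizes (lexicographically smallest rotation or
  reflection, sorted chromosomes) so round-trips and diffs are
  deterministic.
* The empty genome is SD (distance 0, empty model). A chromosome must
  contain at least one marker.
* Insertions may create a new chromosome or attach at an adjacency or
  telomere — mutually exclusive options.
* ILP integerization tolerance 1e-6; big-M constants are vertex-count
  bounds, never larger.
* The brute-force oracle deduplicates states up to chromosome order,
  rotation and reflection; its insertion moves are single-marker segments
  (longer insertions are compositions within the depth bound).

## Scales used by the test suite

Unit tests run on genomes of up to ~40 markers. The acceptance suite uses
the exhaustive sweep over all canonical genomes with up to 4 markers for
the oracle equivalence, 500 random resolved genomes (up to 30 markers) for sorting
optimality, 50 genomes (up to 40 markers) for ILP-formula equivalence, 50
natural genomes (up to 10 markers, families up to size 4) for
ILP-enumeration equivalence, and 50 simulations at 200 root markers with 20
operations per branch for the simulated-distance bound. These sizes keep
the full suite in the minutes range on one CPU while exercising every code
path; the formula and ILP themselves scale to tens of thousands of markers
(model size is linear), with MILP solve time — not model size — the
practical limit for heavily duplicated or heavily rearranged inputs.

## Analyzing real WGD descendants (recipe)

The package consumes gene-order files only. To analyze assembled genomes:
extract one representative (e.g. longest) coding sequence per gene, run an
all-vs-all similarity search, form families transitively from hits at a
chosen e-value cutoff (0.01 is a reasonable default), write the per-genome
gene orders with family names as marker names in the UniMoG dialect, and
run `halve_natural()` (or the `ilp` subcommand of the shipped CLI script)
per genome. Expect hours of MILP time for yeast-sized genomes with many
ambiguous families, and interpret results with care when a genome has few
non-singular markers: the distance is bounded by the matching size, so a
marker-poor matching yields an underestimate. An affine cost model scoring
deleted segment lengths as well as segment counts is the natural extension
for loss-dominated histories.

## Known limitations

* The ILP searches consistent decompositions exactly but relies on a MILP
  backend; without a Python/scipy installation only `write_lp()` export is
  available.
* `sort_halving()` requires a resolved matching; for natural genomes use
  `halve_natural()`, which sorts under the decoded optimal matching.
* The simulator's duplication and insertion samplers are the documented
  choices above, not a claim about any particular published sampler.
* Scenario enumeration (all co-optimal scenarios) and unrestricted-indel
  halving are out of scope.
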