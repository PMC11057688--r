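# dcjhalving

Genome halving under the DCJ-indel model, for genomes with arbitrary gene
family sizes.

After a whole-genome duplication (WGD), a genome carries every marker and
every adjacency twice. Rearrangements and large-scale gene loss erode that
structure; today's descendant has families of size 0, 1, 2, or more. The
*genome halving problem* reconstructs a structurally doubled (SD) ancestor
at minimum distance from the observed genome under a rearrangement model.
`dcjhalving` solves it under the DCJ-indel model — double-cut-and-join
operations plus segmental insertions and deletions, with indels restricted
to singular markers so that loss is modeled without being abused.

For a genome with resolved homology (families of size ≤ 2), the restricted
halving distance has a closed form over the component census of the
supernatural graph (extremities as vertices; adjacency edges and extremity
edges between homologous extremities). With `n` matched pairs, `c°` even
cycles, odd pontoons `p_g|g`, even/odd piers `p_G°g`, `p_G|g`, odd viaducts
`p_G|G` and `l` circular singletons:

    d = l + n − c° + ⌈(q + δ) / 2⌉,   q = p_g|g + max(p_G°g, p_G|g) − p_G|G

where δ = 1 exactly when `p_g|g` is odd and the two pier counts are equal.
`halving_distance()` evaluates this in near-linear time and
`sort_halving()` produces an optimal, verifiable scenario together with the
SD ancestor. For natural genomes (any family sizes) the problem is NP-hard;
`halve_natural()` solves a capping-free integer linear program over all
maximum matchings (model size linear in markers + telomeres) with the HiGHS
solver, then sorts under the decoded matching. A WGD evolution simulator
(`evolve()`), brute-force validation oracles (`bruteforce_halving()`,
`min_over_matchings()`) and UniMoG-dialect gene-order I/O round out the
package.

## Worked example

```r
library(dcjhalving)

gs <- parse_genomes(">A\n1 2 4 3 )")
h  <- homology(list(c("1", "3"), c("2", "4")))   # markers 1≡3 and 2≡4

halving_distance(gs[[1]], h)
#> DCJ-indel halving distance: 1
#>   n = 2, even cycles = 1, q = 0, delta = 0, circular singletons = 0

sort_halving(gs[[1]], h)
#> Halving scenario with 1 operations
#>   DCJ cut {t3.1,h4.1} {h1.1,t2.1} join {t3.1,h1.1} {h4.1,t2.1}
```

The circular genome `(1 2 4 3)` has both families doubled (`n = 2`) but
only one of the two adjacency pairs forms an even cycle, so one DCJ is
needed; the emitted operation cuts the two unpaired adjacencies and rejoins
them, and `write_genomes(sort_halving(gs[[1]], h)$final)` prints the SD
ancestor `1 3 )` / `2 4 )` — two circular chromosomes in which every marker
and adjacency is paired.

A natural genome with an ambiguous family (three copies of marker 1):

```r
res <- halve_natural(parse_genomes(">N\n1 2 1 1 3 )")[[1]])
res$solution
#> Halving ILP solution: objective 1 -> distance 1 ( optimal )
res$scenario
#> Halving scenario with 1 operations
#>   DEL 3.1 1.1 2.1
```

The ILP pairs two of the three copies of family 1 (the maximum matching
constraint allows one singular copy) and a single deletion of the
contiguous singular segment yields the SD ancestor `(1 1)`.

A command-line front end with subcommands `dist`, `sort`, `ilp`,
`simulate` and `oracle` is installed at
`system.file("scripts", "dcjhalving", package = "dcjhalving")`.

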