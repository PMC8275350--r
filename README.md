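# cdbg — compacted de Bruijn graphs from genome collections

`cdbg` builds the (colored) **compacted de Bruijn graph** of one or more
assembled reference genomes: the set of **maximal unitigs** — the maximal
non-branching paths of the bidirected, edge-centric de Bruijn graph over
canonical k-mers — together with, for every input sequence, its tiling by
oriented unitigs. It is aimed at people building pan-genome indexes,
reference-collection analyses or assembly-graph tooling who need a correct,
fully tested compactor at laptop scale, plus the machinery around it:
GFA1/GFA2 export, an independent ground-truth compactor, an output
validator, and a seeded synthetic-genome generator.

## The algorithm

For a string collection *S* and odd k, the de Bruijn graph *G(S, k)* has a
vertex for every distinct canonical k-mer (the lexicographic minimum of the
k-mer and its reverse complement) and an edge for every distinct (k+1)-mer.
Each vertex has a *front* and a *back* side; an edge touches the back of
*u* when its k-prefix is canonical (else the front), and the front of *v*
when its k-suffix is canonical (else the back). A unitig is a path whose
internal vertices each have exactly one incident edge per side; the maximal
unitigs partition the vertex set (a *node decomposition*), and collapsing
each one yields the compacted graph.

The naive route — build all adjacency, then walk it — stores the whole
graph. `cdbg` instead never materializes the graph. Each vertex is a tiny
deterministic finite-state automaton whose state records, per side, either
the single edge character seen so far (4 possibilities each side) or that
the side is *ambiguous* (more than one distinct edge, or an empty-symbol
sentinel at a sequence end): 5 × 5 side configurations plus one *unvisited*
start state, 26 states in all, 5 bits per vertex. Two linear scans over the
input do all the work:

1. **State computation.** Every k-mer instance contributes one input symbol
   — the pair of characters flanking it, orientation-normalized, with
   empty-symbol sentinels at run boundaries and a special rule forcing a
   side ambiguous when the flanking (k+1)-mer is palindromic (a *crossing
   loop*, an edge incident twice to one side). The per-side update is a
   commutative, idempotent monotone join, so the final states are
   independent of processing order.
2. **Unitig extraction.** A second scan classifies each vertex's state into
   one of four classes (single/multi × in/out) and applies initiation and
   termination rules to cut each sequence into maximal unitigs, emitting
   each exactly once via a one-bit emission flag on a signature vertex.

The only per-vertex storage is a minimal perfect index over the static
canonical k-mer set plus 5 state bits and 1 emission bit.

## Worked example

```r
library(cdbg)
g <- compact_dbg(c(ref1 = "CGACATGTCTTAG", ref2 = "GCTCTTAG"), k = 3)
g
#> compacted de Bruijn graph (k = 3)
#>   10 distinct canonical k-mers
#>   4 maximal unitigs (total length 18, longest 6)
#>   6 tiling steps over 2 input run(s)
g$unitigs
#>   id spelling length first_vertex last_vertex
#> 1  1    ATGTC      5          ATG         GAC
#> 2  2      CGA      3          CGA         CGA
#> 3  3   CTAAGA      6          CTA         AGA
#> 4  4     GAGC      4          CTC         AGC
head(g$tilings)
#>   seq_id run_start step unitig_id orientation start
#> 1   ref1         1    1         2           +     1
#> 2   ref1         1    2         1           -     2
#> 3   ref1         1    3         1           +     5
#> 4   ref1         1    4         3           -     8
#> 5   ref2         1    1         4           -     1
#> 6   ref2         1    2         3           -     3
```

The 10 distinct canonical 3-mers of the two sequences collapse into 4
maximal unitigs, reported in canonical spelling. The tiling says how each
input is spelled by oriented unitigs with overlap k−1 = 2: `ref1` is
`CGA`(+) then `ATGTC` reversed (`GACAT`) then `ATGTC` forward then
`CTAAGA` reversed — the unitig `ATGTC` is traversed twice because the
palindromic 4-mer `CATG` forms a loop at vertex `ATG`. Checking the
output:

```r
validate_unitigs(c(ref1 = "CGACATGTCTTAG", ref2 = "GCTCTTAG"), g$unitigs, 3)$ok
#> [1] TRUE
identical(sort(g$unitigs$spelling), naive_compact(c("CGACATGTCTTAG", "GCTCTTAG"), 3))
#> [1] TRUE
```

`write_unitigs_fasta(g$unitigs, "out.fa")` and `write_gfa(g, "out.gfa",
version = 1)` export the graph; `inst/scripts/cdbg` wraps the same
functions as a command-line tool (`build`, `validate`, `fixtures`
subcommands).

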