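---
title: "Compacting de Bruijn graphs with per-vertex automata: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compacting de Bruijn graphs with per-vertex automata: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdbg)
```

This vignette is the package's account of the method it implements: the
graph model and its assumptions, the automaton that replaces explicit
adjacency, the knobs that matter, the numerical and design choices made
where the design was genuinely open, and what the test evidence does and
does not establish.

## The graph model

All sequences are over `A,C,G,T`. For a collection *S* and an odd k ≥ 3,
the edge-centric bidirected de Bruijn graph *G(S, k)* has one vertex per
distinct *canonical* k-mer (`min(x, rc(x))` lexicographically) and one
edge per distinct (k+1)-mer occurring in *S*. k is required to be odd so
that no k-mer equals its own reverse complement: every instance then has
an unambiguous orientation relative to its canonical form, which is what
makes the side rules below total. Even k is rejected at input validation
rather than attempting a tie-break for palindromic k-mers.

Each vertex has a **front** and a **back** side. An edge, read as a
(k+1)-mer `e`, touches the back of its first endpoint when `pre_k(e)` is
canonical (else the front), and the front of its second endpoint when
`suf_k(e)` is canonical (else the back). A walk spelling an input string
enters each vertex through the front exactly when the k-mer instance is
canonical; unitigs are paths entered and exited through opposite sides,
and maximal unitigs cannot be extended on either end.

Two boundary constructions matter in practice:

* **Sentinels.** Each input run is conceptually padded with the empty
  symbol on both ends. The terminal k-mers therefore have one side with
  an empty-symbol incidence, which marks the side ambiguous and prevents
  any unitig from spanning two input strings (or two runs of one string).
* **Crossing loops.** A palindromic (k+1)-mer is an edge both of whose
  incidences land on the same side of the same vertex. That side then has
  two incidences of one edge and can no longer be interior to a unitig.
  Detection is purely local: the flanking (k+1)-mer `p·x` (or `x·n`)
  equals its own reverse complement. This is equivalent to "the adjacent
  instance maps to the same vertex in the opposite orientation", but needs
  no lookahead state, which keeps the instance scan strictly local.

## The vertex automaton

The information the extractor needs per side is only: *the* single edge
character incident there (four possibilities), or the fact that the side
has several distinct edges or a sentinel ("ambiguous"). That gives five
configurations per side, 25 per vertex, plus one shared *unvisited*
initial state: 26 states, packed into 5-bit codes (`ceiling(log2(26))`).

Transitions are made **per vertex instance, not per edge**: the two
flanking characters of an instance are normalized into a `(front, back)`
symbol pair (complementing and swapping when the instance is
non-canonical) and both sides are updated simultaneously. Processing
per-edge instead would require each side to track "unvisited"
independently, inflating the state space to 36; the per-vertex treatment
is why 26 states suffice, and the package deliberately exposes no
single-side transition entry point.

Each side update is a monotone join on the 5-element poset where the four
characters are incomparable and "ambiguous" is the top: from unvisited a
side adopts the observed character; a unique character survives only
unanimous re-observation; ambiguous is absorbing. Joins are commutative
and idempotent, so folding the multiset of instance symbols is
**order independent** — the property that makes chunked (and, in the
original setting, parallel) processing legal without any coordination
beyond per-vertex atomicity. The full 26 × 25 transition table is
generated from these two per-side rules rather than hard-coded; a
snapshot test freezes the generated table so any change to the rules is a
visible diff.

The extraction pass classifies visited states into four classes
(single/multi-in × single/multi-out, sizes 16/4/4/1) and applies the
initiation/termination rules: a vertex initiates a maximal unitig when it
is multi-in multi-out, entered front as multi-in single-out, or entered
back as single-in multi-out (termination is the mirror image); in
addition a vertex initiates after a terminating predecessor and
terminates before an initiating successor, where the cross-referring
condition checks only the other rule's three local conditions and does
not recurse.

## Parameters that matter

* `k` (odd, ≥ 3; no default). The vertex resolution. Small k (≤ 7) makes
  dense, highly branched graphs and is what the tests use to stress
  topology; pan-genome practice uses k around 21–31. No upper limit is
  enforced; k-mers are handled as R strings, correctness over speed.
* `chunks` (default 1). Number of contiguous pieces the instance stream
  is split into during state computation, processed out of order. The
  result is provably identical for every value; the knob exists to
  exercise and document that contract, not to tune performance.
* Fixture generator (`make_collection`): `base_length` 1000 bp,
  `n_references` 3, `snp_rate` 0.01 substitutions/position, `indel_rate`
  0.002 events/position (1–3 bp), `n_run_rate` 0.001 N-runs/position
  (2–10 bp). These emulate a small collection of closely related strains
  — on the order of 1% divergence, occasional short indels and assembly
  gaps — the regime where a colored compacted graph is the natural
  summary. All generation is a pure function of `seed`.

## Numerical and representational choices

* **Side-character encoding.** The character stored for a front side is
  the one for which the edge reads `c·label` (label as suffix); for a
  back side, `label·d`. This is the unique convention invariant under
  strand choice — the same edge seen from either strand contributes the
  same character to the same vertex side (tested exhaustively at k = 3)
  — and it caps distinct edge characters per side at four.
* **State store.** The key set is static, so the "hash table" is a sorted
  array of the canonical k-mers, a k-mer's slot being its position in the
  array (found by exact matching): a minimal perfect index in [0, n). A genuine MPHF would only change
  constants; the store contract hides the choice. Lookups of alien keys
  are a contract violation and raise an error. Payload is 5 state bits
  plus 1 emission bit per vertex, constant in k and n; the emission mark
  is a separate flag rather than "output-tagged" extra states because 26
  states plus tagged variants would not fit 5 bits.
* **Unique emission.** A unitig's signature is the canonical form of the
  first k-mer of its canonical spelling — orientation-stable, and by the
  node decomposition unique to the unitig — and emission test-and-sets
  that vertex's flag.
* **Trivial unitigs.** A vertex may initiate and terminate in the same
  step (e.g. a multi-in multi-out vertex mid-walk); it is emitted as a
  single-vertex unitig and initiation is re-checked at the next vertex.
  A run of length exactly k gets sentinels on both sides, becomes
  multi-in multi-out, and is its own maximal unitig.
* **Determinism.** Unitig ids are assigned in C-locale sorted order of
  canonical spelling; writers emit records in id order with no
  timestamps, so outputs are byte-identical across runs, input orderings
  and chunk counts.
* **Degenerate input.** Lowercase is folded; maximal `A,C,G,T` runs
  shorter than k are dropped; a collection with no valid k-mer at all is
  a hard error rather than an empty result.
* **GFA dialect.** Links/edges are emitted only for adjacencies realized
  by consecutive tiling steps in the input (the edge-centric reading),
  deduplicated as unordered oriented pairs; orientation `+` means the
  step uses the canonical spelling. GFA1 paths / GFA2 ordered groups
  reproduce each input run under (k−1)-overlap gluing, which the test
  suite verifies by expansion.

## The oracle and what the tests show

The trustworthiness of the pipeline rests on an independently written
reference: `naive_compact` builds the explicit incidence table of every
(k+1)-mer instance (sentinels marked, same-side loops counted twice),
classifies sides by incidence counts, and walks mutually-unique links to
enumerate maximal unitigs. It shares no classification code with the
automaton path (even reverse complements come from Biostrings there), so
agreement is evidence, not tautology. The suite compares the two on over
a hundred seeded collections (k ∈ {3, 5, 7}, up to 2000 bp per
collection, 1–5 sequences, N runs, engineered palindromic (k+1)-mers,
duplicated segments within and across sequences) and validates every
output for node decomposition and run reconstruction. Those sizes keep
the whole suite under a couple of minutes on one core while densely
covering branching topology; small k makes collisions and loops vastly
more frequent per base pair than large-k genome practice, which is the
point.

What passing does **not** show: behavior at chromosome scale (the
implementation is pure R and string-based; the design's constant
bits-per-vertex store is checked structurally, not benchmarked), repeat
structure of real genomes (fixtures are i.i.d. uniform with engineered
local features; long approximate repeats are absent), GC skew
(composition-agnostic algorithm, uniform generator), and read data (the
tool consumes assembled references only).

## Known limitations

* Pure-R string handling: no 2-bit packing, no multi-threading; the
  `chunks` contract documents how a parallel realization would be legal
  but none is provided.
* The oracle is quadratic-ish in bookkeeping and intended for inputs of
  at most a few thousand vertices.
* GFA output carries only `LN`/`VN` tags and this package's own record
  layout; no per-color presence bitmaps on unitigs — the colored aspect
  is captured by per-reference tilings only.
* FASTQ input, and characters outside the IUPAC set accepted by
  Biostrings, are not supported.
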