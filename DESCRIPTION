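Package: cdbg
Title: Compacted de Bruijn Graph Construction from Genome Collections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs the (colored) compacted de Bruijn graph over one or
    more assembled reference sequences without ever materializing the full
    graph. Each canonical k-mer vertex is modelled as a small finite-state
    automaton whose state tracks the edges incident to its two sides; two
    implicit traversals of the input sequences compute all automaton states
    and then extract the maximal unitigs, which form a node decomposition of
    the graph. Includes FASTA and GFA1/GFA2 writers, an independent
    explicit-adjacency compactor used as ground truth, an output validator,
    and a deterministic synthetic-genome generator for closely related
    ("colored") reference collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
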