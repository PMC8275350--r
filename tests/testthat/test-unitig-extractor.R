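# Initiation/termination rules, walk spelling, and maximal unitig output.

test_that("walks enter through the front iff the instance is canonical", {
  expect_equal(entry_side("ATG"), "front")
  expect_equal(entry_side("CAT"), "back")
  set.seed(51)
  for (i in 1:20) {
    x <- random_dna(5L)
    expect_equal(entry_side(x) == "front", x == canonical(x))
  }
})

test_that("initiation and termination depend on class and entry side", {
  for (entry in c("front", "back")) {
    expect_true(initiates("multi-in multi-out", entry))
    expect_true(terminates("multi-in multi-out", entry))
    expect_false(initiates("single-in single-out", entry))
    expect_false(terminates("single-in single-out", entry))
  }
  expect_true(initiates("multi-in single-out", "front"))
  expect_false(initiates("multi-in single-out", "back"))
  expect_true(initiates("single-in multi-out", "back"))
  expect_false(initiates("single-in multi-out", "front"))
  expect_true(terminates("single-in multi-out", "front"))
  expect_false(terminates("single-in multi-out", "back"))
  expect_true(terminates("multi-in single-out", "back"))
  expect_false(terminates("multi-in single-out", "front"))
})

test_that("walks spell by gluing per-vertex seen spellings with overlap k-1", {
  expect_equal(spell_walk(c("GAC", "ACA", "ATG")), "GACAT")
  expect_equal(spell_walk(c("GAC", "ACA", "ATG", "ATG")), "GACATG")
  expect_equal(spell_walk("CGA"), "CGA")
  expect_error(spell_walk(c("AAA", "GGG")), "fail the")
})

test_that("reported spellings are canonical", {
  expect_equal(canonical_spelling("GACAT"), "ATGTC")
  expect_equal(canonical_spelling("CGA"), "CGA")
  set.seed(52)
  for (i in 1:20) {
    s <- random_dna(sample(3:30, 1L))
    expect_equal(canonical_spelling(reverse_complement(s)), canonical_spelling(s))
  }
})

test_that("the toy input yields exactly its four maximal unitigs", {
  g <- compact_dbg(toy_seqs(), 3)
  expect_equal(g$unitigs$spelling, c("ATGTC", "CGA", "CTAAGA", "GAGC"))
  expect_equal(g$unitigs$length, c(5L, 3L, 6L, 4L))
  expect_equal(g$unitigs$first_vertex, canonical(substr(g$unitigs$spelling, 1, 3)))
})

test_that("a branch-free run is emitted as a single unitig", {
  s <- "GATTACAGT"  # all 3-mers distinct, no branches
  g <- compact_dbg(c(x = s), 3)
  expect_equal(g$unitigs$spelling, canonical_spelling(s))
  expect_equal(nrow(g$tilings), 1L)
})

test_that("unitigs form a node decomposition and tile the input runs", {
  for (seed in 11:18) {
    fix <- random_fixture(seed)
    g <- compact_dbg(fix$seqs, fix$k)
    k <- fix$k

    # node decomposition: each distinct canonical k-mer in exactly one
    # unitig, exactly once
    uk <- unlist(lapply(g$unitigs$spelling, function(u) {
      m <- nchar(u) - k + 1L
      canonical(substring(u, seq_len(m), seq_len(m) + k - 1L))
    }))
    expect_equal(anyDuplicated(uk), 0L)
    expect_setequal(uk, enumerate_kmers(fix$seqs, k)$kmers)

    # tiling reconstruction: oriented steps glue back into each run
    runs <- cdbg:::.runs_of_collection(fix$seqs, k)
    tl <- g$tilings
    for (r in seq_len(nrow(runs))) {
      steps <- tl[tl$seq_id == runs$seq_id[[r]] & tl$run_start == runs$start[[r]], ]
      steps <- steps[order(steps$step), ]
      oriented <- ifelse(steps$orientation == "+",
                         g$unitigs$spelling[steps$unitig_id],
                         reverse_complement(g$unitigs$spelling[steps$unitig_id]))
      acc <- oriented[[1L]]
      for (j in seq_along(oriented)[-1L]) acc <- glue(acc, oriented[[j]], k - 1L)
      expect_equal(acc, runs$text[[r]])
      # consecutive steps overlap by exactly k-1 characters
      if (nrow(steps) > 1L) {
        expect_equal(diff(steps$start), nchar(oriented)[-length(oriented)] - (k - 1L))
      }
    }
  }
})

test_that("each unitig is emitted once even when seen repeatedly", {
  # the same genome twice: every unitig is encountered in at least two runs
  s <- random_genome(300, seed = 53)
  g <- compact_dbg(c(a = s, b = s), 5)
  expect_equal(anyDuplicated(g$unitigs$spelling), 0L)
  g_rc <- compact_dbg(c(a = s, b = reverse_complement(s)), 5)
  expect_equal(g_rc$unitigs$spelling, g$unitigs$spelling)
})

test_that("unitigs never span runs of one sequence", {
  left <- "GATTACAGT"
  right <- "CCATTGAC"
  joined <- paste0(left, "NN", right)
  g <- compact_dbg(c(x = joined), 3)
  sep <- compact_dbg(c(a = left, b = right), 3)
  expect_equal(g$unitigs$spelling, sep$unitigs$spelling)
  expect_true(all(nchar(g$unitigs$spelling) <= max(nchar(left), nchar(right))))
})

test_that("unitig output is invariant to input order, strand and chunking", {
  for (seed in 19:22) {
    fix <- random_fixture(seed)
    ref <- compact_dbg(fix$seqs, fix$k)$unitigs$spelling
    expect_equal(compact_dbg(rev(fix$seqs), fix$k)$unitigs$spelling, ref)
    flipped <- fix$seqs
    flipped[[1L]] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(toupper(flipped[[1L]]))))
    expect_equal(compact_dbg(flipped, fix$k)$unitigs$spelling, ref)
    expect_equal(compact_dbg(fix$seqs, fix$k, chunks = 4L)$unitigs$spelling, ref)
  }
})

test_that("extraction refuses a store with unvisited vertices", {
  store <- build_store(enumerate_kmers("GATTACAGT", 3))
  runs <- cdbg:::.runs_of_collection("GATTACAGT", 3)
  expect_error(extract_maximal_unitigs(runs, store), "unvisited")
})
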