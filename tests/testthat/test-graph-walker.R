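# Run splitting and the state-computation traversal.

test_that("sequences split into maximal uppercase A/C/G/T runs of length >= k", {
  r <- split_valid_runs("ACGTNNACG", 3)
  expect_equal(r$start, c(1L, 7L))
  expect_equal(r$end, c(4L, 9L))
  expect_equal(r$text, c("ACGT", "ACG"))

  expect_equal(split_valid_runs("acgt", 3)$text, "ACGT")  # case folding
  expect_equal(nrow(split_valid_runs("ACNGT", 3)), 0L)    # both runs too short
  expect_equal(nrow(split_valid_runs("NNNN", 3)), 0L)
  expect_equal(split_valid_runs("nnACGTAcgN", 5),
               data.frame(start = 3L, end = 9L, text = "ACGTACG"))
})

test_that("the vectorized instance contexts match the scalar symbol derivation", {
  set.seed(41)
  for (i in 1:20) {
    k <- sample(c(3L, 5L), 1L)
    txt <- random_dna(sample(k:40, 1L))
    tab <- cdbg:::.instance_table(txt, k)
    m <- nchar(txt) - k + 1L
    expect_equal(nrow(tab), m)
    for (j in seq_len(m)) {
      p <- if (j == 1L) "" else substr(txt, j - 1L, j - 1L)
      n <- if (j == m) "" else substr(txt, j + k, j + k)
      ref <- derive_input_symbol(tab$inst[[j]], p, n)
      expect_equal(c(tab$front[[j]], tab$back[[j]]), unname(ref))
    }
  }
})

test_that("computed states equal the ground-truth classification on the toy input", {
  seqs <- toy_seqs()
  store <- compute_states(cdbg:::.runs_of_collection(seqs, 3),
                          build_store(enumerate_kmers(seqs, 3)))
  expect_state <- function(v, class, front = NULL, back = NULL) {
    s <- get_state(store, v)
    expect_equal(state_class(s), class)
    if (!is.null(front)) expect_equal(state_sides(s)[["front"]], front)
    if (!is.null(back)) expect_equal(state_sides(s)[["back"]], back)
  }
  expect_state("GAC", "multi-in single-out", back = "A")
  expect_state("ACA", "single-in single-out", front = "G", back = "T")
  # the palindromic loop CATG counts twice on ATG's front, making it flanking
  expect_state("ATG", "multi-in single-out", back = "T")
  expect_true(all(store$codes != unvisited_state()))
})

test_that("no vertex is left unvisited after the pass", {
  for (seed in 1:5) {
    fix <- random_fixture(seed)
    runs <- cdbg:::.runs_of_collection(fix$seqs, fix$k)
    store <- compute_states(runs, build_store(enumerate_kmers(fix$seqs, fix$k)))
    expect_true(all(store$codes != unvisited_state()))
  }
})

test_that("a run of length exactly k yields the multi-in multi-out state", {
  seqs <- c(a = "ACGTA", b = "TTTTTTT")
  store <- compute_states(cdbg:::.runs_of_collection(seqs, 5),
                          build_store(enumerate_kmers(seqs, 5)))
  expect_equal(state_class(get_state(store, "ACGTA")), "multi-in multi-out")
})

test_that("final states are invariant to input order, strand and chunking", {
  for (seed in 6:10) {
    fix <- random_fixture(seed)
    seqs <- fix$seqs
    k <- fix$k
    base_runs <- cdbg:::.runs_of_collection(seqs, k)
    ref <- compute_states(base_runs, build_store(enumerate_kmers(seqs, k)))$codes

    perm <- rev(seqs)
    s1 <- compute_states(cdbg:::.runs_of_collection(perm, k),
                         build_store(enumerate_kmers(perm, k)))
    expect_identical(s1$codes, ref)

    flipped <- seqs
    flipped[[1L]] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(toupper(flipped[[1L]]))))
    s2 <- compute_states(cdbg:::.runs_of_collection(flipped, k),
                         build_store(enumerate_kmers(flipped, k)))
    expect_identical(s2$codes, ref)

    for (chunks in c(3L, 7L)) {
      s3 <- compute_states(base_runs, build_store(enumerate_kmers(seqs, k)),
                           chunks = chunks)
      expect_identical(s3$codes, ref)
    }
  }
})

test_that("a store keyed on other sequences is rejected", {
  store <- build_store(enumerate_kmers("ACGTACCA", 3))
  runs <- cdbg:::.runs_of_collection("GGGGGG", 3)
  expect_error(compute_states(runs, store), "inconsistent input")
})
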