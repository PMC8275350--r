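# String primitives and bidirected-graph semantics.

test_that("reverse complement complements, reverses, and is an involution", {
  expect_equal(reverse_complement("ATG"), "CAT")
  expect_equal(reverse_complement("CATG"), "CATG")  # palindromic 4-mer
  expect_equal(reverse_complement(c("A", "ACGT")), c("T", "ACGT"))
  set.seed(11)
  for (i in 1:25) {
    x <- random_dna(sample(1:40, 1L))
    expect_equal(reverse_complement(reverse_complement(x)), x)
  }
  expect_error(reverse_complement("ACGN"), "invalid alphabet")
  expect_error(reverse_complement("acg"), "invalid alphabet")
})

test_that("canonical form is the lexicographic minimum and is idempotent", {
  expect_equal(canonical("CAT"), "ATG")
  expect_equal(canonical("GAC"), "GAC")
  expect_equal(canonical("ACA"), "ACA")  # min(ACA, TGT)
  set.seed(12)
  for (i in 1:25) {
    x <- random_dna(7L)
    cx <- canonical(x)
    expect_equal(canonical(cx), cx)
    expect_equal(canonical(reverse_complement(x)), cx)
    expect_true(cx <= reverse_complement(cx))
  }
})

test_that("odd k-mers are never their own reverse complement", {
  for (x in all_dna_strings(3L)) {
    expect_false(x == reverse_complement(x))
  }
})

test_that("glue appends past the verified overlap", {
  expect_equal(glue("GAC", "ACA", 2), "GACA")
  expect_equal(glue("ATGT", "GTC", 2), "ATGTC")
  expect_equal(glue("GAC", "GAC", 3), "GAC")   # full-overlap identity
  expect_equal(glue("AC", "GT", 0), "ACGT")
  expect_error(glue("GAC", "TTT", 2), "overlap mismatch")
  expect_error(glue("GAC", "ACA", 4), "out of range")
})

test_that("edge endpoints follow the canonical-orientation incidence rule", {
  e <- edge_endpoints("CGAC")
  expect_equal(e$first, list(vertex = "CGA", side = "back"))
  expect_equal(e$second, list(vertex = "GAC", side = "front"))

  loop <- edge_endpoints("CATG")  # palindromic: both incidences on ATG's front
  expect_equal(loop$first, list(vertex = "ATG", side = "front"))
  expect_equal(loop$second, list(vertex = "ATG", side = "front"))

  g <- edge_endpoints("GCTC")
  expect_equal(g$first, list(vertex = "AGC", side = "front"))
  expect_equal(g$second, list(vertex = "CTC", side = "front"))

  expect_error(edge_endpoints("ACGTA"), "k odd")   # length 5 => k = 4, even
})

test_that("edge incidences are orientation invariant over all edges at k=3", {
  unordered <- function(ep) {
    keys <- c(paste(ep$first$vertex, ep$first$side),
              paste(ep$second$vertex, ep$second$side))
    sort(keys)
  }
  for (e in all_dna_strings(4L)) {
    expect_equal(unordered(edge_endpoints(e)),
                 unordered(edge_endpoints(reverse_complement(e))))
  }
})

test_that("input symbols encode edges consistently from either strand", {
  expect_equal(derive_input_symbol("GAC", "C", "A"), c(front = "C", back = "A"))
  expect_equal(derive_input_symbol("CAT", "A", "G"), c(front = "*", back = "T"))
  expect_equal(derive_input_symbol("CGA", "", "C"), c(front = "*", back = "C"))

  # reverse-complementing the whole context leaves the symbol unchanged
  comp1 <- function(c) if (c == "") "" else chartr("ACGT", "TGCA", c)
  set.seed(13)
  for (i in 1:200) {
    x <- random_dna(5L)
    p <- sample(c("A", "C", "G", "T", ""), 1L)
    n <- sample(c("A", "C", "G", "T", ""), 1L)
    expect_identical(derive_input_symbol(x, p, n),
                     derive_input_symbol(reverse_complement(x), comp1(n), comp1(p)))
  }
})

test_that("instances of one edge on either strand agree at each vertex side", {
  # exhaustively at k=3: an edge e occurring forward in one sequence and
  # reverse-complemented in another must contribute the same character to
  # the same side of each endpoint vertex
  comp1 <- function(c) chartr("ACGT", "TGCA", c)
  for (e in all_dna_strings(4L)) {
    rce <- reverse_complement(e)
    # right endpoint of e, viewed from e and from rc(e)
    x <- substr(e, 2L, 4L)
    from_fwd <- derive_input_symbol(x, substr(e, 1L, 1L), "")
    from_rev <- derive_input_symbol(reverse_complement(x), "", comp1(substr(e, 1L, 1L)))
    side <- if (x == canonical(x)) "front" else "back"
    expect_equal(unname(from_fwd[[side]]), unname(from_rev[[side]]))
    # left endpoint likewise
    y <- substr(e, 1L, 3L)
    from_fwd <- derive_input_symbol(y, "", substr(e, 4L, 4L))
    from_rev <- derive_input_symbol(reverse_complement(y), comp1(substr(e, 4L, 4L)), "")
    side <- if (y == canonical(y)) "back" else "front"
    expect_equal(unname(from_fwd[[side]]), unname(from_rev[[side]]))
  }
})

test_that("a vertex side can see at most four distinct edge characters", {
  set.seed(14)
  for (i in 1:20) {
    x <- random_dna(5L)
    fronts <- unique(vapply(c("A", "C", "G", "T"), function(p) {
      derive_input_symbol(x, p, "A")[["front"]]
    }, character(1L)))
    backs <- unique(vapply(c("A", "C", "G", "T"), function(n) {
      derive_input_symbol(x, "A", n)[["back"]]
    }, character(1L)))
    expect_lte(length(setdiff(fronts, "*")), 4L)
    expect_lte(length(setdiff(backs, "*")), 4L)
  }
})
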