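# Seeded random test inputs. Each fixture is a small collection of
# sequences (total length <= 2000) that deliberately exercises the hard
# cases: N runs breaking sequences into several valid runs, engineered
# palindromic (k+1)-mers (crossing loops), repeated vertices, and shared
# k-mers across sequences.

# a palindromic (k+1)-mer: y followed by its reverse complement
palindromic_edge <- function(k) {
  half <- (k + 1L) / 2L
  y <- paste(sample(c("A", "C", "G", "T"), half, replace = TRUE), collapse = "")
  paste0(y, reverse_complement(y))
}

# splice `piece` into `s` at a random position
splice_in <- function(s, piece) {
  pos <- sample.int(nchar(s) + 1L, 1L)
  paste0(substr(s, 1L, pos - 1L), piece, substring(s, pos))
}

random_fixture <- function(seed, k = NULL) {
  set.seed(seed)
  if (is.null(k)) k <- sample(c(3L, 5L, 7L), 1L)
  n_seq <- sample(1:5, 1L)
  total <- sample(200:2000, 1L)
  lens <- pmax(k + 2L, as.integer(stats::rmultinom(1L, total, rep(1, n_seq))))
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, character(1L))
  # engineered palindromic (k+1)-mers in about half the sequences
  for (i in seq_along(seqs)) {
    if (runif(1) < 0.5) seqs[[i]] <- splice_in(seqs[[i]], palindromic_edge(k))
  }
  # duplicated segments within and across sequences (repeats, shared k-mers)
  if (n_seq >= 2L && nchar(seqs[[1L]]) > 4L * k) {
    seg <- substr(seqs[[1L]], k, 3L * k)
    seqs[[n_seq]] <- splice_in(seqs[[n_seq]], seg)
    seqs[[1L]] <- splice_in(seqs[[1L]], seg)
  }
  # N runs and lowercase in some sequences
  for (i in seq_along(seqs)) {
    if (runif(1) < 0.5) {
      seqs[[i]] <- inject_n_runs(seqs[[i]], n_run_rate = 0.01, seed = NULL)
    }
    if (runif(1) < 0.3) seqs[[i]] <- tolower(seqs[[i]])
  }
  names(seqs) <- sprintf("s%d", seq_along(seqs))
  list(seqs = seqs, k = k)
}

# the worked toy input used across tests
toy_seqs <- function() c(ref1 = "CGACATGTCTTAG", ref2 = "GCTCTTAG")

# all DNA strings of length n (4^n of them), for exhaustive checks
all_dna_strings <- function(n) {
  g <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), n))
  apply(g, 1L, paste, collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
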