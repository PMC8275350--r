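# Deterministic synthetic inputs emulating the tool's use cases: a single
# random genome, and a "colored" collection of closely related genomes
# obtained by mutating a base genome with substitutions, short indels and
# runs of N. Everything is fully determined by an integer seed; the
# caller's RNG state is left untouched.

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Generate a random genome
#'
#' Bases are drawn i.i.d. uniformly from A/C/G/T (no GC skew: the
#' compaction algorithm is composition agnostic).
#'
#' @param length Genome length, >= 1.
#' @param seed Integer seed; the same seed always yields the same genome.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed = NULL) {
  if (length < 1L) stop("length must be >= 1", call. = FALSE)
  .with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                         collapse = ""))
}

#' Mutate a reference genome
#'
#' Applies, independently at each position: a substitution to one of the
#' three other bases with probability `snp_rate`, and with probability
#' `indel_rate` an indel event -- either an insertion of 1-3 random bases
#' before the position or a deletion of 1-3 bases starting at it.
#'
#' @param reference A DNA string (A/C/G/T).
#' @param snp_rate,indel_rate Per-position event probabilities in `[0, 1)`.
#' @param seed Integer seed.
#' @return The mutated string.
#' @export
mutate_genome <- function(reference, snp_rate = 0.01, indel_rate = 0.002, seed = NULL) {
  .check_dna(reference, "reference")
  if (snp_rate < 0 || snp_rate >= 1 || indel_rate < 0 || indel_rate >= 1) {
    stop("rates must be in [0, 1)", call. = FALSE)
  }
  .with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ch <- strsplit(reference, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    sub_at <- stats::runif(n) < snp_rate
    if (any(sub_at)) {
      ch[sub_at] <- vapply(ch[sub_at],
                           function(b) sample(setdiff(bases, b), 1L),
                           character(1L), USE.NAMES = FALSE)
    }
    indel_at <- which(stats::runif(n) < indel_rate)
    if (length(indel_at) > 0L) {
      pieces <- ch
      skip_until <- 0L
      for (i in indel_at) {
        if (i <= skip_until) next
        if (stats::runif(1L) < 0.5) {
          ins <- paste(sample(bases, sample(1:3, 1L), replace = TRUE), collapse = "")
          pieces[[i]] <- paste0(ins, pieces[[i]])
        } else {
          del <- sample(1:3, 1L)
          gone <- i:min(i + del - 1L, n)
          pieces[gone] <- ""
          skip_until <- max(gone)
        }
      }
      ch <- pieces
    }
    paste(ch, collapse = "")
  })
}

#' Inject runs of N
#'
#' Each position independently starts a run of 2-10 `N` characters with
#' probability `n_run_rate`, overwriting the bases underneath; mimics
#' assembly gaps in real references.
#'
#' @param sequence A DNA string.
#' @param n_run_rate Per-position probability of starting an N run.
#' @param seed Integer seed.
#' @return The string with N runs injected.
#' @export
inject_n_runs <- function(sequence, n_run_rate = 0.001, seed = NULL) {
  if (n_run_rate < 0 || n_run_rate >= 1) stop("n_run_rate must be in [0, 1)", call. = FALSE)
  .with_seed(seed, {
    ch <- strsplit(sequence, "", fixed = TRUE)[[1L]]
    n <- length(ch)
    at <- which(stats::runif(n) < n_run_rate)
    for (i in at) {
      len <- sample(2:10, 1L)
      ch[i:min(i + len - 1L, n)] <- "N"
    }
    paste(ch, collapse = "")
  })
}

#' Generate a collection of closely related genomes
#'
#' One base genome plus `n_references - 1` mutated copies, emulating a
#' "colored" input: several references of the same or closely related
#' species, differing by SNPs, short indels and assembly gaps.
#'
#' @param base_length Length of the base genome.
#' @param n_references Number of references in the collection.
#' @param snp_rate,indel_rate Mutation rates for the derived references
#'   (defaults emulate closely related strains: 1% substitutions, 0.2%
#'   indel events).
#' @param n_run_rate Per-position probability of an assembly-gap N run
#'   (applied to every reference).
#' @param seed Integer seed; fully determines the collection.
#' @param path Optional FASTA output path; when given the collection is
#'   also written via [write_fasta()].
#' @return A data frame with columns `id` and `sequence` (invisibly when
#'   `path` is given).
#' @export
make_collection <- function(base_length = 1000L, n_references = 3L,
                            snp_rate = 0.01, indel_rate = 0.002,
                            n_run_rate = 0.001, seed = 1L, path = NULL) {
  if (n_references < 1L) stop("n_references must be >= 1", call. = FALSE)
  seqs <- .with_seed(seed, {
    base <- paste(sample(c("A", "C", "G", "T"), base_length, replace = TRUE),
                  collapse = "")
    out <- character(n_references)
    out[[1L]] <- base
    for (i in seq_len(n_references - 1L)) {
      out[[i + 1L]] <- mutate_genome(base, snp_rate, indel_rate, seed = NULL)
    }
    if (n_run_rate > 0) {
      out <- vapply(out, inject_n_runs, character(1L),
                    n_run_rate = n_run_rate, seed = NULL, USE.NAMES = FALSE)
    }
    out
  })
  records <- data.frame(id = sprintf("ref%d", seq_len(n_references)),
                        sequence = seqs, stringsAsFactors = FALSE)
  if (!is.null(path)) {
    write_fasta(records, path)
    return(invisible(records))
  }
  records
}
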