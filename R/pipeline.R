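# End-to-end orchestration: enumerate the distinct canonical k-mers, build
# the state store over them, compute all automaton states by implicit
# traversal, then extract the maximal unitigs.

#' Build the compacted de Bruijn graph of a sequence collection
#'
#' Runs the full pipeline on a set of reference sequences: the vertices
#' (distinct canonical k-mers) are enumerated and indexed, every vertex's
#' automaton state is computed in one implicit traversal of the inputs,
#' and the maximal unitigs are extracted in a second traversal. The full
#' de Bruijn graph is never materialized; per vertex the algorithm keeps
#' only a 5-bit state code and a 1-bit emission flag.
#'
#' @param sequences Character vector of reference sequences (may contain
#'   lowercase and non-A/C/G/T characters; maximal A/C/G/T runs of length
#'   at least `k` are used), optionally named with sequence ids.
#' @param k Odd integer >= 3, the k-mer length.
#' @param chunks Number of chunks for the state-computation pass (see
#'   [compute_states()]); the result is identical for any value.
#' @param store Optional precomputed `state_store` for these sequences (as
#'   saved by [save_store()] before extraction); skips enumeration and the
#'   state pass.
#' @return An object of class `cdbg`: list with `k`, `n_kmers`, `unitigs`,
#'   `tilings` (see [extract_maximal_unitigs()]) and the final `store`.
#' @examples
#' g <- compact_dbg(c("CGACATGTCTTAG", "GCTCTTAG"), k = 3)
#' g$unitigs$spelling  # "ATGTC" "CGA" "CTAAGA" "GAGC"
#' @export
compact_dbg <- function(sequences, k, chunks = 1L, store = NULL) {
  k <- .check_k(k)
  runs <- .runs_of_collection(sequences, k)
  if (nrow(runs) == 0L) {
    stop("no sequence contains a valid k-mer (all A/C/G/T runs shorter than k)",
         call. = FALSE)
  }
  if (is.null(store)) {
    kset <- enumerate_kmers(sequences, k)
    store <- build_store(kset)
    store <- compute_states(runs, store, chunks = chunks)
  } else {
    if (store$k != k) stop("store was built with a different k", call. = FALSE)
    store$emitted <- logical(store$n)  # extraction flags are per invocation
  }
  res <- extract_maximal_unitigs(runs, store)
  structure(
    list(k = k, n_kmers = store$n, unitigs = res$unitigs,
         tilings = res$tilings, store = res$store),
    class = "cdbg"
  )
}

#' @export
print.cdbg <- function(x, ...) {
  cat(sprintf("compacted de Bruijn graph (k = %d)\n", x$k))
  cat(sprintf("  %d distinct canonical k-mers\n", x$n_kmers))
  cat(sprintf("  %d maximal unitigs (total length %d, longest %d)\n",
              nrow(x$unitigs), sum(x$unitigs$length), max(x$unitigs$length)))
  cat(sprintf("  %d tiling steps over %d input run(s)\n",
              nrow(x$tilings), length(unique(paste(x$tilings$seq_id, x$tilings$run_start)))))
  invisible(x)
}
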