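# Hash-table structure for the automata: the distinct canonical k-mer set,
# a minimal bijective index over it, and a fixed-width code table holding
# each vertex's automaton state plus a one-bit emission flag.
#
# The key set is static: it is enumerated once from the input sequences and
# never grows or shrinks. The index is a sorted array (C-locale radix
# order); position in the array is the minimal perfect index in [0, n).
# Callers must never query alien keys -- lookups of k-mers outside the set
# return NA and the traversal code treats that as an inconsistent-input
# error. Per vertex the store holds a 5-bit state code (26 states) and a
# separate 1-bit emission flag, i.e. a constant 6 bits of payload per
# distinct k-mer independent of k and n.

#' Enumerate the distinct canonical k-mers of a sequence collection
#'
#' Scans every maximal A/C/G/T run of length at least `k` (lowercase is
#' folded; other characters break runs) and collects the canonical forms of
#' all k-mers, deduplicated across sequences and orientations. These are
#' the vertices of the edge-centric de Bruijn graph.
#'
#' @param sequences Character vector of (possibly degenerate) DNA strings.
#' @param k Odd integer >= 3.
#' @return An object of class `kmer_set`: list with `kmers` (sorted
#'   character vector of canonical k-mers), `k` and `n`.
#' @examples
#' enumerate_kmers(c("CGACATGTCTTAG", "GCTCTTAG"), 3)$n  # 10
#' @export
enumerate_kmers <- function(sequences, k) {
  k <- .check_k(k)
  runs <- .runs_of_collection(sequences, k)
  if (nrow(runs) == 0L) {
    stop("no sequence contains a valid k-mer (all A/C/G/T runs shorter than k)",
         call. = FALSE)
  }
  canon <- unlist(lapply(runs$text, function(txt) {
    m <- nchar(txt) - k + 1L
    inst <- substring(txt, seq_len(m), seq_len(m) + k - 1L)
    rc <- .rc_substrings(txt, seq_len(m), k)
    unique(ifelse(inst <= rc, inst, rc))
  }), use.names = FALSE)
  kmers <- sort(unique(canon), method = "radix")
  structure(list(kmers = kmers, k = k, n = length(kmers)), class = "kmer_set")
}

#' @export
print.kmer_set <- function(x, ...) {
  cat(sprintf("kmer_set: %d distinct canonical %d-mers\n", x$n, x$k))
  invisible(x)
}

# reverse complements of the k-length substrings of txt starting at `starts`,
# computed by indexing into the reverse complement of the whole run once
.rc_substrings <- function(txt, starts, len) {
  rc_txt <- reverse_complement(txt)
  L <- nchar(txt)
  substring(rc_txt, L - starts - len + 2L, L - starts + 1L)
}

#' Build a state store over a k-mer set
#'
#' Allocates the per-vertex state table: every vertex starts in the
#' unvisited state with its emission flag clear.
#'
#' @param kmers A `kmer_set` from [enumerate_kmers()].
#' @return An object of class `state_store`: list with `keys` (sorted
#'   canonical k-mers), `k`, `n`, `codes` (integer state codes in `0:25`)
#'   and `emitted` (logical flags).
#' @export
build_store <- function(kmers) {
  if (!inherits(kmers, "kmer_set")) stop("'kmers' must be a kmer_set", call. = FALSE)
  if (kmers$n == 0L) stop("empty k-mer set", call. = FALSE)
  structure(
    list(keys = kmers$kmers, k = kmers$k, n = kmers$n,
         codes = integer(kmers$n), emitted = logical(kmers$n)),
    class = "state_store"
  )
}

#' @export
print.state_store <- function(x, ...) {
  cat(sprintf("state_store: %d vertices (k = %d), %d visited, %d emitted\n",
              x$n, x$k, sum(x$codes > 0L), sum(x$emitted)))
  invisible(x)
}

#' Minimal perfect index of vertices in a store
#'
#' Maps canonical k-mers to their slot in `[1, n]` (1-based in R); the map
#' is a bijection from the key set onto `1:n`. Alien keys map to `NA`.
#'
#' @param store A `state_store`.
#' @param kmers Character vector of canonical k-mers.
#' @return Integer vector of slot indices.
#' @export
store_index <- function(store, kmers) {
  match(kmers, store$keys)
}

#' Encode / decode vertex states as fixed-width codes
#'
#' The automaton's 26 states are stored as 5-bit codes (`0` = unvisited,
#' `1:25` = visited with the packed side pair). `encode_state()` validates
#' and packs a readable state description; `decode_state()` unpacks a code.
#' Codes `26:31` are representable in 5 bits but unassigned; decoding one
#' is a corruption error.
#'
#' @param state A list with `visited` (logical) and, when visited, `front`
#'   and `back` side characters (`A,C,G,T,*`).
#' @return `encode_state()`: an integer code in `0:25`. `decode_state()`:
#'   the readable list form.
#' @examples
#' decode_state(encode_state(list(visited = TRUE, front = "C", back = "A")))
#' @export
encode_state <- function(state) {
  if (!is.list(state) || is.null(state$visited)) {
    stop("state must be a list with at least a 'visited' element", call. = FALSE)
  }
  if (!isTRUE(state$visited)) return(0L)
  vertex_state(state$front, state$back)
}

#' @rdname encode_state
#' @param code Integer code in `0:25`.
#' @export
decode_state <- function(code) {
  if (length(code) != 1L || is.na(code) || code != as.integer(code) ||
      code < 0L || code >= bitwShiftL(1L, STATE_CODE_BITS)) {
    stop("state code must be a single integer representable in 5 bits", call. = FALSE)
  }
  if (code >= N_STATES) {
    stop(sprintf("corrupt state code %d: 5-bit value outside the 26 assigned states", code),
         call. = FALSE)
  }
  if (code == 0L) return(list(visited = FALSE))
  sides <- state_sides(as.integer(code))
  list(visited = TRUE, front = unname(sides[["front"]]), back = unname(sides[["back"]]))
}

#' Apply one automaton input to a vertex in the store
#'
#' Functional update: returns the store with the vertex's state advanced by
#' [transition()]. Updates to one vertex must be serialized; in this
#' single-threaded implementation that holds trivially, and the transition
#' join is order independent across vertices and instances.
#'
#' @param store A `state_store`.
#' @param vertex Canonical k-mer present in the store.
#' @param symbol Length-2 character symbol `(front, back)`.
#' @return The updated store.
#' @export
update_state <- function(store, vertex, symbol) {
  i <- store_index(store, vertex)
  if (is.na(i)) {
    stop(sprintf("vertex '%s' is not a key of the store (alien-key contract violation)",
                 vertex), call. = FALSE)
  }
  store$codes[i] <- transition(store$codes[i], symbol)
  store
}

#' Read a vertex's state from the store
#'
#' @inheritParams update_state
#' @return Integer state code in `0:25`.
#' @export
get_state <- function(store, vertex) {
  i <- store_index(store, vertex)
  if (is.na(i)) {
    stop(sprintf("vertex '%s' is not a key of the store", vertex), call. = FALSE)
  }
  store$codes[i]
}

# --- on-disk serialization -------------------------------------------------
# Versioned binary layout (little endian):
#   bytes 0-3   magic "CDBG"
#   int32       format version (1)
#   int32       k
#   int32       n
#   int32       payload width in bits per vertex (6 = 5 state + 1 emission)
#   n bytes     packed payload, one byte per vertex:
#                 bits 0-4 state code, bit 5 emission flag
#   rest        keys, newline-joined, UTF-8

#' Save / load a state store
#'
#' Writes the store (keys, state codes, emission flags) to a small
#' versioned binary file so a computed store can be built once and reused.
#'
#' @param store A `state_store`.
#' @param path File path.
#' @return `save_store()`: the path, invisibly. `load_store()`: the store.
#' @export
save_store <- function(store, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("CDBG"), con)
  writeBin(c(1L, store$k, store$n, 6L), con, size = 4L, endian = "little")
  payload <- as.raw(bitwOr(store$codes, bitwShiftL(as.integer(store$emitted), 5L)))
  writeBin(payload, con)
  writeBin(charToRaw(paste(store$keys, collapse = "\n")), con)
  invisible(path)
}

#' @rdname save_store
#' @export
load_store <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (magic != "CDBG") stop("not a state-store file (bad magic)", call. = FALSE)
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  if (hdr[1L] != 1L) stop(sprintf("unsupported store format version %d", hdr[1L]), call. = FALSE)
  k <- hdr[2L]; n <- hdr[3L]
  if (hdr[4L] != 6L) stop("unexpected payload width", call. = FALSE)
  payload <- as.integer(readBin(con, "raw", n))
  keys <- strsplit(rawToChar(readBin(con, "raw", n * (k + 1L) + 1024L)), "\n", fixed = TRUE)[[1L]]
  if (length(keys) != n) stop("corrupt store file: key count mismatch", call. = FALSE)
  structure(
    list(keys = keys, k = k, n = n,
         codes = bitwAnd(payload, 31L),
         emitted = bitwAnd(payload, 32L) > 0L),
    class = "state_store"
  )
}
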