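# The state-computation pass: walk every input sequence implicitly,
# derive one automaton input symbol per k-mer instance, and drive the
# per-vertex automata in the store. The graph itself is never built.

#' Split a sequence into maximal valid runs
#'
#' References may carry lowercase characters and non-A/C/G/T symbols
#' (typically runs of `N`). Lowercase is folded to uppercase; maximal runs
#' over `A,C,G,T` shorter than `k` are discarded; each surviving run is
#' treated as an independent input string with its own empty-symbol
#' sentinels, so no unitig ever spans a run boundary.
#'
#' @param sequence A single string.
#' @param k Odd integer >= 3.
#' @return A data frame with columns `start`, `end` (1-based, inclusive,
#'   positions in the original sequence) and `text` (the uppercased run).
#' @examples
#' split_valid_runs("ACGTNNACG", 3)
#' @export
split_valid_runs <- function(sequence, k) {
  k <- .check_k(k)
  if (length(sequence) != 1L || is.na(sequence)) {
    stop("'sequence' must be a single string", call. = FALSE)
  }
  up <- toupper(sequence)
  m <- gregexpr("[ACGT]+", up)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  keep <- len >= k
  if (!any(keep)) {
    return(data.frame(start = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE))
  }
  start <- start[keep]; len <- len[keep]
  data.frame(start = start, end = start + len - 1L,
             text = substring(up, start, start + len - 1L),
             stringsAsFactors = FALSE)
}

# runs of a whole collection, with sequence ids attached
.runs_of_collection <- function(sequences, k) {
  ids <- names(sequences)
  if (is.null(ids)) ids <- sprintf("seq%d", seq_along(sequences))
  out <- lapply(seq_along(sequences), function(i) {
    r <- split_valid_runs(sequences[[i]], k)
    if (nrow(r) > 0L) r$seq_id <- ids[[i]]
    r
  })
  out <- out[vapply(out, nrow, integer(1L)) > 0L]
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), seq_id = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

# Vectorized per-instance context table for one run. Mirrors
# derive_input_symbol() exactly (a property test asserts the agreement):
# columns are the instance, its canonical form, the entry orientation and
# the symbol's two side characters plus their packed index.
.instance_table <- function(text, k) {
  L <- nchar(text)
  m <- L - k + 1L
  pos <- seq_len(m)
  inst <- substring(text, pos, pos + k - 1L)
  rc_inst <- .rc_substrings(text, pos, k)
  is_can <- inst <= rc_inst
  canon <- ifelse(is_can, inst, rc_inst)

  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  p <- c("", chars[seq_len(m - 1L)])            # char before each instance
  n <- c(chars[pos[-1L] + k - 1L], "")          # char after each instance
  p_comp <- ifelse(p == "", "", .complement_chr(p))
  n_comp <- ifelse(n == "", "", .complement_chr(n))

  front <- ifelse(is_can, p, n_comp)
  back <- ifelse(is_can, n, p_comp)

  # crossing loops: flag palindromic flanking (k+1)-mers; edge j covers
  # positions j .. j+k (it precedes instance j+1 and succeeds instance j)
  if (m > 1L) {
    e <- substring(text, seq_len(m - 1L), seq_len(m - 1L) + k)
    e_rc <- .rc_substrings(text, seq_len(m - 1L), k + 1L)
    pal <- e == e_rc
    p_loop <- c(FALSE, pal)   # the edge before instance i is palindromic
    n_loop <- c(pal, FALSE)   # the edge after instance i is palindromic
    front[(p_loop & is_can) | (n_loop & !is_can)] <- "*"
    back[(n_loop & is_can) | (p_loop & !is_can)] <- "*"
  }
  front[front == ""] <- "*"
  back[back == ""] <- "*"

  f_idx <- match(front, SIDE_CHARS)
  b_idx <- match(back, SIDE_CHARS)
  data.frame(pos = pos, inst = inst, canon = canon, is_can = is_can,
             front = front, back = back,
             sym = (f_idx - 1L) * 5L + b_idx,
             stringsAsFactors = FALSE)
}

#' Compute all automaton states by implicit traversal
#'
#' Walks every run, derives the input symbol of each k-mer instance from
#' its immediate context (including empty-symbol sentinels at run
#' boundaries and crossing-loop detection) and folds it into the vertex's
#' automaton in the store. Because the per-side update is a commutative,
#' idempotent monotone join, the final store does not depend on the order
#' in which instances are processed; `chunks > 1` exercises this by
#' processing contiguous chunks of the instance stream out of order, and is
#' guaranteed to produce a bit-identical store.
#'
#' @param runs Data frame of runs as produced by [split_valid_runs()] /
#'   the collection helper used by [compact_dbg()] (only the `text` column
#'   is required).
#' @param store A freshly built (or partially computed) `state_store` whose
#'   key set is exactly the canonical k-mer content of `runs`.
#' @param chunks Number of contiguous chunks the instance stream is split
#'   into; chunk processing order is scrambled deterministically.
#' @return The store with every vertex in a visited state.
#' @export
compute_states <- function(runs, store, chunks = 1L) {
  if (!inherits(store, "state_store")) stop("'store' must be a state_store", call. = FALSE)
  k <- store$k
  tabs <- lapply(runs$text, .instance_table, k = k)
  idx <- unlist(lapply(tabs, function(t) match(t$canon, store$keys)), use.names = FALSE)
  sym <- unlist(lapply(tabs, `[[`, "sym"), use.names = FALSE)
  if (anyNA(idx)) {
    stop("inconsistent input: a k-mer instance is absent from the store",
         call. = FALSE)
  }
  delta <- transition_table()
  codes <- store$codes
  total <- length(idx)
  chunks <- max(1L, min(as.integer(chunks), total))
  bounds <- floor(seq(0L, total, length.out = chunks + 1L))
  for (c_i in rev(seq_len(chunks))) {     # deliberately not in stream order
    lo <- bounds[c_i] + 1L
    hi <- bounds[c_i + 1L]
    if (hi < lo) next
    for (t in lo:hi) {
      i <- idx[t]
      codes[i] <- delta[codes[i] + 1L, sym[t]]
    }
  }
  store$codes <- codes
  store
}
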