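# The per-vertex deterministic finite-state automaton.
#
# A visited vertex state is a pair of side statuses, one for the front and
# one for the back; each side is either "unique with edge character c"
# (c in A,C,G,T) or "ambiguous" (more than one distinct incident edge, or an
# epsilon-encoded sentinel edge). Together with the single unvisited start
# state this gives 1 + 5*5 = 26 states, packed into integer codes:
#
#   0           unvisited
#   1..25       visited; code = (front_idx - 1) * 5 + back_idx, where
#               front_idx/back_idx index into c("A","C","G","T","*")
#
# The code range [0, 25] is exactly the minimal 5-bit representation of the
# state set; encode_state()/decode_state() in the store module map between
# these codes and a readable form.
#
# Transitions are made per vertex, not per edge: each k-mer instance
# contributes a pair of side characters (see derive_input_symbol()) and both
# sides are updated simultaneously. Each side update is a monotone join --
# ambiguous is absorbing, a unique character stays only if re-observed --
# so folding any multiset of symbols is order independent, which is what
# makes chunked processing of the inputs legal.

N_STATES <- 26L
STATE_CODE_BITS <- 5L  # ceiling(log2(26))

.side_idx <- function(ch) {
  i <- match(ch, SIDE_CHARS)
  if (anyNA(i)) stop("side character must be one of A,C,G,T,*", call. = FALSE)
  i
}

#' Construct a visited vertex state
#'
#' @param front,back Side status characters: one of `"A","C","G","T"` for a
#'   side with a single unique incident edge, or `"*"` for an ambiguous side.
#' @return Integer state code in `1:25`.
#' @examples
#' vertex_state("C", "A")
#' vertex_state("*", "*")  # the single multi-in multi-out state
#' @export
vertex_state <- function(front, back) {
  f <- .side_idx(front)
  b <- .side_idx(back)
  (f - 1L) * 5L + b
}

#' The unvisited (initial) state code
#' @return The integer code `0`.
#' @export
unvisited_state <- function() 0L

#' Side statuses of a state code
#'
#' @param code Integer state code in `0:25`.
#' @return Named character vector `c(front=, back=)`, or `NA` entries for
#'   the unvisited state.
#' @export
state_sides <- function(code) {
  .check_state_code(code)
  if (code == 0L) return(c(front = NA_character_, back = NA_character_))
  f <- (code - 1L) %/% 5L + 1L
  b <- (code - 1L) %% 5L + 1L
  c(front = SIDE_CHARS[f], back = SIDE_CHARS[b])
}

.check_state_code <- function(code) {
  if (length(code) != 1L || is.na(code) || code != as.integer(code) ||
      code < 0L || code >= N_STATES) {
    stop("state code must be a single integer in [0, 25]", call. = FALSE)
  }
  invisible(as.integer(code))
}

.check_symbol <- function(symbol) {
  if (!is.character(symbol) || length(symbol) != 2L) {
    stop("symbol must be a length-2 character vector (front, back)", call. = FALSE)
  }
  c(.side_idx(symbol[[1L]]), .side_idx(symbol[[2L]]))
}

#' Automaton state transition
#'
#' Applies one input symbol (the pair of side characters derived from one
#' k-mer instance) to a vertex state. From the unvisited state each side
#' adopts the symbol's character; afterwards each side keeps a unique
#' character only while every further observation agrees with it, and
#' `"*"` (ambiguous) is absorbing. Both sides update simultaneously.
#'
#' @param state Integer state code in `0:25`.
#' @param symbol Length-2 character vector `(front, back)` over
#'   `A,C,G,T,*`, as produced by [derive_input_symbol()].
#' @return The new integer state code, always in `1:25`.
#' @examples
#' s <- transition(unvisited_state(), c("C", "A"))
#' state_sides(s)
#' state_sides(transition(s, c("A", "A")))  # front disagrees -> ambiguous
#' @export
transition <- function(state, symbol) {
  state <- .check_state_code(state)
  sym <- .check_symbol(symbol)
  if (state == 0L) {
    f <- sym[[1L]]
    b <- sym[[2L]]
  } else {
    f0 <- (state - 1L) %/% 5L + 1L
    b0 <- (state - 1L) %% 5L + 1L
    f <- if (f0 == sym[[1L]]) f0 else 5L
    b <- if (b0 == sym[[2L]]) b0 else 5L
  }
  (f - 1L) * 5L + b
}

#' State classes of visited vertices
#'
#' Visited states partition into four classes by whether each side has a
#' single unique incident edge ("single") or not ("multi"); "in" refers to
#' the front side and "out" to the back. Class sizes are 16, 4, 4 and 1.
#'
#' @param state Integer state code in `1:25` (querying the unvisited state
#'   is an error: after the state-computation pass no vertex may remain
#'   unvisited).
#' @return One of `"single-in single-out"`, `"multi-in single-out"`,
#'   `"single-in multi-out"`, `"multi-in multi-out"`.
#' @examples
#' state_class(vertex_state("G", "T"))
#' state_class(vertex_state("*", "A"))
#' @export
state_class <- function(state) {
  state <- .check_state_code(state)
  if (state == 0L) {
    stop("state_class() queried with the unvisited state; every vertex must be visited before classification",
         call. = FALSE)
  }
  f_amb <- ((state - 1L) %/% 5L + 1L) == 5L
  b_amb <- ((state - 1L) %% 5L + 1L) == 5L
  if (!f_amb && !b_amb) "single-in single-out"
  else if (f_amb && !b_amb) "multi-in single-out"
  else if (!f_amb && b_amb) "single-in multi-out"
  else "multi-in multi-out"
}

#' All input symbols of the automaton
#'
#' @return A 25 x 2 character matrix, one row per symbol `(front, back)`.
#' @keywords internal
all_symbols <- function() {
  g <- expand.grid(back = SIDE_CHARS, front = SIDE_CHARS,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  cbind(front = g$front, back = g$back)
}

#' Full transition table
#'
#' The 26 x 25 table of [transition()] over every state code (rows, codes
#' `0:25`) and every input symbol (columns, indexed `(front_idx-1)*5 +
#' back_idx`). Generated from the two per-side update rules rather than
#' hard-coded; cached after first use.
#'
#' @return Integer matrix with dimnames giving states and symbols.
#' @export
transition_table <- function() {
  cached <- .cdbg_cache$delta
  if (!is.null(cached)) return(cached)
  syms <- all_symbols()
  tab <- matrix(NA_integer_, nrow = N_STATES, ncol = nrow(syms))
  for (s in 0:(N_STATES - 1L)) {
    for (j in seq_len(nrow(syms))) {
      tab[s + 1L, j] <- transition(s, syms[j, ])
    }
  }
  rownames(tab) <- c("unvisited",
                     apply(all_symbols(), 1L, function(r) paste0("(", r[1L], ",", r[2L], ")")))
  colnames(tab) <- apply(syms, 1L, function(r) paste0("(", r[1L], ",", r[2L], ")"))
  .cdbg_cache$delta <- tab
  tab
}

.cdbg_cache <- new.env(parent = emptyenv())

#' Enumerate all reachable automaton states
#'
#' Computes the closure of [transition()] from the unvisited state over all
#' input symbols and returns it together with the initial state. The result
#' partitions into the unvisited state plus the four visited classes.
#'
#' @return Integer vector of state codes (sorted); its length is 26.
#' @examples
#' length(enumerate_reachable_states())  # 26
#' @export
enumerate_reachable_states <- function() {
  syms <- all_symbols()
  seen <- rep(FALSE, N_STATES)
  seen[0L + 1L] <- TRUE
  frontier <- 0L
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (s in frontier) {
      for (j in seq_len(nrow(syms))) {
        t <- transition(s, syms[j, ])
        if (!seen[t + 1L]) {
          seen[t + 1L] <- TRUE
          nxt <- c(nxt, t)
        }
      }
    }
    frontier <- nxt
  }
  which(seen) - 1L
}
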