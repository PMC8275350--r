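# DNA-string primitives and the bidirected, edge-centric de Bruijn graph
# semantics: canonicalization, edge incidence sides, glue, and derivation of
# the per-vertex automaton input symbols from sequence context.
#
# Conventions used throughout the package:
#   * vertices are canonical k-mers (lexicographic min of a k-mer and its
#     reverse complement); k must be odd so no k-mer is its own reverse
#     complement and canonical orientation is always well defined;
#   * each vertex has two sides, "front" and "back"; reading a vertex label
#     from front to back spells the canonical k-mer;
#   * an edge is a (k+1)-mer; it touches the back of u when its k-prefix is
#     canonical (else u's front), and the front of v when its k-suffix is
#     canonical (else v's back);
#   * the empty symbol (epsilon) marks the absent edge at the two ends of
#     every input string, and is represented in-band as "".

#' Characters a vertex side can carry
#'
#' The four nucleotides plus `"*"`, the ambiguity marker (more than one
#' distinct incident edge, or an epsilon-encoded sentinel edge).
#' @keywords internal
SIDE_CHARS <- c("A", "C", "G", "T", "*")

.complement_chr <- function(s) chartr("ACGT", "TGCA", s)

.check_dna <- function(s, arg = "s") {
  if (!is.character(s) || anyNA(s)) {
    stop(sprintf("'%s' must be a character vector without NAs", arg), call. = FALSE)
  }
  bad <- grepl("[^ACGT]", s)
  if (any(bad)) {
    stop(sprintf("invalid alphabet in '%s': %s (only A/C/G/T allowed)",
                 arg, s[bad][1L]), call. = FALSE)
  }
  invisible(s)
}

.check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 3L || k %% 2L == 0L) {
    stop("k must be a single odd integer >= 3", call. = FALSE)
  }
  as.integer(k)
}

#' Reverse complement of DNA strings
#'
#' @param s Character vector of strings over A/C/G/T.
#' @return Character vector of the same length with each string reversed and
#'   complemented (A<->T, C<->G). The operation is an involution.
#' @examples
#' reverse_complement("ATG")   # "CAT"
#' reverse_complement("CATG")  # "CATG", a palindromic 4-mer
#' @export
reverse_complement <- function(s) {
  .check_dna(s)
  comp <- .complement_chr(s)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""),
         character(1L), USE.NAMES = FALSE)
}

#' Canonical form of DNA strings
#'
#' The canonical form is the lexicographic minimum of a string and its
#' reverse complement; it is the identity used for graph vertices.
#'
#' @param x Character vector of strings over A/C/G/T.
#' @return Character vector of canonical forms; idempotent.
#' @examples
#' canonical("CAT")  # "ATG"
#' canonical("GAC")  # "GAC"
#' @export
canonical <- function(x) {
  rc <- reverse_complement(x)
  ifelse(x <= rc, x, rc)
}

#' Test whether a DNA string is palindromic (equals its reverse complement)
#'
#' Only even-length strings can be palindromic; a palindromic (k+1)-mer is
#' exactly the crossing-loop case, an edge incident twice to the same side
#' of one vertex.
#' @param s Character vector over A/C/G/T.
#' @return Logical vector.
#' @export
is_palindromic <- function(s) {
  s == reverse_complement(s)
}

#' Endpoints and incidence sides of a de Bruijn graph edge
#'
#' An edge is a (k+1)-mer `e`. Its first endpoint is the canonical form of
#' the k-prefix of `e`, touched on its back side when the k-prefix is
#' already canonical and on its front side otherwise; the second endpoint is
#' the canonical form of the k-suffix, touched on its front side when the
#' k-suffix is canonical and on its back side otherwise. Loops (both
#' endpoints equal) are permitted.
#'
#' @param e A single (k+1)-mer over A/C/G/T, with k odd.
#' @return A list with elements `first` and `second`, each a list with
#'   `vertex` (canonical k-mer) and `side` (`"front"` or `"back"`).
#' @examples
#' edge_endpoints("CGAC")
#' edge_endpoints("CATG")  # palindromic loop: both incidences on ATG's front
#' @export
edge_endpoints <- function(e) {
  if (length(e) != 1L) stop("'e' must be a single string", call. = FALSE)
  .check_dna(e, "e")
  k <- nchar(e) - 1L
  if (k < 3L || k %% 2L == 0L) {
    stop("edge length must be k+1 with k odd and >= 3", call. = FALSE)
  }
  pre <- substr(e, 1L, k)
  suf <- substr(e, 2L, k + 1L)
  pre_c <- canonical(pre)
  suf_c <- canonical(suf)
  list(
    first  = list(vertex = pre_c, side = if (pre == pre_c) "back" else "front"),
    second = list(vertex = suf_c, side = if (suf == suf_c) "front" else "back")
  )
}

#' Glue two overlapping strings
#'
#' `glue(x, y, l)` appends to `x` the part of `y` after its length-`l`
#' prefix, requiring that the length-`l` suffix of `x` equals that prefix.
#' Unitig spellings are built by gluing consecutive vertex spellings with
#' overlap k-1.
#'
#' @param x,y Single DNA strings.
#' @param l Overlap length, `0 <= l <= min(nchar(x), nchar(y))`.
#' @return The glued string of length `nchar(x) + nchar(y) - l`.
#' @examples
#' glue("GAC", "ACA", 2)   # "GACA"
#' glue("ATGT", "GTC", 2)  # "ATGTC"
#' @export
glue <- function(x, y, l) {
  if (length(x) != 1L || length(y) != 1L) stop("x and y must be single strings", call. = FALSE)
  l <- as.integer(l)
  if (l < 0L || l > min(nchar(x), nchar(y))) {
    stop("overlap length out of range", call. = FALSE)
  }
  if (substr(x, nchar(x) - l + 1L, nchar(x)) != substr(y, 1L, l)) {
    stop(sprintf("glue overlap mismatch between '%s' and '%s' at length %d",
                 x, y, l), call. = FALSE)
  }
  paste0(x, substr(y, l + 1L, nchar(y)))
}

#' Automaton input symbol for one k-mer instance
#'
#' Derives the pair of per-side edge characters fed to a vertex's automaton
#' from the context of one instance of its k-mer in an input sequence:
#' the instance `x` exactly as it appears (possibly non-canonical), the
#' character `p` immediately before it and the character `n` immediately
#' after it (`""` for the empty symbol at a run boundary).
#'
#' The per-side encoding is orientation invariant: the front character `c`
#' is the one for which the incident edge reads `c %+% label` with the label
#' as suffix, and the back character `d` the one for which it reads
#' `label %+% d`. Concretely, when `x` is canonical the symbol is `(p, n)`;
#' otherwise it is `(complement(n), complement(p))`. An empty-symbol side
#' maps to the ambiguity marker `"*"`. If the flanking (k+1)-mer `p x`
#' (resp. `x n`) is palindromic the edge is a crossing loop, incident twice
#' to one side, and that side is forced to `"*"` as well.
#'
#' @param x A single k-mer instance as it appears in the sequence.
#' @param p,n Preceding / succeeding character, or `""` at a boundary.
#' @return Named character vector `c(front=, back=)` with values in
#'   `A,C,G,T,*`.
#' @examples
#' derive_input_symbol("GAC", "C", "A")  # front "C", back "A"
#' derive_input_symbol("CAT", "A", "G")  # CATG is palindromic: front "*"
#' derive_input_symbol("CGA", "",  "C")  # sentinel: front "*"
#' @export
derive_input_symbol <- function(x, p = "", n = "") {
  .check_dna(x, "x")
  for (ch in list(p, n)) {
    if (!(is.character(ch) && length(ch) == 1L && (ch == "" || ch %in% c("A", "C", "G", "T")))) {
      stop("p and n must each be one of A,C,G,T or \"\"", call. = FALSE)
    }
  }
  is_can <- x == canonical(x)
  comp1 <- function(c) if (c == "") "" else .complement_chr(c)
  if (is_can) {
    front <- p
    back <- n
  } else {
    front <- comp1(n)
    back <- comp1(p)
  }
  # crossing loops: a palindromic flanking (k+1)-mer touches one side twice
  p_loop <- p != "" && is_palindromic(paste0(p, x))
  n_loop <- n != "" && is_palindromic(paste0(x, n))
  if (p_loop) { if (is_can) front <- "*" else back <- "*" }
  if (n_loop) { if (is_can) back <- "*" else front <- "*" }
  if (front == "") front <- "*"
  if (back == "") back <- "*"
  c(front = front, back = back)
}
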