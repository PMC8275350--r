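# The extraction pass: walk each run again, apply the initiation /
# termination rules on the computed state classes, spell each maximal
# unitig by gluing consecutive vertex spellings, canonicalize, and emit
# every maximal unitig exactly once using a per-vertex emission flag.

#' Side through which a walk enters a vertex
#'
#' A walk spelling an input run enters a vertex through its front side when
#' the k-mer instance (as it appears in the run) is canonical, and through
#' its back side otherwise. For the first vertex of a run, which has no
#' entering edge, the entry side is defined as the side opposite its exit
#' side -- which reduces to the same rule.
#'
#' @param instance A single k-mer as it appears in the sequence.
#' @return `"front"` or `"back"`.
#' @examples
#' entry_side("ATG")  # front
#' entry_side("CAT")  # back: CAT is the non-canonical orientation of ATG
#' @export
entry_side <- function(instance) {
  if (instance == canonical(instance)) "front" else "back"
}

#' Unitig initiation / termination rules
#'
#' During the extraction walk, a vertex initiates a maximal unitig when its
#' state class is multi-in multi-out, when it is entered through the front
#' and is multi-in single-out, or when it is entered through the back and
#' is single-in multi-out; symmetrically it terminates when multi-in
#' multi-out, entered front and single-in multi-out, or entered back and
#' multi-in single-out. (The walk-level rules additionally initiate after
#' any termination and terminate before any initiation; those
#' cross-referring conditions are applied by [extract_maximal_unitigs()]
#' and deliberately do not recurse.)
#'
#' @param class A state class string from [state_class()].
#' @param entry `"front"` or `"back"`.
#' @return Logical.
#' @export
initiates <- function(class, entry) {
  class == "multi-in multi-out" ||
    (entry == "front" && class == "multi-in single-out") ||
    (entry == "back" && class == "single-in multi-out")
}

#' @rdname initiates
#' @export
terminates <- function(class, entry) {
  class == "multi-in multi-out" ||
    (entry == "front" && class == "single-in multi-out") ||
    (entry == "back" && class == "multi-in single-out")
}

#' Spell a walk from its vertex labels
#'
#' The spelling of a walk is the glue of the per-vertex seen spellings with
#' overlap k-1, where a vertex's seen spelling is its label when entered
#' through the front and the label's reverse complement when entered
#' through the back. Given the vertex labels in walk order, the
#' orientation of each vertex is resolved by the overlap constraint (the
#' label orientation is preferred when both glue).
#'
#' @param labels Character vector of k-mers, the walk's vertices in order.
#' @return The spelled string of length `k + (length(labels) - 1)`.
#' @examples
#' spell_walk(c("GAC", "ACA", "ATG"))         # "GACAT"
#' spell_walk(c("GAC", "ACA", "ATG", "ATG"))  # "GACATG"
#' @export
spell_walk <- function(labels) {
  .check_dna(labels, "labels")
  k <- nchar(labels[[1L]])
  if (any(nchar(labels) != k)) stop("all labels must have equal length", call. = FALSE)
  if (length(labels) == 1L) return(labels[[1L]])
  fits <- function(acc, s) substr(acc, nchar(acc) - k + 2L, nchar(acc)) == substr(s, 1L, k - 1L)
  for (first in c(labels[[1L]], reverse_complement(labels[[1L]]))) {
    acc <- first
    ok <- TRUE
    for (lab in labels[-1L]) {
      rc <- reverse_complement(lab)
      s <- if (fits(acc, lab)) lab else if (fits(acc, rc)) rc else NULL
      if (is.null(s)) { ok <- FALSE; break }
      acc <- glue(acc, s, k - 1L)
    }
    if (ok) return(acc)
  }
  stop("labels do not form a walk: consecutive vertices fail the (k-1)-overlap",
       call. = FALSE)
}

#' Canonical spelling of a unitig
#'
#' @param s A DNA string.
#' @return `min(s, reverse_complement(s))`; reported unitigs always use
#'   this form.
#' @examples
#' canonical_spelling("GACAT")  # "ATGTC"
#' @export
canonical_spelling <- function(s) {
  canonical(s)
}

#' Extract all maximal unitigs
#'
#' Walks every run once more, using the computed state classes to decide
#' where maximal unitigs start and end, and emits each distinct maximal
#' unitig exactly once (test-and-set on the emission flag of its signature
#' vertex: the canonical form of the first k-mer of its canonical
#' spelling). The unitigs form a node decomposition of the graph: every
#' distinct canonical k-mer occurs in exactly one unitig, exactly once.
#'
#' @param runs Data frame of runs (columns `text`, and optionally `seq_id`,
#'   `start` for tiling coordinates).
#' @param store A `state_store` on which [compute_states()] has completed
#'   for the same runs.
#' @return A list with:
#'   * `unitigs`: data frame `id`, `spelling` (canonical), `length`,
#'     `first_vertex`, `last_vertex`; ids are assigned in sorted order of
#'     canonical spelling, so output is deterministic;
#'   * `tilings`: data frame `seq_id`, `run_start`, `step`, `unitig_id`,
#'     `orientation` (`"+"` canonical, `"-"` reverse), `start` (1-based
#'     position of the step in the original sequence); consecutive steps of
#'     one run overlap by exactly k-1 characters;
#'   * `store`: the store with emission flags set.
#' @export
extract_maximal_unitigs <- function(runs, store) {
  if (!inherits(store, "state_store")) stop("'store' must be a state_store", call. = FALSE)
  k <- store$k
  if (any(store$codes == 0L)) {
    stop("store contains unvisited vertices; run compute_states() first",
         call. = FALSE)
  }
  seq_ids <- if ("seq_id" %in% names(runs)) runs$seq_id else sprintf("seq%d", seq_len(nrow(runs)))
  run_starts <- if ("start" %in% names(runs)) runs$start else rep(1L, nrow(runs))

  spellings <- character(0)
  tile <- list()
  emitted <- store$emitted
  codes <- store$codes

  for (r in seq_len(nrow(runs))) {
    txt <- runs$text[[r]]
    tab <- .instance_table(txt, k)
    idx <- match(tab$canon, store$keys)
    if (anyNA(idx)) stop("inconsistent input: k-mer absent from store", call. = FALSE)
    code <- codes[idx]
    if (any(code == 0L)) {
      stop("extraction walk reached an unvisited vertex (invariant violation)",
           call. = FALSE)
    }
    f_amb <- ((code - 1L) %/% 5L + 1L) == 5L
    b_amb <- ((code - 1L) %% 5L) + 1L == 5L
    cls_mm <- f_amb & b_amb
    cls_ms <- f_amb & !b_amb
    cls_sm <- !f_amb & b_amb
    front_entry <- tab$is_can

    init3 <- cls_mm | (front_entry & cls_ms) | (!front_entry & cls_sm)
    term3 <- cls_mm | (front_entry & cls_sm) | (!front_entry & cls_ms)
    m <- nrow(tab)
    starts <- which(init3 | c(TRUE, term3[-m]))
    ends <- which(term3 | c(init3[-1L], TRUE))
    if (length(starts) != length(ends) || any(starts > ends)) {
      stop("initiation/termination rules produced unpaired boundaries (invariant violation)",
           call. = FALSE)
    }
    for (j in seq_along(starts)) {
      s_i <- starts[[j]]; e_i <- ends[[j]]
      seen <- substring(txt, s_i, e_i + k - 1L)
      cs <- canonical(seen)
      sig <- tab$canon[[if (seen == cs) s_i else e_i]]
      si <- match(sig, store$keys)
      if (!emitted[si]) {
        emitted[si] <- TRUE
        spellings <- c(spellings, cs)
      }
      tile[[length(tile) + 1L]] <- list(
        seq_id = seq_ids[[r]], run_start = run_starts[[r]], step = j,
        spelling = cs, orientation = if (seen == cs) "+" else "-",
        start = run_starts[[r]] + s_i - 1L
      )
    }
  }

  ord <- sort(unique(spellings), method = "radix")
  if (length(ord) != length(spellings)) {
    stop("a unitig was emitted twice (emission invariant violation)", call. = FALSE)
  }
  unitigs <- data.frame(
    id = seq_along(ord),
    spelling = ord,
    length = nchar(ord),
    first_vertex = canonical(substr(ord, 1L, k)),
    last_vertex = canonical(substring(ord, nchar(ord) - k + 1L)),
    stringsAsFactors = FALSE
  )
  tilings <- data.frame(
    seq_id = vapply(tile, `[[`, character(1L), "seq_id"),
    run_start = vapply(tile, function(x) as.integer(x$run_start), integer(1L)),
    step = vapply(tile, function(x) as.integer(x$step), integer(1L)),
    unitig_id = match(vapply(tile, `[[`, character(1L), "spelling"), ord),
    orientation = vapply(tile, `[[`, character(1L), "orientation"),
    start = vapply(tile, function(x) as.integer(x$start), integer(1L)),
    stringsAsFactors = FALSE
  )
  store$emitted <- emitted
  list(unitigs = unitigs, tilings = tilings, store = store)
}
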