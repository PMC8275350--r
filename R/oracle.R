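# Ground truth: a naive compactor that builds the explicit adjacency of
# the bidirected graph and enumerates maximal non-branching paths, plus
# the output validator. This code path deliberately shares no
# classification logic with the automaton pipeline (reverse complements
# here come from Biostrings, side statuses from an explicit incidence
# table), so agreement between the two is meaningful evidence.

.rc_bio <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.canon_bio <- function(x) {
  rc <- .rc_bio(x)
  ifelse(x <= rc, x, rc)
}

# Explicit incidence table over all (k+1)-mer instances of the runs, plus
# the empty-symbol sentinels at run boundaries. For each (vertex, side)
# it records the distinct incident edges -- a same-side loop (palindromic
# (k+1)-mer) contributes two incidences of its single edge -- and whether
# a sentinel touches the side.
.adjacency <- function(runs, k) {
  inc <- lapply(runs$text, function(txt) {
    L <- nchar(txt)
    m <- L - k + 1L
    # sentinels: the entering side of the first instance, exiting side of the last
    first <- substr(txt, 1L, k)
    last <- substring(txt, L - k + 1L)
    sent <- data.frame(
      vertex = .canon_bio(c(first, last)),
      side = c(if (first == .canon_bio(first)) "front" else "back",
               if (last == .canon_bio(last)) "back" else "front"),
      edge = "", mult = 1L, stringsAsFactors = FALSE)
    if (m < 2L) return(sent)
    e <- substring(txt, seq_len(m - 1L), seq_len(m - 1L) + k)
    pre <- substr(e, 1L, k)
    suf <- substring(e, 2L)
    pre_c <- .canon_bio(pre)
    suf_c <- .canon_bio(suf)
    e_c <- .canon_bio(e)
    pre_side <- ifelse(pre == pre_c, "back", "front")
    suf_side <- ifelse(suf == suf_c, "front", "back")
    crossing <- pre_c == suf_c & pre_side == suf_side
    data.frame(
      vertex = c(sent$vertex, pre_c[!crossing], suf_c[!crossing], pre_c[crossing]),
      side = c(sent$side, pre_side[!crossing], suf_side[!crossing], pre_side[crossing]),
      edge = c(sent$edge, e_c[!crossing], e_c[!crossing], e_c[crossing]),
      mult = c(sent$mult, rep(1L, 2L * sum(!crossing)), rep(2L, sum(crossing))),
      stringsAsFactors = FALSE
    )
  })
  inc <- do.call(rbind, inc)
  # distinct edges per (vertex, side); repeated instances of one edge count
  # once, but a crossing loop keeps multiplicity 2
  key <- paste(inc$vertex, inc$side, inc$edge, sep = "\r")
  inc <- inc[order(key, -inc$mult), , drop = FALSE]
  inc[!duplicated(paste(inc$vertex, inc$side, inc$edge, sep = "\r")), , drop = FALSE]
}

#' Naive compacted de Bruijn graph construction (reference implementation)
#'
#' Builds the bidirected graph explicitly: every (k+1)-mer instance is
#' recorded as an edge incidence on the sides it touches (a palindromic
#' (k+1)-mer touches one side twice; sentinel sides at run boundaries are
#' marked), a side is branching unless it carries exactly one incidence
#' and no sentinel, and the maximal unitigs are enumerated by walking
#' chains of mutually non-branching links. Quadratic bookkeeping and no
#' clever data structures: this is the ground-truth implementation used to
#' check the automaton pipeline, not a tool for large inputs.
#'
#' @param sequences Character vector of reference sequences.
#' @param k Odd integer >= 3.
#' @return Sorted character vector of canonical maximal-unitig spellings.
#' @export
naive_compact <- function(sequences, k) {
  k <- .check_k(k)
  runs <- .runs_of_collection(sequences, k)
  if (nrow(runs) == 0L) stop("no valid k-mer in input", call. = FALSE)
  inc <- .adjacency(runs, k)

  side_key <- paste(inc$vertex, inc$side, sep = "\r")
  tot <- rowsum(inc$mult, side_key)  # sentinel incidences count too
  tot_map <- stats::setNames(as.integer(tot), rownames(tot))
  vertices <- sort(unique(inc$vertex), method = "radix")
  rc_map <- stats::setNames(.rc_bio(vertices), vertices)

  # unique-side map: (vertex, side) -> its single incident edge, when the
  # side has exactly one incidence and it is not a sentinel
  unique_edge <- new.env(parent = emptyenv())
  for (i in which(inc$edge != "" & unname(tot_map[side_key]) == 1L)) {
    assign(side_key[[i]], inc$edge[[i]], envir = unique_edge)
  }

  # endpoint map: canonical (k+1)-mer -> its two (vertex, side) incidences
  edges <- unique(inc$edge[inc$edge != ""])
  ends_map <- new.env(parent = emptyenv())
  if (length(edges) > 0L) {
    pre <- substr(edges, 1L, k); suf <- substring(edges, 2L)
    pre_c <- .canon_bio(pre); suf_c <- .canon_bio(suf)
    pre_side <- ifelse(pre == pre_c, "back", "front")
    suf_side <- ifelse(suf == suf_c, "front", "back")
    for (j in seq_along(edges)) {
      assign(edges[[j]],
             list(list(vertex = pre_c[[j]], side = pre_side[[j]]),
                  list(vertex = suf_c[[j]], side = suf_side[[j]])),
             envir = ends_map)
    }
  }
  link <- function(vertex, side) {
    skey <- paste(vertex, side, sep = "\r")
    if (!exists(skey, envir = unique_edge, inherits = FALSE)) return(NULL)
    edge <- get(skey, envir = unique_edge)
    ends <- get(edge, envir = ends_map)
    nb <- if (ends[[1L]]$vertex == vertex && ends[[1L]]$side == side) ends[[2L]] else ends[[1L]]
    nkey <- paste(nb$vertex, nb$side, sep = "\r")
    if (!exists(nkey, envir = unique_edge, inherits = FALSE)) return(NULL)
    if (get(nkey, envir = unique_edge) != edge) return(NULL)
    nb
  }

  opposite <- function(s) if (s == "front") "back" else "front"
  done <- new.env(parent = emptyenv())
  spellings <- character(0)
  for (v in vertices) {
    if (exists(v, envir = done, inherits = FALSE)) next
    # chain through v: extend backwards through the front, forwards through
    # the back, stopping at non-mutual links or when the chain closes
    chain <- list(list(vertex = v, enter = "front"))  # enter side of each step
    in_chain <- new.env(parent = emptyenv())
    assign(v, TRUE, envir = in_chain)
    repeat {   # extend forward: exit through side opposite the entry
      tail <- chain[[length(chain)]]
      nb <- link(tail$vertex, opposite(tail$enter))
      if (is.null(nb) || exists(nb$vertex, envir = in_chain, inherits = FALSE)) break
      chain[[length(chain) + 1L]] <- list(vertex = nb$vertex, enter = nb$side)
      assign(nb$vertex, TRUE, envir = in_chain)
    }
    repeat {   # extend backward from the head
      head <- chain[[1L]]
      nb <- link(head$vertex, head$enter)
      if (is.null(nb) || exists(nb$vertex, envir = in_chain, inherits = FALSE)) break
      chain <- c(list(list(vertex = nb$vertex, enter = opposite(nb$side))), chain)
      assign(nb$vertex, TRUE, envir = in_chain)
    }
    spell <- NULL
    for (step in chain) {
      assign(step$vertex, TRUE, envir = done)
      s <- if (step$enter == "front") step$vertex else rc_map[[step$vertex]]
      spell <- if (is.null(spell)) s else {
        stopifnot(substring(spell, nchar(spell) - k + 2L) == substr(s, 1L, k - 1L))
        paste0(spell, substring(s, k))
      }
    }
    spellings <- c(spellings, spell)
  }
  sort(.canon_bio(spellings), method = "radix")
}

#' Validate a set of unitigs against the input sequences
#'
#' Performs the two defining checks of a correct compaction:
#' (i) node decomposition -- every distinct canonical k-mer of the input
#' occurs in exactly one unitig, exactly once, and the unitigs contain no
#' other k-mers; (ii) reconstruction -- every maximal A/C/G/T run of every
#' input sequence can be spelled as a tiling of complete oriented unitigs
#' glued with overlap k-1.
#'
#' @param sequences Character vector of reference sequences.
#' @param unitigs Character vector of unitig spellings (canonical), or a
#'   unitig data frame from [compact_dbg()].
#' @param k Odd integer >= 3.
#' @return A list with logicals `node_decomposition`, `reconstruction`,
#'   `ok` (both), and a character vector `diagnostics` describing any
#'   failures.
#' @export
validate_unitigs <- function(sequences, unitigs, k) {
  k <- .check_k(k)
  if (is.data.frame(unitigs)) unitigs <- unitigs$spelling
  diag <- character(0)

  runs <- .runs_of_collection(sequences, k)
  input_kmers <- sort(unique(unlist(lapply(runs$text, function(txt) {
    m <- nchar(txt) - k + 1L
    .canon_bio(substring(txt, seq_len(m), seq_len(m) + k - 1L))
  }))), method = "radix")

  unitig_kmers <- unlist(lapply(unitigs, function(u) {
    m <- nchar(u) - k + 1L
    .canon_bio(substring(u, seq_len(m), seq_len(m) + k - 1L))
  }))
  node_ok <- TRUE
  dup <- unique(unitig_kmers[duplicated(unitig_kmers)])
  if (length(dup) > 0L) {
    node_ok <- FALSE
    diag <- c(diag, sprintf("k-mer occurs more than once across unitigs: %s",
                            paste(utils::head(dup, 5L), collapse = ", ")))
  }
  missing <- setdiff(input_kmers, unitig_kmers)
  if (length(missing) > 0L) {
    node_ok <- FALSE
    diag <- c(diag, sprintf("%d input k-mer(s) absent from the unitigs (e.g. %s)",
                            length(missing), missing[[1L]]))
  }
  alien <- setdiff(unitig_kmers, input_kmers)
  if (length(alien) > 0L) {
    node_ok <- FALSE
    diag <- c(diag, sprintf("%d unitig k-mer(s) absent from the input (e.g. %s)",
                            length(alien), alien[[1L]]))
  }

  # reconstruction: greedy tiling; thanks to the node decomposition each
  # canonical k-mer starts at most one oriented unitig
  starts <- new.env(parent = emptyenv())
  for (i in seq_along(unitigs)) {
    u <- unitigs[[i]]
    for (o in c("+", "-")) {
      s <- if (o == "+") u else .rc_bio(u)
      key <- substr(s, 1L, k)
      hit <- if (exists(key, envir = starts, inherits = FALSE)) {
        get(key, envir = starts)
      } else list()
      hit[[length(hit) + 1L]] <- s
      assign(key, hit, envir = starts)
    }
  }
  recon_ok <- TRUE
  for (r in seq_len(nrow(runs))) {
    txt <- runs$text[[r]]
    L <- nchar(txt)
    pos <- 1L
    ok <- TRUE
    while (pos <= L - k + 1L) {
      key <- substr(txt, pos, pos + k - 1L)
      cand <- if (exists(key, envir = starts, inherits = FALSE)) get(key, envir = starts) else list()
      step <- NULL
      for (s in cand) {
        if (pos + nchar(s) - 1L <= L && substr(txt, pos, pos + nchar(s) - 1L) == s) {
          step <- s
          break
        }
      }
      if (is.null(step)) { ok <- FALSE; break }
      if (pos + nchar(step) - 1L == L) { pos <- L - k + 2L; break }
      pos <- pos + nchar(step) - (k - 1L)
    }
    if (!ok || pos != L - k + 2L) {
      recon_ok <- FALSE
      diag <- c(diag, sprintf("run %d (%s) is not a tiling of complete unitigs",
                              r, runs$seq_id[[r]]))
    }
  }

  list(node_decomposition = node_ok, reconstruction = recon_ok,
       ok = node_ok && recon_ok, diagnostics = diag)
}
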