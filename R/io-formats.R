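# Readers and writers for the formats the tool touches: FASTA in,
# unitig FASTA / GFA1 / GFA2 out. FASTA parsing is delegated to
# Biostrings, which handles gzip compression, wrapped lines, CRLF endings
# and lowercase/IUPAC characters; writers are deterministic (fixed record
# order, no timestamps) so repeated runs are byte-identical.

#' Read FASTA files
#'
#' @param paths Character vector of FASTA file paths (plain or gzip).
#' @return A data frame with columns `id` (first header token),
#'   `description` (remainder of the header) and `sequence`, in file
#'   order. Duplicate ids are disambiguated with a numeric suffix and a
#'   warning.
#' @export
read_fasta <- function(paths) {
  recs <- lapply(paths, function(p) {
    set <- tryCatch(
      Biostrings::readDNAStringSet(p),
      error = function(e) stop(sprintf("failed to parse FASTA file '%s': %s",
                                       p, conditionMessage(e)), call. = FALSE)
    )
    hdr <- names(set)
    data.frame(
      id = sub("\\s.*$", "", hdr),
      description = ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), ""),
      sequence = as.character(set),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  if (anyDuplicated(out$id)) {
    warning("duplicate sequence ids in input; disambiguating with suffixes")
    out$id <- make.unique(out$id, sep = "_dup")
  }
  out
}

#' Write a collection of sequences as FASTA
#'
#' @param records Data frame with columns `id` and `sequence` (and
#'   optionally `description`).
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 80L) {
  con <- file(path, "wb")  # binary: byte-identical output on any platform
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    desc <- if (!is.null(records$description) && nzchar(records$description[[i]])) {
      paste0(" ", records$description[[i]])
    } else ""
    writeLines(paste0(">", records$id[[i]], desc), con, sep = "\n")
    writeLines(.wrap_seq(records$sequence[[i]], width), con, sep = "\n")
  }
  invisible(path)
}

.wrap_seq <- function(s, width) {
  n <- nchar(s)
  if (n <= width) return(s)
  starts <- seq(1L, n, by = width)
  substring(s, starts, pmin(starts + width - 1L, n))
}

#' Write maximal unitigs as FASTA
#'
#' One record per unitig, header `>cf_<id> LN:i:<length>`, in id order
#' (ids are assigned by sorted canonical spelling, so the file is
#' deterministic).
#'
#' @param unitigs Unitig data frame from [compact_dbg()] /
#'   [extract_maximal_unitigs()].
#' @param path Output file path.
#' @param width Line-wrap width.
#' @return The path, invisibly.
#' @export
write_unitigs_fasta <- function(unitigs, path, width = 80L) {
  records <- data.frame(
    id = sprintf("cf_%d", unitigs$id),
    description = sprintf("LN:i:%d", unitigs$length),
    sequence = unitigs$spelling,
    stringsAsFactors = FALSE
  )
  write_fasta(records, path, width = width)
}

# per-run groups of tiling steps, in deterministic order
.tiling_runs <- function(tilings) {
  key <- paste(tilings$seq_id, tilings$run_start, sep = "\r")
  split(tilings, factor(key, levels = unique(key)))
}

#' Write the compacted graph in GFA format
#'
#' Emits the compacted de Bruijn graph: one segment per maximal unitig
#' (canonical spelling) and one link per realized adjacency, i.e. per pair
#' of consecutive tiling steps observed in the input (links are
#' deduplicated as unordered oriented pairs). Every overlap is exactly
#' `k-1` characters. Each input run is written as a path (GFA1 `P` line)
#' or ordered group (GFA2 `O` line); expanding a path by gluing its
#' oriented segments with `k-1` overlaps reproduces the run.
#'
#' @param graph A `cdbg` object from [compact_dbg()].
#' @param path Output file path.
#' @param version GFA version, `1` or `2`.
#' @return The path, invisibly.
#' @export
write_gfa <- function(graph, path, version = 1L) {
  if (!inherits(graph, "cdbg")) stop("'graph' must be a cdbg object", call. = FALSE)
  if (!version %in% c(1L, 2L)) stop("version must be 1 or 2", call. = FALSE)
  u <- graph$unitigs
  k <- graph$k
  seg <- sprintf("cf_%d", u$id)
  seg_len <- u$length

  runs <- .tiling_runs(graph$tilings)
  run_names <- vapply(seq_along(runs), function(i) {
    r <- runs[[i]]
    if (sum(graph$tilings$seq_id == r$seq_id[[1L]] & graph$tilings$step == 1L) > 1L) {
      sprintf("%s_run%d", r$seq_id[[1L]], r$run_start[[1L]])
    } else r$seq_id[[1L]]
  }, character(1L))

  links <- list()
  seen_keys <- character(0)
  flip <- function(o) ifelse(o == "+", "-", "+")
  for (r in runs) {
    if (nrow(r) < 2L) next
    for (j in seq_len(nrow(r) - 1L)) {
      a <- r$unitig_id[[j]]; oa <- r$orientation[[j]]
      b <- r$unitig_id[[j + 1L]]; ob <- r$orientation[[j + 1L]]
      fwd <- sprintf("%d%s>%d%s", a, oa, b, ob)
      rev <- sprintf("%d%s>%d%s", b, flip(ob), a, flip(oa))
      key <- min(fwd, rev)
      if (key %in% seen_keys) next
      seen_keys <- c(seen_keys, key)
      links[[length(links) + 1L]] <- list(a = a, oa = oa, b = b, ob = ob)
    }
  }

  lines <- character(0)
  if (version == 1L) {
    lines <- c(lines, "H\tVN:Z:1.0")
    lines <- c(lines, sprintf("S\t%s\t%s\tLN:i:%d", seg, u$spelling, seg_len))
    for (l in links) {
      lines <- c(lines, sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                                seg[[l$a]], l$oa, seg[[l$b]], l$ob, k - 1L))
    }
    for (i in seq_along(runs)) {
      r <- runs[[i]]
      lines <- c(lines, sprintf("P\t%s\t%s\t%s",
                                run_names[[i]],
                                paste0(seg[r$unitig_id], r$orientation, collapse = ","),
                                paste(rep(sprintf("%dM", k - 1L), max(nrow(r) - 1L, 0L)),
                                      collapse = ",")))
    }
  } else {
    lines <- c(lines, "H\tVN:Z:2.0")
    lines <- c(lines, sprintf("S\t%s\t%d\t%s", seg, seg_len, u$spelling))
    pos <- function(id, o, end) {
      # overlap interval on a segment: the trailing k-1 bases of the
      # outgoing end, leading k-1 of the incoming end, in segment coords
      n <- seg_len[[id]]
      if ((o == "+") == end) c(sprintf("%d", n - k + 1L), sprintf("%d$", n))
      else c("0", sprintf("%d", k - 1L))
    }
    for (l in links) {
      pa <- pos(l$a, l$oa, TRUE)
      pb <- pos(l$b, l$ob, FALSE)
      lines <- c(lines, sprintf("E\t*\t%s%s\t%s%s\t%s\t%s\t%s\t%s\t%dM",
                                seg[[l$a]], l$oa, seg[[l$b]], l$ob,
                                pa[[1L]], pa[[2L]], pb[[1L]], pb[[2L]], k - 1L))
    }
    for (i in seq_along(runs)) {
      r <- runs[[i]]
      lines <- c(lines, sprintf("O\t%s\t%s",
                                run_names[[i]],
                                paste0(seg[r$unitig_id], r$orientation, collapse = " ")))
    }
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
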