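#' Build a breakpoint graph from translocation calls
#'
#' Chromosomes are cut at every reported breakpoint (donor segment edges and
#' numeric acceptor insertion sites); the resulting oriented segments are
#' the nodes.  Each call contributes a novel adjacency edge between its
#' donor segment (at the junction end implied by the call orientation) and
#' the acceptor segment at the insertion site.  Contradictory orientations
#' for one adjacency are both retained and flagged.
#'
#' @param calls an `sv_calls` table (see [detect_translocations()]).
#' @param genome a `genome_model`.
#' @return list of class `breakpoint_graph`: `nodes` (data.table `node`,
#'   `chrom`, `start`, `end`), `edges` (data.table `from`, `to`, `call`,
#'   `score`, `conflict`).
#' @export
build_breakpoint_graph <- function(calls, genome) {
  ch <- genome$chromosomes
  cuts <- lapply(seq_len(nrow(ch)), function(i) {
    cc <- ch$name[i]
    p <- c(0, ch$length[i])
    if (nrow(calls)) {
      p <- c(p,
             calls[chrom_donor == cc, c(seg_start, seg_end)],
             suppressWarnings(as.numeric(
               calls[chrom_acceptor == cc & !grepl("^ter", insertion), insertion_bp])))
    }
    sort(unique(p[is.finite(p) & p >= 0 & p <= ch$length[i]]))
  })
  names(cuts) <- ch$name
  nodes <- rbindlist(lapply(ch$name, function(cc) {
    p <- cuts[[cc]]
    if (length(p) < 2L) return(NULL)
    data.table(chrom = cc, start = head(p, -1L), end = tail(p, -1L))
  }))
  nodes[, node := .I]
  find_node <- function(cc, s, e) {
    nodes[chrom == cc & start >= s - 1 & end <= e + 1][
      which.max(end - start), node]
  }
  node_at <- function(cc, pos, side) {
    # side "L": segment ending at pos; "R": segment starting at pos
    hit <- if (side == "L") nodes[chrom == cc & end == pos, node]
           else nodes[chrom == cc & start == pos, node]
    if (length(hit)) hit[1L] else {
      cand <- nodes[chrom == cc & start <= pos & end >= pos, node]
      if (length(cand)) cand[1L] else NA_integer_
    }
  }
  edges <- list()
  if (nrow(calls)) for (k in seq_len(nrow(calls))) {
    cl <- calls[k]
    dn_all <- nodes[chrom == cl$chrom_donor & start >= cl$seg_start - 1 &
                    end <= cl$seg_end + 1]
    # junction extremity of the donor interval: '+' fuses the low end
    dn <- NA_integer_; dend <- "L"
    if (nrow(dn_all)) {
      if (cl$orientation == "-") { dn <- dn_all[which.max(end), node]; dend <- "R" }
      else { dn <- dn_all[which.min(start), node]; dend <- "L" }
    }
    if (grepl("^ter", cl$insertion)) {
      L <- chrom_length(genome, cl$chrom_acceptor)
      if (cl$insertion == "ter:p") { an <- node_at(cl$chrom_acceptor, 0, "R"); aend <- "L" }
      else { an <- node_at(cl$chrom_acceptor, L, "L"); aend <- "R" }
    } else { an <- node_at(cl$chrom_acceptor, cl$insertion_bp, "L"); aend <- "R" }
    if (is.na(dn) || is.na(an)) next
    edges[[length(edges) + 1L]] <- data.table(from = dn, from_end = dend,
                                              to = an, to_end = aend,
                                              call = k, score = cl$score,
                                              conflict = FALSE)
  }
  edges <- if (length(edges)) rbindlist(edges) else
    data.table(from = integer(), from_end = character(), to = integer(),
               to_end = character(), call = integer(),
               score = numeric(), conflict = logical())
  if (nrow(edges) > 1L) {
    # the same segment extremity claimed by several adjacencies: retained,
    # flagged as conflicting evidence
    ext <- c(paste(edges$from, edges$from_end), paste(edges$to, edges$to_end))
    dup <- ext[duplicated(ext)]
    edges[, conflict := paste(from, from_end) %in% dup |
            paste(to, to_end) %in% dup]
  }
  structure(list(nodes = nodes[], edges = edges[]), class = "breakpoint_graph")
}

#' Reconstruct candidate derivative chromosomes
#'
#' Maximal simple paths through the novel-adjacency graph, each emitted as
#' an ordered, oriented segment list and ranked by total evidence score.
#' Branching produces multiple ranked alternatives; components that are
#' pure cycles are reported as unresolvable rather than emitted.
#'
#' @param graph a [build_breakpoint_graph()] result.
#' @return list of derivative reconstructions, each a list with `name`,
#'   `segments` (data.table `chrom`, `start`, `end`, `orientation`) and
#'   `score`; attribute `unresolvable` counts cyclic components.
#' @export
reconstruct_derivatives <- function(graph) {
  ed <- graph$edges
  if (!nrow(ed)) {
    out <- list()
    attr(out, "unresolvable") <- 0L
    return(out)
  }
  # adjacency lists between segment extremities ("node.L" / "node.R")
  ekey <- function(n, e) paste0(n, ".", e)
  adj <- new.env(parent = emptyenv())
  addadj <- function(a, b, sc) {
    assign(a, rbind(get0(a, envir = adj), data.frame(to = b, score = sc)),
           envir = adj)
  }
  for (k in seq_len(nrow(ed))) {
    a <- ekey(ed$from[k], ed$from_end[k]); b <- ekey(ed$to[k], ed$to_end[k])
    addadj(a, b, ed$score[k]); addadj(b, a, ed$score[k])
  }
  other_end <- function(v) {
    n <- sub("\\..*", "", v); e <- sub(".*\\.", "", v)
    ekey(n, if (e == "L") "R" else "L")
  }
  involved <- unique(c(ed$from, ed$to))
  # start extremities: segment ends with no adjacency (free telomere side)
  starts <- unlist(lapply(involved, function(n) {
    v <- c(ekey(n, "L"), ekey(n, "R"))
    v[vapply(v, function(x) is.null(get0(x, envir = adj)), TRUE)]
  }))
  paths <- list(); scores <- numeric(); orients <- list()
  walk <- function(entry, visited, ors, sc) {
    # entry = extremity where the current segment is entered
    n <- sub("\\..*", "", entry)
    e <- sub(".*\\.", "", entry)
    visited <- c(visited, n)
    ors <- c(ors, if (e == "L") "+" else "-")
    out_ext <- other_end(entry)
    nx <- get0(out_ext, envir = adj)
    extended <- FALSE
    if (!is.null(nx)) for (i in seq_len(nrow(nx))) {
      nn <- sub("\\..*", "", nx$to[i])
      if (nn %in% visited) next
      extended <- TRUE
      walk(nx$to[i], visited, ors, sc + nx$score[i])
    }
    if (!extended) {
      paths[[length(paths) + 1L]] <<- visited
      orients[[length(orients) + 1L]] <<- ors
      scores[length(scores) + 1L] <<- sc
    }
    invisible()
  }
  entries <- character()
  if (length(starts)) for (v in starts) { entries <- c(entries, v) }
  cyclic <- 0L
  if (length(entries)) for (v in entries) walk(v, character(), character(), 0)
  # components without any free extremity are cycles: unresolvable
  comp_nodes_seen <- unique(unlist(lapply(paths, identity)))
  g0 <- igraph::graph_from_data_frame(
    ed[, .(from = as.character(from), to = as.character(to))], directed = FALSE)
  comps <- igraph::components(g0)
  for (cid in seq_len(comps$no)) {
    members <- names(comps$membership)[comps$membership == cid]
    if (!any(members %in% comp_nodes_seen)) cyclic <- cyclic + 1L
  }
  if (!length(paths)) {
    out <- list()
    attr(out, "unresolvable") <- cyclic
    return(out)
  }
  # dedupe reversed duplicates and dominated (sub-path) reconstructions
  keys <- vapply(paths, function(p) paste(sort(p), collapse = "-"), "")
  ord <- order(-lengths(paths), -scores)
  seen <- character(); keep <- integer()
  for (i in ord) {
    if (keys[i] %in% seen) next
    seen <- c(seen, keys[i]); keep <- c(keep, i)
  }
  out <- lapply(keep, function(i) {
    p <- as.integer(paths[[i]])
    segs <- graph$nodes[match(p, node)]
    segs <- segs[, .(chrom, start, end)]
    segs[, orientation := orients[[i]]]
    list(name = sprintf("der(%s)", paste(unique(segs$chrom), collapse = ";")),
         segments = segs[],
         score = scores[i])
  })
  ord2 <- order(-vapply(out, `[[`, 0, "score"),
                vapply(out, function(d) d$segments$chrom[1L], ""))
  out <- out[ord2]
  attr(out, "unresolvable") <- cyclic
  out
}

#' Estimate the chromosome number of a rearranged karyotype
#'
#' Starts from the per-chromosome copy number (ploidy, or the rounded
#' coverage-based copy estimate when a copy-number track is given) and
#' subtracts one chromosome for every pair of whole chromosomes joined in a
#' derivative reconstruction: a derivative containing `k` (near-)whole
#' chromosomes replaces them with a single body, removing `k - 1`.
#'
#' @param derivatives a [reconstruct_derivatives()] result.
#' @param genome a `genome_model`.
#' @param copy_number optional [copy_number_track()]-like table used for
#'   whole-chromosome gains/losses.
#' @param whole_fraction fraction of a chromosome a segment must cover to
#'   count as whole (default 0.9).
#' @return integer chromosome count.
#' @export
estimate_chromosome_count <- function(derivatives, genome, copy_number = NULL,
                                      whole_fraction = 0.9) {
  ch <- genome$chromosomes
  copies <- ch$ploidy
  if (!is.null(copy_number)) {
    cn <- as.data.table(copy_number)[, .(copy = round(mean(copy))), by = chrom]
    m <- match(ch$name, cn$chrom)
    copies <- ifelse(is.na(m), copies, pmax(0L, cn$copy[m]))
  }
  n <- sum(copies)
  for (d in derivatives) {
    segs <- d$segments
    lens <- chrom_length(genome, segs$chrom)
    wholes <- sum((segs$end - segs$start) / lens >= whole_fraction)
    n <- n - max(0L, wholes - 1L)
  }
  as.integer(n)
}

#' Exact chromosome count of a simulated karyotype
#'
#' @param karyotype a `derivative_karyotype`.
#' @return number of derivative chromosomes across all haplotypes.
#' @export
chromosome_count <- function(karyotype) {
  sum(lengths(karyotype$haplotypes))
}
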