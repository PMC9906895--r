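#' Describe a single karyotype edit
#'
#' Edits are expressed in reference coordinates (0-based, half-open) and are
#' applied sequentially to one haplotype of a diploid karyotype, each edit
#' being resolved through the haplotype mapping produced by the preceding
#' ones.  Supported kinds mirror the rearrangement classes visible in Hi-C
#' maps of rearranged karyotypes:
#'
#' * `translocation`: the donor interval is excised (`mode = "moved"`,
#'   unbalanced) or copied (`mode = "duplicated"`, translocated duplication)
#'   and inserted at the acceptor site.  `insertion` is either a bp position
#'   on the acceptor chromosome or a terminal sentinel `"ter:p"` / `"ter:q"`
#'   (joined before the first / after the last reference bp of the acceptor,
#'   the unresolvable "terminal fusion" geometry).  With `balanced = TRUE`
#'   the distal tails of donor and acceptor are exchanged reciprocally.
#' * `deletion`: the interval is removed from the haplotype.
#' * `inversion`: the interval is flipped in place.
#' * `duplication`: `copies` extra tandem copies are inserted after the
#'   interval (or at `acceptor`/`insertion` if given).
#' * `whole_chrom_gain`: an extra whole-chromosome copy is appended to the
#'   haplotype.
#'
#' @param kind one of `"translocation"`, `"deletion"`, `"inversion"`,
#'   `"duplication"`, `"whole_chrom_gain"`.
#' @param donor_chrom,donor_start,donor_end donor interval (bp, 0-based
#'   half-open).  For `whole_chrom_gain` only `donor_chrom` is used.
#' @param orientation `"+"` or `"-"`: orientation of the inserted segment
#'   relative to the acceptor.
#' @param acceptor_chrom,insertion acceptor site for translocations /
#'   duplications; `insertion` is bp or `"ter:p"`/`"ter:q"`.
#' @param mode `"moved"` (donor excised) or `"duplicated"` (donor retained).
#' @param balanced reciprocal tail exchange (translocation only).
#' @param haplotype 1 or 2: which haplotype carries the edit.
#' @param copies number of extra copies for `duplication`.
#' @param name optional label used in error messages and reports.
#' @return a `karyotype_edit` object.
#' @export
karyotype_edit <- function(kind, donor_chrom, donor_start = NA, donor_end = NA,
                           orientation = "+", acceptor_chrom = NA,
                           insertion = NA, mode = "moved", balanced = FALSE,
                           haplotype = 1L, copies = 1L, name = NULL) {
  kind <- match.arg(kind, c("translocation", "deletion", "inversion",
                            "duplication", "whole_chrom_gain"))
  if (!orientation %in% c("+", "-")) stop("orientation must be '+' or '-'")
  mode <- match.arg(mode, c("moved", "duplicated"))
  if (kind != "whole_chrom_gain") {
    if (!is.numeric(donor_start) || !is.numeric(donor_end) ||
        is.na(donor_start) || is.na(donor_end) ||
        donor_start < 0 || donor_start >= donor_end)
      stop("need 0 <= donor_start < donor_end")
  }
  if (is.null(name))
    name <- if (kind == "whole_chrom_gain") sprintf("gain(%s)", donor_chrom)
            else sprintf("%s(%s:%s-%s)", kind, donor_chrom,
                         format(donor_start, scientific = FALSE),
                         format(donor_end, scientific = FALSE))
  structure(list(kind = kind, donor_chrom = donor_chrom,
                 donor_start = donor_start, donor_end = donor_end,
                 orientation = orientation, acceptor_chrom = acceptor_chrom,
                 insertion = insertion, mode = mode, balanced = balanced,
                 haplotype = as.integer(haplotype), copies = as.integer(copies),
                 name = name),
            class = "karyotype_edit")
}

new_der_chrom <- function(name, segments) {
  segments <- as.data.table(segments)
  list(name = name, segments = segments)
}

#' Identity (unedited) karyotype for a genome
#'
#' @param genome a `genome_model`.
#' @return a `derivative_karyotype` whose haplotypes carry one intact copy of
#'   each chromosome per unit of ploidy.
#' @export
identity_karyotype <- function(genome) {
  ch <- genome$chromosomes
  nhap <- max(ch$ploidy)
  haps <- lapply(seq_len(nhap), function(h) {
    idx <- which(ch$ploidy >= h)
    lapply(idx, function(i) {
      new_der_chrom(sprintf("%s.%d", ch$name[i], h),
                    data.table(chrom = ch$name[i], start = 0,
                               end = ch$length[i], orientation = "+"))
    })
  })
  structure(list(genome = genome, haplotypes = haps, edits = list()),
            class = "derivative_karyotype")
}

#' @export
print.derivative_karyotype <- function(x, ...) {
  nseg <- sum(vapply(x$haplotypes, function(h)
    sum(vapply(h, function(d) nrow(d$segments), 1L)), 1))
  cat(sprintf("<derivative_karyotype> %d haplotypes, %d derivative chromosomes, %d segments, %d edits\n",
              length(x$haplotypes),
              sum(lengths(x$haplotypes)), nseg, length(x$edits)))
  invisible(x)
}

flip_run <- function(run) {
  run <- run[rev(seq_len(nrow(run)))]
  run[, orientation := fifelse(orientation == "+", "-", "+")]
  run
}

merge_segments <- function(seg) {
  if (nrow(seg) <= 1L) return(seg)
  keep <- rep(TRUE, nrow(seg))
  i <- 1L
  for (j in 2:nrow(seg)) {
    same <- seg$chrom[j] == seg$chrom[i] && seg$orientation[j] == seg$orientation[i]
    joins <- same && ((seg$orientation[i] == "+" && seg$end[i] == seg$start[j]) ||
                      (seg$orientation[i] == "-" && seg$start[i] == seg$end[j]))
    if (joins) {
      if (seg$orientation[i] == "+") seg$end[i] <- seg$end[j]
      else seg$start[i] <- seg$start[j]
      keep[j] <- FALSE
    } else i <- j
  }
  seg[keep]
}

# Locate the insertion point for reference coordinate (chrom, pos) in a
# haplotype.  Returns list(d = derivative index, at = row index after which to
# insert, split = optional replacement rows for the row being split).
# When pos falls on an existing boundary the new material goes immediately
# before the segment that starts (in reference terms) at pos, i.e. after any
# previously inserted foreign material at that boundary.
hap_find_insertion <- function(hap, chrom, pos) {
  for (d in seq_along(hap)) {
    seg <- hap[[d]]$segments
    for (k in seq_len(nrow(seg))) {
      if (seg$chrom[k] != chrom) next
      s <- seg$start[k]; e <- seg$end[k]; o <- seg$orientation[k]
      if (pos > s && pos < e) {
        rows <- if (o == "+")
          data.table(chrom = chrom, start = c(s, pos), end = c(pos, e), orientation = "+")
        else
          data.table(chrom = chrom, start = c(pos, s), end = c(e, pos), orientation = "-")
        return(list(d = d, at = k, split = rows))
      }
      boundary_start <- (o == "+" && pos == s) || (o == "-" && pos == e)
      if (boundary_start) return(list(d = d, at = k - 1L, split = NULL))
    }
  }
  # second pass: position at the end of a segment with no successor
  # starting there (e.g. re-inserting into an excision gap)
  for (d in seq_along(hap)) {
    seg <- hap[[d]]$segments
    for (k in seq_len(nrow(seg))) {
      if (seg$chrom[k] != chrom) next
      boundary_end <- (seg$orientation[k] == "+" && pos == seg$end[k]) ||
        (seg$orientation[k] == "-" && pos == seg$start[k])
      if (boundary_end) return(list(d = d, at = k, split = NULL))
    }
  }
  NULL
}

# terminal insertion point: arm = "p" (before reference bp 0) or "q" (after
# the last reference bp) of `chrom`.
hap_find_terminal <- function(hap, chrom, arm, chrom_len) {
  for (d in seq_along(hap)) {
    seg <- hap[[d]]$segments
    for (k in seq_len(nrow(seg))) {
      if (seg$chrom[k] != chrom) next
      if (arm == "p" &&
          ((seg$orientation[k] == "+" && seg$start[k] == 0) ||
           (seg$orientation[k] == "-" && seg$start[k] == 0))) {
        at <- if (seg$orientation[k] == "+") k - 1L else k
        return(list(d = d, at = at, split = NULL))
      }
      if (arm == "q" &&
          ((seg$orientation[k] == "+" && seg$end[k] == chrom_len) ||
           (seg$orientation[k] == "-" && seg$end[k] == chrom_len))) {
        at <- if (seg$orientation[k] == "+") k else k - 1L
        return(list(d = d, at = at, split = NULL))
      }
    }
  }
  NULL
}

# Excise reference interval [s, e) of `chrom` from a haplotype.  The interval
# must be covered contiguously (one monotone run of segments on a single
# derivative chromosome).  Returns list(run = excised rows in reference '+'
# order, hap = haplotype after excision) or errors with `label`.
hap_excise <- function(hap, chrom, s, e, label, remove = TRUE) {
  for (d in seq_along(hap)) {
    seg <- hap[[d]]$segments
    hit <- which(seg$chrom == chrom & seg$start < e & seg$end > s)
    if (!length(hit)) next
    # require one contiguous block of rows covering [s, e); a partial copy
    # (e.g. from an earlier duplication) is skipped in favor of a full one
    rows <- seg[hit]
    cov <- sum(pmin(rows$end, e) - pmax(rows$start, s))
    if (cov < e - s || any(diff(hit) != 1L)) next
    # orientation of the run
    o <- unique(rows$orientation)
    if (length(o) != 1L) next
    ord <- if (o == "+") order(rows$start) else order(-rows$start)
    if (!identical(ord, seq_len(nrow(rows)))) next
    first <- hit[1L]; last <- hit[length(hit)]
    pre <- seg[seq_len(first - 1L)]
    post <- if (last < nrow(seg)) seg[(last + 1L):nrow(seg)] else seg[0L]
    # trim partial coverage at the run edges back onto the residue
    run <- copy(rows)
    resid_left <- rows[0L]; resid_right <- rows[0L]
    for (k in seq_len(nrow(run))) {
      if (run$start[k] < s) {
        r <- data.table(chrom = chrom, start = run$start[k], end = s,
                        orientation = run$orientation[k])
        if (run$orientation[k] == "+") resid_left <- rbind(resid_left, r)
        else resid_right <- rbind(resid_right, r)
        run$start[k] <- s
      }
      if (run$end[k] > e) {
        r <- data.table(chrom = chrom, start = e, end = run$end[k],
                        orientation = run$orientation[k])
        if (run$orientation[k] == "+") resid_right <- rbind(resid_right, r)
        else resid_left <- rbind(resid_left, r)
        run$end[k] <- e
      }
    }
    if (remove) {
      # resid_left goes before the gap, resid_right after, preserving order
      newseg <- merge_segments(rbind(pre, resid_left, resid_right, post))
      if (nrow(newseg) == 0L) hap[[d]] <- NULL else hap[[d]]$segments <- newseg
    }
    run_plus <- if (o == "+") run else flip_run(run)
    return(list(run = run_plus, run_der = run, hap = hap))
  }
  stop(sprintf("edit %s: donor interval %s:%s-%s is not contiguously present on the haplotype (conflicting earlier edit?)",
               label, chrom, format(s, scientific = FALSE), format(e, scientific = FALSE)))
}

hap_insert <- function(hap, where, rows) {
  seg <- hap[[where$d]]$segments
  if (!is.null(where$split)) {
    before <- if (where$at > 1L) seg[seq_len(where$at - 1L)] else seg[0L]
    after <- if (where$at < nrow(seg)) seg[(where$at + 1L):nrow(seg)] else seg[0L]
    newseg <- rbind(before, where$split[1L], rows, where$split[2L], after)
  } else {
    before <- if (where$at >= 1L) seg[seq_len(where$at)] else seg[0L]
    after <- if (where$at < nrow(seg)) seg[(where$at + 1L):nrow(seg)] else seg[0L]
    newseg <- rbind(before, rows, after)
  }
  hap[[where$d]]$segments <- merge_segments(newseg)
  hap
}

parse_insertion <- function(insertion) {
  if (is.character(insertion) && grepl("^ter:[pq]$", insertion))
    list(ter = sub("ter:", "", insertion), pos = NA_real_)
  else if (is.numeric(insertion) && !is.na(insertion))
    list(ter = NULL, pos = as.numeric(insertion))
  else stop("insertion must be a bp position or 'ter:p'/'ter:q'")
}

apply_one_edit <- function(hap, genome, ed) {
  lab <- ed$name
  if (ed$kind == "whole_chrom_gain") {
    L <- chrom_length(genome, ed$donor_chrom)
    hap[[length(hap) + 1L]] <- new_der_chrom(
      sprintf("%s.gain", ed$donor_chrom),
      data.table(chrom = ed$donor_chrom, start = 0, end = L, orientation = "+"))
    return(hap)
  }
  L <- chrom_length(genome, ed$donor_chrom)
  if (ed$donor_end > L)
    stop(sprintf("edit %s: donor interval exceeds chromosome length", lab))
  if (ed$kind == "deletion") {
    ex <- hap_excise(hap, ed$donor_chrom, ed$donor_start, ed$donor_end, lab)
    return(ex$hap)
  }
  if (ed$kind == "inversion") {
    ex <- hap_excise(hap, ed$donor_chrom, ed$donor_start, ed$donor_end, lab)
    where <- hap_find_insertion(ex$hap, ed$donor_chrom, ed$donor_start)
    if (is.null(where))  # interval reached a chromosome boundary
      where <- hap_find_terminal(ex$hap, ed$donor_chrom,
                                 if (ed$donor_start == 0) "p" else "q", L)
    if (is.null(where)) stop(sprintf("edit %s: cannot re-insert inversion", lab))
    return(hap_insert(ex$hap, where, flip_run(ex$run_der)))
  }
  if (ed$kind == "duplication") {
    ex <- hap_excise(hap, ed$donor_chrom, ed$donor_start, ed$donor_end, lab,
                     remove = FALSE)
    rows <- ex$run
    if (ed$orientation == "-") rows <- flip_run(rows)
    rows <- rows[rep(seq_len(nrow(rows)), ed$copies)]
    if (!is.na(ed$acceptor_chrom) && !is.null(ed$insertion) && !all(is.na(ed$insertion))) {
      ins <- parse_insertion(ed$insertion)
      where <- if (!is.null(ins$ter))
        hap_find_terminal(hap, ed$acceptor_chrom, ins$ter,
                          chrom_length(genome, ed$acceptor_chrom))
      else hap_find_insertion(hap, ed$acceptor_chrom, ins$pos)
      if (is.null(where)) stop(sprintf("edit %s: acceptor site not found", lab))
    } else {
      where <- hap_find_insertion(hap, ed$donor_chrom, ed$donor_end)
      if (is.null(where))
        where <- hap_find_terminal(hap, ed$donor_chrom, "q", L)
      if (is.null(where)) stop(sprintf("edit %s: tandem site not found", lab))
    }
    return(hap_insert(hap, where, rows))
  }
  # translocation
  if (is.na(ed$acceptor_chrom)) stop(sprintf("edit %s: translocation needs an acceptor", lab))
  if (isTRUE(ed$balanced)) {
    ins <- parse_insertion(ed$insertion)
    if (is.null(ins$ter)) {
      La <- chrom_length(genome, ed$acceptor_chrom)
      exA <- hap_excise(hap, ed$donor_chrom, ed$donor_start, L, lab)
      exB <- hap_excise(exA$hap, ed$acceptor_chrom, ins$pos, La,
                        paste0(lab, "[reciprocal]"))
      hap2 <- exB$hap
      wA <- hap_find_terminal(hap2, ed$donor_chrom, "q", ed$donor_start)
      wB <- hap_find_terminal(hap2, ed$acceptor_chrom, "q", ins$pos)
      # terminal lookup uses the *current* last reference bp of each residue
      if (is.null(wA) || is.null(wB))
        stop(sprintf("edit %s: reciprocal exchange failed", lab))
      hap2 <- hap_insert(hap2, wA, exB$run)
      wB <- hap_find_terminal(hap2, ed$acceptor_chrom, "q", ins$pos)
      hap2 <- hap_insert(hap2, wB, exA$run)
      return(hap2)
    }
    stop(sprintf("edit %s: balanced translocation needs a bp insertion site", lab))
  }
  ex <- hap_excise(hap, ed$donor_chrom, ed$donor_start, ed$donor_end, lab,
                   remove = (ed$mode == "moved"))
  rows <- ex$run
  if (ed$orientation == "-") rows <- flip_run(rows)
  hap2 <- if (ed$mode == "moved") ex$hap else hap
  ins <- parse_insertion(ed$insertion)
  where <- if (!is.null(ins$ter))
    hap_find_terminal(hap2, ed$acceptor_chrom, ins$ter,
                      chrom_length(genome, ed$acceptor_chrom))
  else hap_find_insertion(hap2, ed$acceptor_chrom, ins$pos)
  if (is.null(where))
    stop(sprintf("edit %s: acceptor site %s:%s not found on the haplotype",
                 lab, ed$acceptor_chrom, paste(ed$insertion, collapse = "")))
  hap_insert(hap2, where, rows)
}

#' Apply karyotype edits to a genome
#'
#' Edits are applied in list order to the haplotype each names; coordinates
#' always refer to the reference and are resolved through the haplotype
#' mapping produced by the preceding edits.
#'
#' @param genome a `genome_model`.
#' @param edits a list of [karyotype_edit()] objects.
#' @return a `derivative_karyotype`.
#' @export
apply_edits <- function(genome, edits) {
  kar <- identity_karyotype(genome)
  for (ed in edits) {
    if (!inherits(ed, "karyotype_edit")) stop("edits must be karyotype_edit objects")
    h <- ed$haplotype
    if (h < 1L || h > length(kar$haplotypes))
      stop(sprintf("edit %s: haplotype %d does not exist", ed$name, h))
    kar$haplotypes[[h]] <- apply_one_edit(kar$haplotypes[[h]], genome, ed)
  }
  kar$edits <- edits
  kar
}

#' Per-bin copy-number track implied by a karyotype
#'
#' Counts, for each reference bin, the haplotype segments covering the bin
#' midpoint, summed over haplotypes.  For an unedited diploid region the
#' value is the ploidy.
#'
#' @param karyotype a `derivative_karyotype`.
#' @param bin_size bin size in bp.
#' @return a data.table with columns `chrom`, `start`, `end`, `copy`.
#' @export
copy_number_track <- function(karyotype, bin_size = 250e3) {
  bt <- bin_table(karyotype$genome, bin_size)$bins
  bt[, copy := 0L]
  mids <- bt[, (start + end) / 2]
  for (hap in karyotype$haplotypes) for (d in hap) {
    seg <- d$segments
    for (k in seq_len(nrow(seg))) {
      cov <- which(bt$chrom == seg$chrom[k] & mids >= seg$start[k] & mids < seg$end[k])
      if (length(cov)) bt[cov, copy := copy + 1L]
    }
  }
  bt[]
}

#' Flatten a karyotype into a segment table
#'
#' @param karyotype a `derivative_karyotype`.
#' @return data.table with one row per derivative segment: `hap`, `dchrom`
#'   (derivative chromosome name), `dstart`, `dend` (derivative coordinates),
#'   `chrom`, `start`, `end`, `orientation` (reference interval).
#' @export
karyotype_segments <- function(karyotype) {
  out <- list()
  for (h in seq_along(karyotype$haplotypes)) {
    for (d in karyotype$haplotypes[[h]]) {
      seg <- copy(d$segments)
      w <- seg$end - seg$start
      seg[, `:=`(hap = h, dchrom = d$name,
                 dstart = cumsum(c(0, head(w, -1L))), dend = cumsum(w))]
      out[[length(out) + 1L]] <- seg
    }
  }
  rbindlist(out)[, .(hap, dchrom, dstart, dend, chrom, start, end, orientation)]
}
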