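#' Detection parameters for structural-variant scanning
#'
#' @param scan_bin coarse scan resolution in bp (default 250 kb).
#' @param refine_bin fine localization resolution (default 5 kb); must
#'   divide `scan_bin`.
#' @param enrichment_z_min minimum block-level mean z-score (default 4).
#' @param min_segment_bp blocks smaller than this on both axes are
#'   discarded (default 200 kb, the conventional floor for large events).
#' @param background_model `"per-pair-median"` (robust to the block itself)
#'   or `"global-trans-mean"`.
#' @param smoothing_window box-sum smoothing width in bins (odd, default 3).
#' @param fusion_span_fraction blocks covering at least this fraction of a
#'   chromosome with no internal change-point are terminal fusions
#'   (default 0.9).
#' @param fdr_alpha Benjamini-Hochberg level for per-pixel Poisson tail
#'   tests within a chromosome pair (default 0.01).
#' @param refine_window half-width (bp) of the fine-resolution window
#'   fetched around junctions and segment edges (default 2 Mb).
#' @param inv_score_min minimum butterfly log-ratio score for inversion
#'   calls (default 0.5).
#' @param inv_grid_bins coarse candidate-grid step for inversion scanning,
#'   in bins (default 5).
#' @return a `detection_params` object.
#' @export
detection_params <- function(scan_bin = 250e3, refine_bin = 5e3,
                             enrichment_z_min = 4, min_segment_bp = 200e3,
                             background_model = c("per-pair-median",
                                                  "global-trans-mean"),
                             smoothing_window = 3L,
                             fusion_span_fraction = 0.9,
                             fdr_alpha = 0.01,
                             refine_window = 2e6,
                             inv_score_min = 0.5,
                             inv_grid_bins = 5L) {
  background_model <- match.arg(background_model)
  stopifnot(scan_bin %% refine_bin == 0, min_segment_bp >= refine_bin,
            smoothing_window %% 2 == 1)
  structure(list(scan_bin = scan_bin, refine_bin = refine_bin,
                 enrichment_z_min = enrichment_z_min,
                 min_segment_bp = min_segment_bp,
                 background_model = background_model,
                 smoothing_window = as.integer(smoothing_window),
                 fusion_span_fraction = fusion_span_fraction,
                 fdr_alpha = fdr_alpha, refine_window = refine_window,
                 inv_score_min = inv_score_min,
                 inv_grid_bins = as.integer(inv_grid_bins)),
            class = "detection_params")
}

# box sum of a matrix over a k x k neighborhood (edge-truncated); returns
# list(sum, n) with the number of cells contributing at each position
box_sum <- function(M, k) {
  r <- (k - 1L) %/% 2L
  S <- M * 0; N <- M * 0
  ones <- matrix(1, nrow(M), ncol(M))
  for (di in -r:r) for (dj in -r:r) {
    ri <- seq_len(nrow(M)); ci <- seq_len(ncol(M))
    si <- ri + di; sj <- ci + dj
    ok_i <- si >= 1 & si <= nrow(M); ok_j <- sj >= 1 & sj <= ncol(M)
    S[ri[ok_i], ci[ok_j]] <- S[ri[ok_i], ci[ok_j]] + M[si[ok_i], sj[ok_j]]
    N[ri[ok_i], ci[ok_j]] <- N[ri[ok_i], ci[ok_j]] + 1
  }
  list(sum = S, n = N)
}

# label 8-connected components of a logical matrix; returns integer matrix
label_components <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  lab <- matrix(0L, nrow(mask), ncol(mask))
  if (!nrow(idx)) return(lab)
  key <- (idx[, 2] - 1L) * nrow(mask) + idx[, 1]
  edges <- list()
  for (di in c(-1L, 0L, 1L)) for (dj in c(-1L, 0L, 1L)) {
    if (di == 0L && dj == 0L) next
    nb <- (idx[, 2] - 1L + dj) * nrow(mask) + (idx[, 1] + di)
    ok <- idx[, 1] + di >= 1L & idx[, 1] + di <= nrow(mask) &
      idx[, 2] + dj >= 1L & idx[, 2] + dj <= ncol(mask)
    m <- match(nb[ok], key)
    hit <- !is.na(m)
    if (any(hit)) edges[[length(edges) + 1L]] <-
        cbind(which(ok)[hit], m[hit])
  }
  g <- igraph::make_empty_graph(n = length(key), directed = FALSE)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(e))
  }
  comp <- igraph::components(g)$membership
  lab[cbind(idx[, 1], idx[, 2])] <- as.integer(comp)
  lab
}

#' Interchromosomal contact-enrichment blocks for one chromosome pair
#'
#' Coarsens to `scan_bin`, estimates a flat background for the pair,
#' computes per-pixel Poisson upper-tail probabilities on box-smoothed
#' counts, adjusts them by Benjamini-Hochberg across the pair, and joins
#' significant pixels into 8-connected components.  Component bounding
#' boxes are returned as enrichment blocks; blocks smaller than
#' `min_segment_bp` on both axes, or with mean z below
#' `enrichment_z_min`, are discarded.
#'
#' @param m a `contact_matrix`.
#' @param chromA,chromB chromosome names (order defines the axes).
#' @param params a [detection_params()].
#' @return data.table (`chromA`, `startA`, `endA`, `chromB`, `startB`,
#'   `endB`, `mean_z`, `pixel_count`); empty when nothing is significant.
#' @export
trans_enrichment <- function(m, chromA, chromB, params = detection_params(),
                             coverage = NULL, lam_override = NULL) {
  mc <- if (m$bins$bin_size < params$scan_bin)
    coarsen_matrix(m, params$scan_bin) else m
  bA <- mc$bins$bins[chrom == chromA]; bB <- mc$bins$bins[chrom == chromB]
  if (!nrow(bA) || !nrow(bB)) stop("chromosome absent from the matrix")
  X <- dense_block(mc, bA$gbin, bB$gbin)
  lam <- if (params$background_model == "per-pair-median") {
    med <- median(X)
    if (med > 0) med else max(mean(X), 1e-6)
  } else {
    px <- pixel_chroms(mc)
    tp <- px[chrom1 != chrom2, sum(count)]
    npair <- {
      tabs <- mc$bins$bins[, .N, by = chrom]$N
      (sum(tabs)^2 - sum(tabs^2)) / 2
    }
    max(tp / npair, 1e-6)
  }
  # expected model: flat background scaled by the coverage product, so
  # copy-number-driven uniform trans enrichment (duplications, gains) is
  # absorbed into the null and only localized junction signal stands out
  if (!is.null(coverage)) {
    cv <- as.data.table(coverage)
    cA <- cv$value[match(bA$gbin, cv$gbin)]
    cB <- cv$value[match(bB$gbin, cv$gbin)]
    cA[is.na(cA)] <- 0; cB[is.na(cB)] <- 0
    # cap at the amplification scale (~6 copies): the product must absorb
    # copy number, not the block signal itself, which can dominate a
    # fusion-adjacent bin's trans marginal
    cA <- pmin(cA, 4); cB <- pmin(cB, 4)
    cp <- outer(cA, cB)
    if (!is.null(lam_override)) lam <- lam_override
    else {
      ok <- cp > 0
      if (any(ok)) lam <- median(X[ok] / cp[ok])
      if (lam <= 0) lam <- max(mean(X[ok] / cp[ok]), 1e-6)
    }
    Lam <- lam * cp
  } else {
    if (!is.null(lam_override)) lam <- lam_override
    Lam <- matrix(lam, nrow(X), ncol(X))
  }
  usable <- Lam > 0
  bs <- box_sum(X, params$smoothing_window)
  Lsm <- box_sum(Lam, params$smoothing_window)$sum
  pv <- ppois(bs$sum - 1, Lsm, lower.tail = FALSE)
  pv[!usable] <- 1
  padj <- matrix(p.adjust(pv, "BH"), nrow(X), ncol(X))
  mask <- padj <= params$fdr_alpha
  if (!any(mask)) return(empty_blocks())
  # independent raw-pixel support: a block must contain >= 2 significant
  # unsmoothed pixels, so a single Poisson spike cannot seed a call
  pv_raw <- ppois(X - 1, Lam, lower.tail = FALSE)
  pv_raw[!usable] <- 1
  raw_sig <- matrix(p.adjust(pv_raw, "BH"), nrow(X), ncol(X)) <=
    params$fdr_alpha
  lab <- label_components(mask)
  z <- (bs$sum - Lsm) / sqrt(pmax(Lsm, 1e-12))
  out <- rbindlist(lapply(seq_len(max(lab)), function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    rbindlist(lapply(split_anti_diagonal(w), function(ws)
      data.table(chromA = chromA,
                 startA = bA$start[min(ws[, 1])], endA = bA$end[max(ws[, 1])],
                 chromB = chromB,
                 startB = bB$start[min(ws[, 2])], endB = bB$end[max(ws[, 2])],
                 mean_z = mean(z[ws]), pixel_count = nrow(ws),
                 raw_support = sum(raw_sig[ws]))))
  }))
  out <- out[mean_z >= params$enrichment_z_min & raw_support >= 2L]
  out[, raw_support := NULL]
  out <- out[(endA - startA) >= params$min_segment_bp |
             (endB - startB) >= params$min_segment_bp]
  merge_blocks(out)
}

# One rearrangement produces one contiguous gradient region, but the far
# tail of the gradient can dip below significance and split the component.
# Blocks of a pair that overlap on either axis interval are therefore
# merged (complementary-quadrant reciprocal blocks are disjoint on both
# axes and stay separate).
merge_blocks <- function(bl, tol = 0) {
  if (nrow(bl) <= 1L) return(bl[])
  repeat {
    merged <- FALSE
    for (i in seq_len(nrow(bl) - 1L)) {
      for (j in (i + 1L):nrow(bl)) {
        ovA <- min(bl$endA[c(i, j)]) - max(bl$startA[c(i, j)]) > tol
        ovB <- min(bl$endB[c(i, j)]) - max(bl$startB[c(i, j)]) > tol
        if (ovA || ovB) {
          np <- bl$pixel_count[i] + bl$pixel_count[j]
          bl[i, `:=`(startA = min(bl$startA[c(i, j)]),
                     endA = max(bl$endA[c(i, j)]),
                     startB = min(bl$startB[c(i, j)]),
                     endB = max(bl$endB[c(i, j)]),
                     mean_z = (bl$mean_z[i] * bl$pixel_count[i] +
                               bl$mean_z[j] * bl$pixel_count[j]) / np,
                     pixel_count = np)]
          bl <- bl[-j]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  bl[]
}

# A reciprocal (balanced) translocation produces two enrichment blocks in
# complementary quadrants that touch at the breakpoint corner, so
# 8-connected labeling fuses them into one L-shaped component.  Split a
# component when a row cut separates its pixels into two parts with
# (near-)disjoint column ranges on opposite sides.
split_anti_diagonal <- function(w, min_pixels = 4L, tol = 1L) {
  rows <- sort(unique(w[, 1]))
  if (length(rows) < 2L || nrow(w) < 2L * min_pixels) return(list(w))
  # a reciprocal pair cuts both chromosomes: narrow strips cannot be one
  if (diff(range(w[, 1])) < 4L || diff(range(w[, 2])) < 4L) return(list(w))
  q <- function(x, p) unname(stats::quantile(x, p, type = 1))
  for (r0 in rows[-length(rows)]) {
    top <- w[w[, 1] <= r0, , drop = FALSE]
    bot <- w[w[, 1] > r0, , drop = FALSE]
    if (nrow(top) < min_pixels || nrow(bot) < min_pixels) next
    # anti-diagonal: top-right + bottom-left, or top-left + bottom-right
    # (column-quantile comparison tolerates smoothing spill at the corner;
    # a column cut then removes the spill from both parts)
    if (q(top[, 2], 0.1) >= q(bot[, 2], 0.9) - tol) {
      c0 <- floor((q(top[, 2], 0.1) + q(bot[, 2], 0.9)) / 2)
      out <- list(w[w[, 1] <= r0 & w[, 2] > c0, , drop = FALSE],
                  w[w[, 1] > r0 & w[, 2] <= c0, , drop = FALSE])
    } else if (q(top[, 2], 0.9) <= q(bot[, 2], 0.1) + tol) {
      c0 <- floor((q(top[, 2], 0.9) + q(bot[, 2], 0.1)) / 2)
      out <- list(w[w[, 1] <= r0 & w[, 2] <= c0, , drop = FALSE],
                  w[w[, 1] > r0 & w[, 2] > c0, , drop = FALSE])
    } else next
    if (all(vapply(out, nrow, 1L) >= min_pixels)) return(out)
  }
  list(w)
}

empty_blocks <- function() {
  data.table(chromA = character(), startA = numeric(), endA = numeric(),
             chromB = character(), startB = numeric(), endB = numeric(),
             mean_z = numeric(), pixel_count = integer())
}

# two-segment Poisson change-point on a count profile; returns the cut k
# (boundary between positions k and k+1) maximizing the likelihood, with
# the two segment means
poisson_changepoint <- function(y) {
  n <- length(y)
  if (n < 2L) return(list(k = NA_integer_, mu1 = mean(y), mu2 = mean(y), ll = 0))
  cs <- cumsum(y); tot <- cs[n]
  k <- seq_len(n - 1L)
  sl <- cs[k]; sr <- tot - sl
  nl <- k; nr <- n - k
  term <- function(s, m) ifelse(s > 0, s * log(s / m), 0)
  ll <- term(sl, nl) + term(sr, nr)
  best <- which.max(ll)
  list(k = best, mu1 = sl[best] / nl[best], mu2 = sr[best] / nr[best],
       ll = ll[best] - term(tot, n))
}

# extract a dense window (rows: chromA bins in [a1,a2), cols: chromB bins)
# from a contact matrix at its native resolution
window_block <- function(m, chromA, a1, a2, chromB, b1, b2) {
  bA <- m$bins$bins[chrom == chromA & end > a1 & start < a2]
  bB <- m$bins$bins[chrom == chromB & end > b1 & start < b2]
  list(X = dense_block(m, bA$gbin, bB$gbin), binsA = bA, binsB = bB)
}

# junction bin boundary from a marginal profile: the gradient decays away
# from the fusion point, so the junction is the boundary of the argmax bin
# on the side the signal falls off: bin start when the signal extends to
# the right, bin end when it extends to the left.  `pk` may be supplied
# (corner-consistent localization).
junction_boundary <- function(marg, coords, k = 3L, pk = NULL) {
  if (is.null(pk)) pk <- which.max(marg)
  n <- length(marg)
  left <- if (pk > 1) mean(marg[max(1L, pk - k):(pk - 1L)]) else -Inf
  right <- if (pk < n) mean(marg[(pk + 1L):min(n, pk + k)]) else -Inf
  sig_right <- right >= left
  list(peak = pk, bp = if (sig_right) coords$start[pk] else coords$end[pk],
       sig_right = sig_right)
}

# per-axis localization summary: junction boundary (conditioned on the
# other axis near the corner) plus how far the off-signal side of the
# full marginal sits above the expected flat background `bg` (a donor
# axis steps to background, excess ~ 0; an acceptor axis keeps signal on
# both sides of the insertion).
axis_profile <- function(marg_full, marg_local, coords, bg) {
  jb <- junction_boundary(marg_local, coords)
  pk <- jb$peak
  n <- length(marg_full)
  lo_side <- if (pk > 1) mean(marg_full[seq_len(pk - 1L)]) else NA_real_
  hi_side <- if (pk < n) mean(marg_full[(pk + 1L):n]) else NA_real_
  outside <- if (jb$sig_right) lo_side else hi_side
  signal <- if (jb$sig_right) hi_side else lo_side
  outside_excess <- if (is.na(outside)) 0 else
    max(0, (outside - bg) / max(bg, 1e-9))
  list(peak = pk, peak_bp = jb$bp, sig_right = jb$sig_right,
       outside_excess = outside_excess,
       signal = if (is.na(signal)) 0 else signal)
}

#' Localize a breakpoint within an enrichment block
#'
#' Formalizes gradient-based visual localization: within the block (plus a
#' margin) the junction is the maximum of the smoothed contact surface --
#' the point the enrichment gradient decays away from -- refined on each
#' axis as the argmax of the box-smoothed marginal profile.  Segment edges
#' away from the junction are placed by a two-segment Poisson change-point
#' fit on the marginals; the donor axis is the one whose profile steps to
#' background across the junction, and the orientation follows from which
#' segment end carries the junction.
#'
#' @param block one row of [trans_enrichment()] output.
#' @param m the matrix used for scanning (at `scan_bin`).
#' @param params a [detection_params()].
#' @param refine optional fine matrix or fetch function (see
#'   [hic_fetcher()]); when supplied, junction and edges are re-estimated
#'   at `refine_bin` in windows of half-width `refine_window`.
#' @return one-row data.table (an `sv_call`): donor/acceptor chromosomes,
#'   breakpoints, segment interval, orientation, score and uncertainty.
#' @export
localize_breakpoint <- function(block, m, params = detection_params(),
                                refine = NULL) {
  margin <- 2 * params$scan_bin
  binsA_all <- m$bins$bins[chrom == block$chromA]
  binsB_all <- m$bins$bins[chrom == block$chromB]
  lenA <- binsA_all[, max(end)]; lenB <- binsB_all[, max(end)]
  # flat background of the whole chromosome pair (robust to the block)
  bg <- median(dense_block(m, binsA_all$gbin, binsB_all$gbin))
  a1 <- max(0, block$startA - margin); a2 <- min(lenA, block$endA + margin)
  b1 <- max(0, block$startB - margin); b2 <- min(lenB, block$endB + margin)
  wb <- window_block(m, block$chromA, a1, a2, block$chromB, b1, b2)
  # corner-consistent junction: 2D argmax of the smoothed window picks one
  # junction corner; each axis marginal is then conditioned on the other
  # axis near that corner (interior insertions have two equivalent
  # corners, and mixing them would scramble the estimates)
  sm <- box_sum(wb$X, params$smoothing_window)$sum
  corner <- which(sm == max(sm), arr.ind = TRUE)[1L, ]
  ncol_loc <- max(1L, corner[2L] - 2L):min(ncol(wb$X), corner[2L] + 2L)
  nrow_loc <- max(1L, corner[1L] - 2L):min(nrow(wb$X), corner[1L] + 2L)
  profA <- axis_profile(rowSums(wb$X),
                        rowSums(wb$X[, ncol_loc, drop = FALSE]),
                        wb$binsA, bg * ncol(wb$X))
  profB <- axis_profile(colSums(wb$X),
                        colSums(wb$X[nrow_loc, , drop = FALSE]),
                        wb$binsB, bg * nrow(wb$X))
  junctionA <- profA$peak_bp
  junctionB <- profB$peak_bp
  unc <- m$bins$bin_size
  # segment edges away from the junction: the block bound on the signal
  # side of each axis
  edgeA <- if (profA$sig_right) block$endA else block$startA
  edgeB <- if (profB$sig_right) block$endB else block$startB

  if (!is.null(refine)) {
    rw <- params$refine_window
    fetch <- function(ca1, ca2, cb1, cb2) {
      ca1 <- max(0, ca1); ca2 <- min(lenA, ca2)
      cb1 <- max(0, cb1); cb2 <- min(lenB, cb2)
      mr <- if (is.function(refine))
        refine(block$chromA, ca1, ca2, block$chromB, cb1, cb2) else refine
      window_block(mr, block$chromA, ca1, ca2, block$chromB, cb1, cb2)
    }
    # Junction refinement: on each axis the junction is the boundary
    # between flat background and the gradient.  Conditioning the strip on
    # the near-junction bins of the other axis (its signal side) maximizes
    # the step contrast, and a two-segment Poisson change-point on the
    # strip marginal localizes the boundary to one refine bin.
    depth <- params$scan_bin
    half <- 2 * params$scan_bin
    strip_cp <- function(marg, coords, fallback) {
      if (length(marg) < 6L) return(fallback)
      cp <- poisson_changepoint(marg)
      if (is.na(cp$k) || max(cp$mu1, cp$mu2) < 2 * min(cp$mu1, cp$mu2) + 1e-9)
        return(fallback)
      bp <- coords$end[cp$k]
      # refinement must stay within one coarse bin of the scan estimate
      if (abs(bp - fallback) > params$scan_bin) fallback else bp
    }
    rowsA <- if (profA$sig_right) c(junctionA, junctionA + depth)
             else c(junctionA - depth, junctionA)
    ws <- fetch(rowsA[1], rowsA[2], junctionB - half, junctionB + half)
    if (nrow(ws$binsB) >= 6L && nrow(ws$binsA) >= 1L) {
      junctionB <- strip_cp(colSums(ws$X), ws$binsB, junctionB)
      unc <- params$refine_bin
    }
    colsB <- if (profB$sig_right) c(junctionB, junctionB + depth)
             else c(junctionB - depth, junctionB)
    ws <- fetch(junctionA - half, junctionA + half, colsB[1], colsB[2])
    if (nrow(ws$binsA) >= 6L && nrow(ws$binsB) >= 1L) {
      junctionA <- strip_cp(rowSums(ws$X), ws$binsA, junctionA)
      unc <- params$refine_bin
    }
    # refine the far segment edges: a two-segment Poisson change-point on
    # a strip marginal across the signal-to-background step
    ws <- fetch(edgeA - 2 * params$scan_bin, edgeA + 2 * params$scan_bin,
                junctionB - rw, junctionB + rw)
    if (nrow(ws$binsA) > 3) {
      cp <- poisson_changepoint(rowSums(ws$X))
      if (!is.na(cp$k)) edgeA <- ws$binsA$end[cp$k]
    }
    ws <- fetch(junctionA - rw, junctionA + rw,
                edgeB - 2 * params$scan_bin, edgeB + 2 * params$scan_bin)
    if (nrow(ws$binsB) > 3) {
      cp <- poisson_changepoint(colSums(ws$X))
      if (!is.na(cp$k)) edgeB <- ws$binsB$end[cp$k]
    }
  }

  # donor = axis whose off-signal side steps down to background; when
  # exactly one junction is interior to its chromosome, that axis carries
  # the donor segment (a near-terminal junction is an insertion site /
  # terminal fusion on the other chromosome)
  near_end <- function(bp, len) bp <= 2 * params$scan_bin ||
    bp >= len - 2 * params$scan_bin
  intA <- !near_end(junctionA, lenA); intB <- !near_end(junctionB, lenB)
  donor_is_A <- if (intA != intB) intA
  else if (profA$outside_excess != profB$outside_excess)
    profA$outside_excess < profB$outside_excess
  else profA$signal >= profB$signal
  don <- if (donor_is_A) list(chrom = block$chromA, junction = junctionA,
                              prof = profA, edge = edgeA, len = lenA)
         else list(chrom = block$chromB, junction = junctionB, prof = profB,
                   edge = edgeB, len = lenB)
  acc <- if (donor_is_A) list(chrom = block$chromB, junction = junctionB,
                              prof = profB, len = lenB)
         else list(chrom = block$chromA, junction = junctionA, prof = profA,
                   len = lenA)

  seg <- sort(c(don$junction, don$edge))
  # orientation from the junction corner's side pairing: '+' when the
  # donor's low-coordinate end joins the acceptor's upstream side (or,
  # equivalently for the other corner of an interior insertion, the high
  # end joins the downstream side)
  donor_at_start <- abs(don$junction - seg[1L]) <= abs(don$junction - seg[2L])
  orientation <- if (donor_at_start == !acc$prof$sig_right) "+" else "-"
  low_conf <- don$prof$outside_excess > 1
  data.table(kind = "translocation",
             chrom_donor = don$chrom, bp_donor = don$junction,
             seg_start = seg[1L], seg_end = seg[2L],
             orientation = if (low_conf) "unknown" else orientation,
             chrom_acceptor = acc$chrom,
             insertion_bp = acc$junction,
             insertion = format_insertion(acc$junction, acc$len, unc),
             classification = "unclassified",
             score = block$mean_z, uncertainty_bp = unc,
             low_confidence = low_conf,
             startA = block$startA, endA = block$endA,
             startB = block$startB, endB = block$endB,
             chromA = block$chromA, chromB = block$chromB)
}

format_insertion <- function(bp, chrom_len, unc) {
  if (bp <= 2 * unc) "ter:p"
  else if (bp >= chrom_len - 2 * unc) "ter:q"
  else format(bp, scientific = FALSE, trim = TRUE)
}

#' Classify translocation calls for one chromosome pair
#'
#' Reciprocal block pairs in complementary quadrants are balanced; single
#' blocks are classified by donor-segment coverage: elevated coverage
#' (>= 1.25 of the diploid expectation) indicates a translocated
#' duplication (the donor kept its copies), reduced coverage (< 0.75)
#' an unbalanced event with loss, and normal coverage an unbalanced moved
#' segment.  Blocks spanning at least `fusion_span_fraction` of a
#' chromosome with no internal change-point become terminal fusions with a
#' `ter` breakpoint.
#'
#' @param calls `sv_call` rows sharing one chromosome pair.
#' @param coverage optional normalized [coverage_track()].
#' @param params a [detection_params()].
#' @param genome optional `genome_model` (for chromosome lengths; inferred
#'   from calls otherwise).
#' @return the calls with `kind` and `classification` filled in.
#' @export
classify_translocation <- function(calls, coverage = NULL,
                                   params = detection_params(),
                                   genome = NULL) {
  calls <- copy(calls)
  if (!nrow(calls)) return(calls)
  # balanced: two calls whose blocks occupy complementary quadrants
  if (nrow(calls) >= 2L) {
    for (i in seq_len(nrow(calls) - 1L)) for (j in (i + 1L):nrow(calls)) {
      a <- calls[i]; b <- calls[j]
      same_pair <- a$chromA == b$chromA && a$chromB == b$chromB
      if (!same_pair) next
      tol <- 4 * params$scan_bin
      disjointA <- a$endA <= b$startA + tol || b$endA <= a$startA + tol
      disjointB <- a$endB <= b$startB + tol || b$endB <= a$startB + tol
      anti <- (a$startA < b$startA) != (a$startB < b$startB)
      if (disjointA && disjointB && anti)
        calls[c(i, j), classification := "balanced"]
    }
  }
  for (k in seq_len(nrow(calls))) {
    if (calls$classification[k] == "balanced") next
    don_len <- if (!is.null(genome)) chrom_length(genome, calls$chrom_donor[k])
      else NA_real_
    span <- calls$seg_end[k] - calls$seg_start[k]
    if (is.finite(don_len) && span / don_len >= params$fusion_span_fraction) {
      calls[k, `:=`(kind = "terminal_fusion", classification = "unbalanced")]
      next
    }
    if (!is.null(coverage)) {
      cv <- coverage[chrom == calls$chrom_donor[k] &
                     end > calls$seg_start[k] & start < calls$seg_end[k], value]
      ratio <- if (length(cv)) mean(cv) else NA_real_
      calls[k, classification :=
        if (!is.finite(ratio)) "unclassified"
        else if (ratio >= 1.25) "translocated_duplication"
        else "unbalanced"]
    } else calls[k, classification := "unclassified"]
  }
  calls[]
}

#' Genome-wide interchromosomal translocation detection
#'
#' Runs [trans_enrichment()] over all chromosome pairs, localizes each
#' block with [localize_breakpoint()] and classifies the calls.  When a
#' reference matrix from a karyotypically normal cell type is supplied,
#' blocks whose region is also enriched in the reference (putative assembly
#' artifacts) are vetoed.
#'
#' @param m a `contact_matrix` (scanned at `scan_bin`).
#' @param params a [detection_params()].
#' @param reference optional reference `contact_matrix`.
#' @param refine optional fine-resolution matrix or fetch function.
#' @param coverage optional normalized [coverage_track()] for
#'   classification.
#' @param genome optional `genome_model`.
#' @return an `sv_calls` data.table, one row per (donor segment, acceptor
#'   site).
#' @export
detect_translocations <- function(m, params = detection_params(),
                                  reference = NULL, refine = NULL,
                                  coverage = NULL, genome = NULL) {
  chroms <- matrix_genome_chroms(m)
  mc <- if (m$bins$bin_size < params$scan_bin)
    coarsen_matrix(m, params$scan_bin) else m
  ref_c <- if (!is.null(reference) && reference$bins$bin_size < params$scan_bin)
    coarsen_matrix(reference, params$scan_bin) else reference
  # trans-only coverage: the marginal over interchromosomal pixels tracks
  # copy number without the cis-driven (compartment/domain) variation that
  # would distort a coverage-product trans background
  cov_scan <- trans_coverage(mc, genome = genome)
  ref_cov <- if (!is.null(ref_c)) trans_coverage(ref_c, genome = genome)
  # genome-wide robust background: the median over chromosome pairs of the
  # pair-median coverage-normalized trans intensity.  A per-pair estimate
  # breaks down for derivative-chain pairs whose co-residency spans the
  # whole rectangle (the signal becomes its own background).
  lam_genome <- robust_trans_background(mc, cov_scan)
  ref_lam <- if (!is.null(ref_c)) robust_trans_background(ref_c, ref_cov)
  out <- list()
  for (ia in seq_along(chroms)[-length(chroms)])
    for (ib in (ia + 1L):length(chroms)) {
      bl <- trans_enrichment(mc, chroms[ia], chroms[ib], params, cov_scan,
                             lam_override = lam_genome)
      if (!nrow(bl)) next
      if (!is.null(ref_c)) {
        rbl <- trans_enrichment(ref_c, chroms[ia], chroms[ib], params, ref_cov,
                                lam_override = ref_lam)
        if (nrow(rbl)) {
          keep <- vapply(seq_len(nrow(bl)), function(k) {
            !any(rbl$startA < bl$endA[k] & rbl$endA > bl$startA[k] &
                 rbl$startB < bl$endB[k] & rbl$endB > bl$startB[k] &
                 rbl$mean_z >= params$enrichment_z_min)
          }, TRUE)
          bl <- bl[keep]
        }
        if (!nrow(bl)) next
      }
      calls <- rbindlist(lapply(seq_len(nrow(bl)), function(k)
        localize_breakpoint(bl[k], mc, params, refine = refine)))
      calls <- classify_translocation(calls, coverage, params, genome)
      out[[length(out) + 1L]] <- calls
    }
  res <- if (length(out)) rbindlist(out) else
    localize_skeleton()
  setattr(res, "class", c("sv_calls", class(res)))
  res[]
}

# per-bin marginal over interchromosomal pixels only, corrected for the
# own-chromosome exclusion (a bin on a large chromosome sees a smaller
# trans target) and normalized to the autosomal median
trans_coverage <- function(mc, genome = NULL) {
  b <- mc$bins$bins
  px <- mc$pixels[b$chrom[bin1] != b$chrom[bin2]]
  mt <- contact_matrix(mc$bins, px)
  cov <- coverage_track(mt, normalize = FALSE)
  nb <- cov[, .N, by = chrom]
  ntot <- sum(nb$N)
  cov[nb, on = "chrom", value := value / (ntot - i.N)]
  auto <- if (!is.null(genome))
    genome$chromosomes[chrom_class %in% c("macro", "micro"), name]
  else unique(cov$chrom)
  med <- cov[chrom %in% auto & value > 0, median(value)]
  if (is.finite(med) && med > 0) cov[, value := value / med]
  cov
}

# median over chromosome pairs of the pair-median coverage-normalized
# trans pixel intensity (zero cells included by rank arithmetic)
robust_trans_background <- function(mc, cov) {
  b <- mc$bins$bins
  cv <- cov$value
  px <- mc$pixels[b$chrom[bin1] != b$chrom[bin2]]
  if (!nrow(px)) return(1e-6)
  px <- px[cv[bin1] > 0 & cv[bin2] > 0]
  px[, `:=`(chrom1 = b$chrom[bin1], chrom2 = b$chrom[bin2],
            ratio = count / (cv[bin1] * cv[bin2]))]
  nb <- b[, .N, by = chrom]
  meds <- px[, {
    ncells <- nb[chrom == chrom1[1L], N] * nb[chrom == chrom2[1L], N]
    nz <- sort(ratio)
    m <- (ncells + 1) %/% 2
    zeros <- ncells - length(nz)
    .(med = if (m <= zeros) 0 else nz[m - zeros])
  }, by = .(chrom1, chrom2)]
  res <- median(meds$med[meds$med > 0])
  if (!is.finite(res) || res <= 0) 1e-6 else res
}

localize_skeleton <- function() {
  data.table(kind = character(), chrom_donor = character(),
             bp_donor = numeric(), seg_start = numeric(), seg_end = numeric(),
             orientation = character(), chrom_acceptor = character(),
             insertion_bp = numeric(), insertion = character(),
             classification = character(), score = numeric(),
             uncertainty_bp = numeric(), low_confidence = logical(),
             startA = numeric(), endA = numeric(), startB = numeric(),
             endB = numeric(), chromA = character(), chromB = character())
}
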