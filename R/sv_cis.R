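# --- binary segmentation with a BIC-style penalty ------------------------

# best single split of y[lo..hi] by RSS reduction
best_split <- function(y, lo, hi) {
  n <- hi - lo + 1L
  if (n < 2L) return(NULL)
  seg <- y[lo:hi]
  cs <- cumsum(seg); tot <- cs[n]
  k <- seq_len(n - 1L)
  rss0 <- sum(seg^2) - tot^2 / n
  rss1 <- (sum(seg^2)) - (cs[k]^2 / k + (tot - cs[k])^2 / (n - k))
  gain <- rss0 - rss1
  kbest <- which.max(gain)
  list(k = lo + kbest - 1L, gain = gain[kbest])
}

# recursive binary segmentation; returns sorted change-point positions
# (boundary after index k).  Penalty: gain must exceed pen * sigma2.
binary_segment <- function(y, sigma2, pen) {
  cps <- integer()
  recurse <- function(lo, hi) {
    sp <- best_split(y, lo, hi)
    if (is.null(sp) || sp$gain < pen * sigma2) return(invisible())
    cps <<- c(cps, sp$k)
    recurse(lo, sp$k)
    recurse(sp$k + 1L, hi)
  }
  recurse(1L, length(y))
  sort(cps)
}

cnv_state <- function(l2, del_het, del_hom, gain, ampl) {
  fifelse(l2 <= del_hom, "deletion_hom",
  fifelse(l2 <= del_het, "deletion_het",
  fifelse(l2 >= ampl, "amplification",
  fifelse(l2 >= gain, "gain", "neutral"))))
}

#' Coverage-based CNV segmentation
#'
#' Computes the per-bin log2 ratio of normalized coverage against a
#' reference track (or against the flat diploid expectation), segments it
#' by recursive binary segmentation with a BIC-style penalty, and labels
#' segments by their mean log2 ratio.  Thresholds separate the 1-, 0-, 3-
#' and >= 4-copy states of a diploid mixture: `<= -0.5` heterozygous
#' deletion, `<= -3` homozygous deletion, `>= +0.4` gain, `>= +1`
#' amplification.
#'
#' @param coverage a normalized [coverage_track()].
#' @param reference_coverage optional reference track on the same bins.
#' @param del_het,del_hom,gain_thr,ampl_thr log2-ratio thresholds.
#' @param penalty multiplier of `sigma^2` (noise variance, estimated from
#'   first differences) per accepted change-point; the default `2 * log(n)`
#'   per chromosome is used when `NULL`.
#' @param eps pseudo-count guarding `log2(0)`.
#' @return data.table (`chrom`, `start`, `end`, `log2_ratio`, `state`,
#'   `uncertainty_bins`), one row per non-neutral segment.
#' @export
cnv_segments <- function(coverage, reference_coverage = NULL,
                         del_het = -0.5, del_hom = -3,
                         gain_thr = 0.4, ampl_thr = 1,
                         penalty = NULL, eps = 0.01) {
  cov <- as.data.table(coverage)
  med <- cov[value > 0, median(value)]
  v <- cov$value / med
  vr <- if (!is.null(reference_coverage)) {
    rr <- as.data.table(reference_coverage)
    stopifnot(nrow(rr) == nrow(cov))
    rr$value / rr[value > 0, median(value)]
  } else rep(1, nrow(cov))
  y <- log2((v + eps) / (vr + eps))
  out <- list()
  for (chr in unique(cov$chrom)) {
    idx <- which(cov$chrom == chr)
    yy <- y[idx]
    n <- length(yy)
    if (n < 2L) next
    sigma2 <- max(var(diff(yy)) / 2, 1e-6)
    pen <- if (is.null(penalty)) 2 * log(n) else penalty
    cps <- binary_segment(yy, sigma2, pen)
    bounds <- c(0L, cps, n)
    for (s in seq_len(length(bounds) - 1L)) {
      i1 <- bounds[s] + 1L; i2 <- bounds[s + 1L]
      l2 <- mean(yy[i1:i2])
      st <- cnv_state(l2, del_het, del_hom, gain_thr, ampl_thr)
      if (st == "neutral") next
      out[[length(out) + 1L]] <- data.table(
        chrom = chr, start = cov$start[idx[i1]], end = cov$end[idx[i2]],
        log2_ratio = l2, state = st, uncertainty_bins = 1L)
    }
  }
  res <- if (length(out)) rbindlist(out) else
    data.table(chrom = character(), start = numeric(), end = numeric(),
               log2_ratio = numeric(), state = character(),
               uncertainty_bins = integer())
  # merge touching segments of the same state
  if (nrow(res) > 1L) {
    setorder(res, chrom, start)
    res[, run := cumsum(c(1L, (chrom[-1] != chrom[-.N]) |
                            (start[-1] != end[-.N]) |
                            (state[-1] != state[-.N])))]
    res <- res[, .(chrom = chrom[1L], start = min(start), end = max(end),
                   log2_ratio = mean(log2_ratio), state = state[1L],
                   uncertainty_bins = 1L), by = run][, run := NULL]
  }
  res[]
}

# depth-matched elementwise log2 ratio of two dense blocks
log_ratio_block <- function(X, R) {
  sR <- sum(R); sX <- sum(X)
  scale <- if (sR > 0 && sX > 0) sX / sR else 1
  log2((X + 1) / (R * scale + 1))
}

#' Detect large inversions against a reference map
#'
#' An inversion of `[a, b]` relocates contacts into two "butterfly" corner
#' boxes around the breakpoints: just-outside-`a` versus just-inside-`b`,
#' and just-inside-`a` versus just-outside-`b`.  Candidate breakpoint
#' pairs on a coarse grid are scored by the mean observed/reference log
#' ratio in the two wings minus the mean in control boxes at the same
#' offsets; candidates above `inv_score_min` are refined by local search.
#' A reference map of the same chromosome is required (the pattern is
#' defined comparatively).
#'
#' @param m observed `contact_matrix`.
#' @param reference reference `contact_matrix` (normal karyotype).
#' @param chrom chromosome to scan.
#' @param params a [detection_params()].
#' @param wing_bins wing box size in bins (default `2 * inv_grid_bins`).
#' @return data.table (`kind`, `chrom`, `start`, `end`, `score`).
#' @export
detect_inversion <- function(m, reference, chrom, params = detection_params(),
                             wing_bins = NULL) {
  if (is.null(reference)) stop("inversion detection requires a reference map")
  chr <- chrom
  stopifnot(m$bins$bin_size == reference$bins$bin_size)
  b <- m$bins$bins[chrom == chr]
  X <- dense_block(m, b$gbin, b$gbin)
  R <- dense_block(reference, chrom_gbins(reference, chr), chrom_gbins(reference, chr))
  stopifnot(all(dim(X) == dim(R)))
  LR <- log_ratio_block(X, R)
  n <- nrow(X)
  d <- if (is.null(wing_bins)) 2L * params$inv_grid_bins else as.integer(wing_bins)
  step <- params$inv_grid_bins
  score_ab <- function(a, bb) {
    if (a - d < 1L || bb + d > n || bb - a < 2L * d) return(-Inf)
    w1 <- LR[(a - d):(a - 1L), (bb - d):(bb - 1L)]
    w2 <- LR[a:(a + d - 1L), bb:(bb + d - 1L)]
    c1 <- LR[(a - d):(a - 1L), bb:(bb + d - 1L)]
    c2 <- LR[a:(a + d - 1L), (bb - d):(bb - 1L)]
    (mean(w1) + mean(w2)) / 2 - (mean(c1) + mean(c2)) / 2
  }
  cand <- CJ(a = seq(d + 1L, n, by = step), b2 = seq(d + 1L, n, by = step))[b2 - a >= 2L * d]
  if (!nrow(cand)) return(inversion_skeleton())
  cand[, score := mapply(score_ab, a, b2)]
  cand <- cand[score >= params$inv_score_min][order(-score)]
  out <- list()
  taken <- cand[0L]
  for (k in seq_len(nrow(cand))) {
    ck <- cand[k]
    if (nrow(taken) && taken[abs(a - ck$a) <= 2L * step &
                             abs(b2 - ck$b2) <= 2L * step, .N] > 0) next
    # local refinement
    best <- ck
    for (da in -step:step) for (db in -step:step) {
      s <- score_ab(ck$a + da, ck$b2 + db)
      if (s > best$score) best <- data.table(a = ck$a + da, b2 = ck$b2 + db, score = s)
    }
    taken <- rbind(taken, best)
    out[[length(out) + 1L]] <- data.table(
      kind = "inversion", chrom = chr,
      start = b$start[best$a], end = b$end[best$b2 - 1L], score = best$score)
  }
  if (!length(out)) return(inversion_skeleton())
  rbindlist(out)[]
}

inversion_skeleton <- function() {
  data.table(kind = character(), chrom = character(), start = numeric(),
             end = numeric(), score = numeric())
}

#' Detect cis deletions combining coverage and gap-bridging contacts
#'
#' Deletions remove coverage and, because the flanks become adjacent on the
#' derivative chromosome, enrich apparent contacts across the deleted gap.
#' Candidate intervals come from [cnv_segments()] (deletion states); each
#' is scored by the mean observed/reference log ratio in the flank-bridging
#' box.
#'
#' @param m observed `contact_matrix`.
#' @param reference reference `contact_matrix`.
#' @param chrom chromosome to scan.
#' @param params a [detection_params()].
#' @param flank_bins bridge box size in bins (default 5).
#' @return data.table (`kind`, `chrom`, `start`, `end`, `state`,
#'   `log2_ratio`, `bridge_score`).
#' @export
detect_cis_deletion <- function(m, reference, chrom,
                                params = detection_params(), flank_bins = 5L) {
  if (is.null(reference)) stop("cis deletion detection requires a reference map")
  chr <- chrom
  cov <- coverage_track(m)
  rcov <- coverage_track(reference)
  cnv <- cnv_segments(cov[chrom == chr], rcov[chrom == chr])
  cnv <- cnv[state %in% c("deletion_het", "deletion_hom")]
  if (!nrow(cnv)) return(data.table(kind = character(), chrom = character(),
                                    start = numeric(), end = numeric(),
                                    state = character(), log2_ratio = numeric(),
                                    bridge_score = numeric()))
  b <- m$bins$bins[chrom == chr]
  X <- dense_block(m, b$gbin, b$gbin)
  R <- dense_block(reference, chrom_gbins(reference, chr),
                   chrom_gbins(reference, chr))
  LR <- log_ratio_block(X, R)
  n <- nrow(X)
  bs <- m$bins$bin_size
  cnv[, bridge_score := {
    a <- pmax(1L, as.integer(start / bs) + 1L)
    bb <- pmin(n, as.integer(ceiling(end / bs)))
    vapply(seq_len(.N), function(k) {
      lo <- max(1L, a[k] - flank_bins); hi <- min(n, bb[k] + flank_bins)
      if (a[k] - lo < 1L || hi - bb[k] < 1L) return(NA_real_)
      mean(LR[lo:(a[k] - 1L), (bb[k] + 1L):hi])
    }, 0)
  }]
  cnv[, .(kind = "deletion", chrom, start, end, state, log2_ratio, bridge_score)]
}
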