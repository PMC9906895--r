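# leading eigenvector of a symmetric matrix by power iteration
# (deterministic start; we only need the dominant pair)
leading_eigen <- function(C, iter = 1000, tol = 1e-12) {
  n <- nrow(C)
  v <- rep(1 / sqrt(n), n)
  alt <- seq(1, n, by = 2)
  v[alt] <- v[alt] + 1e-3  # deterministic asymmetric start
  v <- v / sqrt(sum(v^2))
  lam <- 0
  for (k in seq_len(iter)) {
    w <- as.vector(C %*% v)
    nw <- sqrt(sum(w^2))
    if (nw == 0) break
    w <- w / nw
    lam2 <- sum(w * as.vector(C %*% w))
    done <- abs(lam2 - lam) < tol * max(1, abs(lam2))
    v <- w; lam <- lam2
    if (done) break
  }
  list(vector = v, value = lam)
}

# observed/expected by per-diagonal mean on a dense cis matrix
obs_over_exp <- function(M) {
  n <- nrow(M)
  oe <- matrix(0, n, n)
  d <- row(M) - col(M)
  for (k in 0:(n - 1)) {
    idx <- which(abs(d) == k)
    mu <- mean(M[idx])
    oe[idx] <- if (mu > 0) M[idx] / mu else 0
  }
  oe
}

#' A/B compartment eigenvector for one chromosome
#'
#' The classical pipeline: coarsen to `bin_size`, mask low-coverage bins
#' (zeros and the bottom 2% of the marginal), divide by the expected
#' per-diagonal mean (observed/expected), compute the Pearson correlation
#' matrix of its columns and take its leading eigenvector.  The sign is
#' arbitrary until [orient_sign()] is applied; `A` corresponds to positive
#' values after orientation.
#'
#' @param m a `contact_matrix`.
#' @param chrom chromosome name.
#' @param bin_size working bin size (default 50 kb).
#' @return data.table (`chrom`, `start`, `end`, `value`, `label`) of class
#'   `compartment_track`, with attributes `variance_explained` (leading
#'   eigenvalue over trace of the correlation matrix), `reliable`
#'   (`variance_explained >= 0.1`) and `bin_size`.
#' @export
compartment_eigenvector <- function(m, chrom, bin_size = 50e3) {
  chr <- chrom
  mc <- coarsen_matrix(m, bin_size)
  b <- mc$bins$bins[chrom == chr]
  if (nrow(b) < 20L) stop("chromosome has fewer than 20 bins at this resolution")
  M <- dense_block(mc, b$gbin, b$gbin)
  marg <- rowSums(M)
  cut <- stats::quantile(marg[marg > 0], 0.02, na.rm = TRUE)
  keep <- marg > 0 & marg >= cut
  if (sum(keep) < 20L) stop("all (or nearly all) bins masked on this chromosome")
  Mk <- M[keep, keep, drop = FALSE]
  oe <- obs_over_exp(Mk)
  C <- suppressWarnings(cor(oe))
  C[!is.finite(C)] <- 0
  le <- leading_eigen(C)
  ve <- le$value / sum(diag(C))
  val <- rep(NA_real_, nrow(b))
  val[keep] <- le$vector
  out <- b[, .(chrom, start, end, value = val)]
  out[, label := fifelse(is.na(value), NA_character_,
                         fifelse(value > 0, "A", "B"))]
  setattr(out, "variance_explained", ve)
  setattr(out, "reliable", is.finite(ve) && ve >= 0.1)
  setattr(out, "bin_size", bin_size)
  setattr(out, "class", c("compartment_track", class(out)))
  out[]
}

#' Orient a compartment eigenvector with an activity proxy
#'
#' The eigenvector sign is arbitrary; the track is flipped, if needed, so
#' that its correlation with a per-bin activity proxy (planted signal for
#' synthetic maps, e.g. coverage or gene density for real ones) is
#' positive, making `A` = positive.
#'
#' @param track a `compartment_track`.
#' @param proxy numeric vector, one value per bin of `track`.
#' @return the oriented track; attribute `orientation_ambiguous` is TRUE
#'   when `|r| < 0.05`.
#' @export
orient_sign <- function(track, proxy) {
  stopifnot(length(proxy) == nrow(track))
  ok <- !is.na(track$value) & !is.na(proxy)
  if (!any(ok) || var(proxy[ok]) == 0) stop("zero-variance orientation proxy")
  r <- cor(track$value[ok], proxy[ok])
  out <- copy(track)
  if (is.finite(r) && r < 0) {
    out[, value := -value]
    out[, label := fifelse(is.na(value), NA_character_,
                           fifelse(value > 0, "A", "B"))]
  }
  setattr(out, "variance_explained", attr(track, "variance_explained"))
  setattr(out, "reliable", attr(track, "reliable"))
  setattr(out, "bin_size", attr(track, "bin_size"))
  setattr(out, "orientation_ambiguous", !is.finite(r) || abs(r) < 0.05)
  out[]
}

#' Correlation between two compartment profiles
#'
#' Genome-wide (or chromosome-wide) Pearson correlation of two eigenvector
#' tracks over bins that are non-NA in both.
#'
#' @param t1,t2 `compartment_track`s on the same bins.
#' @return Pearson r.
#' @export
compare_compartments <- function(t1, t2) {
  if (nrow(t1) != nrow(t2) ||
      !isTRUE(all.equal(t1[, .(chrom, start)], t2[, .(chrom, start)])))
    stop("tracks are on different bins")
  ok <- !is.na(t1$value) & !is.na(t2$value)
  if (sum(ok) < 10L) stop("fewer than 10 shared non-NA bins")
  cor(t1$value[ok], t2$value[ok])
}

#' Compartment switch intervals between two profiles
#'
#' Contiguous runs of bins whose A/B label differs between the two tracks,
#' with the switch direction relative to `t1` -> `t2`.
#'
#' @param t1,t2 `compartment_track`s on the same bins.
#' @return data.table (`chrom`, `start`, `end`, `direction`), `direction`
#'   being `"A->B"` or `"B->A"`.
#' @export
compartment_switch_bins <- function(t1, t2) {
  stopifnot(nrow(t1) == nrow(t2))
  dt <- data.table(chrom = t1$chrom, start = t1$start, end = t1$end,
                   l1 = t1$label, l2 = t2$label)
  dt <- dt[!is.na(l1) & !is.na(l2)]
  dt[, direction := fifelse(l1 == l2, NA_character_, paste0(l1, "->", l2))]
  dt <- dt[!is.na(direction)]
  if (!nrow(dt)) return(data.table(chrom = character(), start = numeric(),
                                   end = numeric(), direction = character()))
  dt[, run := cumsum(c(1L, (chrom[-1] != chrom[-.N]) |
                         (start[-1] != end[-.N]) |
                         (direction[-1] != direction[-.N])))]
  dt[, .(chrom = chrom[1L], start = min(start), end = max(end),
         direction = direction[1L]), by = run][, run := NULL][]
}
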