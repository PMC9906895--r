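#' Domain-calling parameters
#'
#' @param gamma_grid resolution parameters of the Armatus-style objective
#'   (default 0.2, 0.25, 0.3; larger gamma favors smaller domains).
#' @param bin_size working bin size (default 50 kb).
#' @param min_domain_bins minimum domain length in bins (default 2).
#' @param max_domain_mb cap on domain length in Mb (default 6), bounding the
#'   dynamic program; visible domains in vertebrate maps are at most a few Mb.
#' @return a `domain_params` object.
#' @export
domain_params <- function(gamma_grid = c(0.2, 0.25, 0.3), bin_size = 50e3,
                          min_domain_bins = 2L, max_domain_mb = 6) {
  stopifnot(all(gamma_grid >= 0), min_domain_bins >= 1)
  structure(list(gamma_grid = gamma_grid, bin_size = bin_size,
                 min_domain_bins = as.integer(min_domain_bins),
                 max_domain_mb = max_domain_mb), class = "domain_params")
}

as_dense_cis <- function(m, chrom) {
  if (is.matrix(m)) return(m)
  stopifnot(inherits(m, "contact_matrix"))
  dense_chrom(m, chrom)
}

# triangle sums S[i, l] = sum of M[a, b], i <= a <= b <= i+l-1 (window of
# length l starting at i), for l = 1..Lmax; returned as an n x Lmax matrix.
triangle_sums <- function(M, Lmax) {
  n <- nrow(M)
  CS <- apply(M, 2, cumsum)            # CS[a, j] = sum M[1..a, j]
  S <- matrix(NA_real_, n, Lmax)
  S[, 1] <- diag(M)
  if (Lmax >= 2) for (l in 2:Lmax) {
    i <- seq_len(n - l + 1)
    j <- i + l - 1
    prev <- numeric(length(i))
    ok <- i > 1
    prev[ok] <- CS[cbind(i[ok] - 1L, j[ok])]
    S[i, l] <- S[i, l - 1] + CS[cbind(j, j)] - prev
  }
  S
}

# scaled window scores and their per-length means
armatus_q <- function(M, gamma, Lmax) {
  n <- nrow(M)
  S <- triangle_sums(M, Lmax)
  lens <- seq_len(Lmax)
  scl <- matrix(lens^gamma, n, Lmax, byrow = TRUE)  # (l-1+1)^gamma = l^gamma
  sg <- S / scl
  mu <- colMeans(sg, na.rm = TRUE)
  q <- sweep(sg, 2, mu, "-")
  q
}

#' Armatus window quality score
#'
#' `q_gamma(i, j) = s_gamma(i, j) - mu_gamma(l)` where
#' `s_gamma(i, j)` is the sum of all matrix entries inside the window
#' `[i, j]` (upper triangle including the diagonal) divided by
#' `(l + 1)^gamma`, `l = j - i`, and `mu_gamma(l)` is the mean of
#' `s_gamma` over all windows of that length on the chromosome.
#'
#' @param m a `contact_matrix` or a dense symmetric matrix.
#' @param chrom chromosome (ignored for dense input).
#' @param i,j window bounds, 1-based bin indices on the chromosome, `i <= j`.
#' @param gamma resolution parameter.
#' @return the quality score (vectorized over `i`, `j`).
#' @export
domain_quality <- function(m, chrom = NULL, i, j, gamma) {
  M <- as_dense_cis(m, chrom)
  stopifnot(all(i <= j), all(i >= 1), all(j <= nrow(M)))
  q <- armatus_q(M, gamma, Lmax = max(j - i + 1L))
  q[cbind(i, j - i + 1L)]
}

#' Armatus-style optimal domain segmentation
#'
#' Dynamic program `OPT(j) = max_{i <= j} OPT(i-1) + max(q_gamma(i,j), 0)`
#' with `OPT(0) = 0`; windows with non-positive quality (or shorter than
#' `min_domain_bins`) contribute zero and become gaps.  Ties are broken
#' toward the longer terminal domain, then leftmost; output is
#' deterministic.
#'
#' @param m a `contact_matrix` or dense symmetric matrix.
#' @param chrom chromosome name (ignored for dense input).
#' @param gamma resolution parameter.
#' @param params a [domain_params()].
#' @return a `domain_set`: data.table (`chrom`, `start_bin`, `end_bin`,
#'   `gamma`, `q`) of non-overlapping domains (1-based inclusive bins),
#'   with attributes `bin_size`, `n_bins` and `opt_score`.
#' @export
armatus_segment <- function(m, chrom = NULL, gamma = 0.25,
                            params = domain_params()) {
  M <- as_dense_cis(m, chrom)
  n <- nrow(M)
  if (n < params$min_domain_bins) stop("chromosome shorter than min_domain_bins")
  Lmax <- max(1L, min(n, as.integer(params$max_domain_mb * 1e6 / params$bin_size)))
  q <- armatus_q(M, gamma, Lmax)
  minb <- params$min_domain_bins
  opt <- numeric(n + 1L)          # opt[j+1] = OPT(j)
  back <- integer(n)
  eps <- 1e-9
  for (j in seq_len(n)) {
    lo <- max(1L, j - Lmax + 1L)
    is <- lo:j
    lens <- j - is + 1L
    contrib <- q[cbind(is, lens)]
    contrib[lens < minb | contrib <= 0 | is.na(contrib)] <- 0
    vals <- opt[is] + contrib
    best <- max(vals)
    pick <- is[which(vals >= best - eps)[1L]]  # smallest i = longest window
    opt[j + 1L] <- best
    back[j] <- pick
  }
  doms <- list()
  j <- n
  while (j >= 1L) {
    i <- back[j]
    len <- j - i + 1L
    qv <- q[i, len]
    if (len >= minb && !is.na(qv) && qv > 0)
      doms[[length(doms) + 1L]] <- data.table(start_bin = i, end_bin = j, q = qv)
    j <- i - 1L
  }
  out <- if (length(doms)) rbindlist(rev(doms)) else
    data.table(start_bin = integer(), end_bin = integer(), q = numeric())
  out[, `:=`(chrom = if (is.null(chrom)) NA_character_ else chrom, gamma = gamma)]
  setcolorder(out, c("chrom", "start_bin", "end_bin", "gamma", "q"))
  setattr(out, "bin_size", params$bin_size)
  setattr(out, "n_bins", n)
  setattr(out, "opt_score", opt[n + 1L])
  setattr(out, "class", c("domain_set", class(out)))
  out[]
}

#' Multi-gamma consensus domains
#'
#' Union of the optimal segmentations over the gamma grid: exact duplicates
#' are merged (their gammas recorded), while overlapping domains from
#' different gammas are retained as hierarchy levels (larger gamma = finer).
#'
#' @inheritParams armatus_segment
#' @return a `domain_set` with one row per distinct domain and a `gammas`
#'   column listing the gammas that produced it.
#' @export
consensus_domains <- function(m, chrom = NULL, params = domain_params()) {
  M <- as_dense_cis(m, chrom)
  all <- rbindlist(lapply(sort(params$gamma_grid), function(g)
    armatus_segment(M, chrom, g, params)))
  if (!nrow(all)) {
    setattr(all, "bin_size", params$bin_size)
    setattr(all, "n_bins", nrow(M))
    setattr(all, "class", c("domain_set", class(all)))
    return(all[])
  }
  out <- all[, .(gammas = paste(sort(unique(gamma)), collapse = ","),
                 q = max(q)), by = .(chrom, start_bin, end_bin)]
  setorder(out, start_bin, end_bin)
  setattr(out, "bin_size", params$bin_size)
  setattr(out, "n_bins", nrow(M))
  setattr(out, "class", c("domain_set", class(out)))
  out[]
}

domain_boundaries <- function(d) sort(unique(c(d$start_bin, d$end_bin + 1L)))

#' Fraction of shared domain boundaries
#'
#' Fraction of `d1`'s boundaries that have a boundary of `d2` within
#' `tol_bins` bins (1 bin tolerance at 50 kb is the conventional accuracy
#' for cross-cell-type TAD comparisons).
#'
#' @param d1,d2 `domain_set`s on the same chromosome and bin size.
#' @param tol_bins matching tolerance in bins (default 1).
#' @return fraction in `[0, 1]`.
#' @export
boundary_overlap <- function(d1, d2, tol_bins = 1L) {
  if (!nrow(d1)) stop("d1 has no domains (no boundaries to compare)")
  b1 <- domain_boundaries(d1); b2 <- domain_boundaries(d2)
  if (!length(b2)) return(0)
  mean(vapply(b1, function(x) any(abs(b2 - x) <= tol_bins), TRUE))
}

domain_partition <- function(d, n_bins = attr(d, "n_bins")) {
  stopifnot(!is.null(n_bins))
  lab <- -(seq_len(n_bins))      # gaps: one singleton cluster per bin
  if (nrow(d)) for (k in seq_len(nrow(d)))
    lab[d$start_bin[k]:d$end_bin[k]] <- k
  lab
}

#' Variation of information between two segmentations
#'
#' Entropy-based distance between the bin partitions induced by two domain
#' sets (gap bins count as singleton clusters): `VI = H(P1) + H(P2) -
#' 2 I(P1; P2)` in bits.  Zero iff the partitions are identical; symmetric.
#'
#' @param d1,d2 `domain_set`s over the same chromosome extent.
#' @param n_bins number of bins (defaults to the `n_bins` attribute).
#' @return VI in bits (>= 0).
#' @export
variation_of_information <- function(d1, d2, n_bins = NULL) {
  n <- n_bins %||% attr(d1, "n_bins") %||% attr(d2, "n_bins")
  p1 <- domain_partition(d1, n); p2 <- domain_partition(d2, n)
  tab <- table(p1, p2) / n
  pr1 <- rowSums(tab); pr2 <- colSums(tab)
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  Hj <- H(as.vector(tab))
  mi <- H(pr1) + H(pr2) - Hj
  max(0, H(pr1) + H(pr2) - 2 * mi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
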