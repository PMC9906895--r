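# ---- internal machinery for the generative contact model ----------------

# Cell-population components of the mixture: list of (karyotype, weight).
mixture_components <- function(karyotype, params) {
  w <- params$het_mixture_weight
  if (length(karyotype$edits) == 0L || w == 1)
    return(list(list(kar = karyotype, u = 1)))
  idk <- identity_karyotype(karyotype$genome)
  if (w == 0) return(list(list(kar = idk, u = 1)))
  list(list(kar = karyotype, u = w), list(kar = idk, u = 1 - w))
}

# Copy table: one row per (reference bin, derivative residence).  Bins are
# assigned to segments by midpoint; `dmid` is the derivative coordinate of
# the bin midpoint, `dcid` a globally unique derivative-chromosome id.
component_copies <- function(kar, bins, dcid_offset = 0L) {
  segs <- karyotype_segments(kar)
  segs[, dcid := .GRP + dcid_offset, by = .(hap, dchrom)]
  b <- copy(bins)
  b[, `:=`(refmid = (start + end) / 2, width = end - start)]
  hit <- segs[b, on = .(chrom, start <= refmid, end > refmid),
              .(gbin = i.gbin, chrom = i.chrom, refmid = i.refmid,
                width = i.width, dcid = x.dcid, orientation = x.orientation,
                dstart = x.dstart, segstart = x.start, segend = x.end),
              nomatch = NULL, allow.cartesian = TRUE]
  hit[, dmid := fifelse(orientation == "+",
                        dstart + (refmid - segstart),
                        dstart + (segend - refmid))]
  hit[, .(gbin, chrom, refmid, width, dcid, dmid)]
}

# factor (1+tau)^k for planted-domain co-membership, applied to pair vectors
tad_factor <- function(params, chrom1, pos1, chrom2, pos2) {
  f <- rep(1, length(pos1))
  if (is.null(params$tads) || params$tad_boost == 0) return(f)
  for (k in seq_len(nrow(params$tads))) {
    d <- params$tads[k]
    inside <- chrom1 == d$chrom & chrom2 == d$chrom &
      pos1 >= d$start & pos1 < d$end & pos2 >= d$start & pos2 < d$end
    f[inside] <- f[inside] * (1 + params$tad_boost)
  }
  f
}

# Structural (co-resident power-law) pixel table for one component.
# Returns data.table(gi, gj, S, CO): S = u * area * decay * factors summed
# over co-resident copy pairs; CO = u * area summed over distinct-copy
# co-resident pairs (background combinations already accounted for).
structural_pixels <- function(copies, params, u) {
  out <- vector("list", 0L)
  a <- params$decay_exponent; s0 <- params$decay_offset
  delta <- params$compartment_strength
  for (id in unique(copies$dcid)) {
    cc <- copies[dcid == id][order(dmid)]
    n <- nrow(cc)
    if (n == 0L) next
    i <- rep.int(seq_len(n), rev(seq_len(n)))
    j <- sequence(rev(seq_len(n))) + i - 1L
    s <- abs(cc$dmid[j] - cc$dmid[i])
    lam <- (s + s0)^(-a)
    if (delta > 0) {
      e1 <- comp_signal(params, cc$chrom[i], cc$refmid[i])
      e2 <- comp_signal(params, cc$chrom[j], cc$refmid[j])
      lam <- lam * (1 + delta * e1 * e2)
    }
    lam <- lam * tad_factor(params, cc$chrom[i], cc$refmid[i],
                            cc$chrom[j], cc$refmid[j])
    gi <- pmin(cc$gbin[i], cc$gbin[j]); gj <- pmax(cc$gbin[i], cc$gbin[j])
    area <- cc$width[i] * cc$width[j]
    area[gi == gj & i == j] <- (cc$width[i][gi == gj & i == j])^2 / 2
    co <- as.numeric(i != j)
    out[[length(out) + 1L]] <-
      data.table(gi = gi, gj = gj, S = u * area * lam, CO = u * area * co)
  }
  if (!length(out)) return(data.table(gi = integer(), gj = integer(),
                                      S = numeric(), CO = numeric()))
  rbindlist(out)[, .(S = sum(S), CO = sum(CO)), by = .(gi, gj)]
}

# copy-count vector per global bin for one component
copy_counts <- function(copies, nbins) {
  n <- rep(0L, nbins)
  tab <- copies[, .N, by = gbin]
  n[tab$gbin] <- tab$N
  n
}

#' Calibrate the simulator's background and scale
#'
#' Computes, at a fixed internal grid (250 kb), the unit background density
#' `B_t` that gives the unedited genome the target cis/trans ratio (unless
#' `trans_background` is numeric), and the global scale factor mapping unit
#' densities to `total_contacts` expected genome-wide contacts for the
#' actual karyotype.
#'
#' @param karyotype a `derivative_karyotype`.
#' @param params a `simulation_params`.
#' @return list with `Bt`, `scale`, `cal_bin`.
#' @export
calibrate_simulation <- function(karyotype, params) {
  genome <- karyotype$genome
  cal_bin <- min(250e3, max(genome$chromosomes$length) / 4)
  bt <- bin_table(genome, cal_bin)
  bins <- bt$bins
  nb <- nrow(bins)
  widths <- bins[, end - start]

  # identity-genome quantities for the cis/trans target
  idk <- identity_karyotype(genome)
  cop_id <- component_copies(idk, bins)
  S_id <- structural_pixels(cop_id, params, u = 1)
  n_id <- copy_counts(cop_id, nb)
  an <- widths * n_id
  chrom_of <- bins$chrom
  # background area-combinations, split cis/trans (closed forms)
  per_chr <- data.table(chrom = chrom_of, an = an, w = widths, n = n_id)[
    , .(Tsum = sum(an), sq = sum(an^2), d2 = sum(w^2 / 2 * n * (n - 1) / 2)),
    by = chrom]
  G_cis_off <- per_chr[, sum((Tsum^2 - sq) / 2)]
  CO_cis <- S_id[, sum(CO)]  # identity co-residency is all cis
  G_cis <- G_cis_off + per_chr[, sum(d2)] - CO_cis
  G_trans <- (sum(an)^2 - sum(per_chr$Tsum^2)) / 2
  S_cis <- S_id[, sum(S)] * params$cis_scale

  Bt <- if (identical(params$trans_background, "auto")) {
    # fallback for genomes where the target ratio is unattainable (single
    # chromosome, or very unequal chromosome sizes): background equals the
    # cis density at half-genome separation
    fallback <- params$cis_scale *
      (sum(genome$chromosomes$length) / 2 + params$decay_offset)^(-params$decay_exponent)
    denom <- params$cis_trans_target * G_trans - G_cis
    if (G_trans <= 0 || denom <= 0) fallback else S_cis / denom
  } else params$trans_background

  # expected unit total for the actual karyotype
  comps <- mixture_components(karyotype, params)
  S_tot <- 0; CO_tot <- 0; G_tot <- 0
  off <- 0L
  for (cm in comps) {
    cop <- component_copies(cm$kar, bins, dcid_offset = off)
    off <- off + cop[, uniqueN(dcid)]
    sp <- structural_pixels(cop, params, u = cm$u)
    S_tot <- S_tot + sp[, sum(S)]
    CO_tot <- CO_tot + sp[, sum(CO)]
    nn <- copy_counts(cop, nb)
    ann <- widths * nn
    G_tot <- G_tot + cm$u * ((sum(ann)^2 - sum(ann^2)) / 2 +
                               sum(widths^2 / 2 * nn * (nn - 1) / 2))
  }
  T_unit <- params$cis_scale * S_tot + Bt * (G_tot - CO_tot)
  list(Bt = Bt, scale = params$total_contacts / T_unit, cal_bin = cal_bin)
}

# Assemble expected pixel intensities (lambda) for selected bins.
# Returns data.table(bin1, bin2, lambda) over all pixel pairs among `sel`
# (upper triangle).  `struct` is the combined structural table, `ncomp` a
# list of per-component copy-count vectors with weights.
lambda_pixels <- function(bins, sel, struct, ncomp, Bt, scale, cis_scale) {
  b <- bins[gbin %in% sel]
  chroms <- unique(b$chrom)
  widths_all <- bins[, end - start]
  out <- vector("list", 0L)
  for (ia in seq_along(chroms)) for (ib in ia:length(chroms)) {
    ga <- b[chrom == chroms[ia], gbin]; gb <- b[chrom == chroms[ib], gbin]
    if (ia == ib) {
      n <- length(ga)
      i <- rep.int(seq_len(n), rev(seq_len(n)))
      j <- sequence(rev(seq_len(n))) + i - 1L
      g1 <- ga[i]; g2 <- ga[j]
    } else {
      g1 <- rep(ga, times = length(gb))
      g2 <- rep(gb, each = length(ga))
    }
    area <- widths_all[g1] * widths_all[g2]
    diag <- g1 == g2
    area[diag] <- widths_all[g1[diag]]^2 / 2
    combos <- numeric(length(g1))
    for (cm in ncomp) {
      n1 <- cm$n[g1]; n2 <- cm$n[g2]
      cb <- n1 * n2
      cb[diag] <- (cm$n[g1[diag]] * (cm$n[g1[diag]] - 1)) / 2
      combos <- combos + cm$u * cb
    }
    dt <- data.table(bin1 = pmin(g1, g2), bin2 = pmax(g1, g2),
                     lambda = Bt * area * combos)
    if (nrow(struct))
      dt[struct, on = .(bin1 = gi, bin2 = gj),
         lambda := lambda + cis_scale * i.S - Bt * i.CO]
    dt[, lambda := pmax(lambda, 0) * scale]
    out[[length(out) + 1L]] <- dt
  }
  rbindlist(out)
}

build_struct <- function(karyotype, params, bins, sel = NULL) {
  comps <- mixture_components(karyotype, params)
  nb <- nrow(bins)
  struct <- list(); ncomp <- list(); off <- 0L
  for (cm in comps) {
    cop <- component_copies(cm$kar, bins, dcid_offset = off)
    off <- off + max(1L, cop[, uniqueN(dcid)])
    ncomp[[length(ncomp) + 1L]] <- list(u = cm$u, n = copy_counts(cop, nb))
    if (!is.null(sel)) cop <- cop[gbin %in% sel]
    struct[[length(struct) + 1L]] <- structural_pixels(cop, params, u = cm$u)
  }
  struct <- rbindlist(struct)
  if (nrow(struct)) struct <- struct[, .(S = sum(S), CO = sum(CO)), by = .(gi, gj)]
  setkey(struct, gi, gj)
  list(struct = struct, ncomp = ncomp)
}

#' Expected contact intensity between bins
#'
#' Evaluates the generative model's expected pixel count for bin pairs,
#' without sampling.  Symmetric in (i, j).
#'
#' @param karyotype a `derivative_karyotype`.
#' @param params a `simulation_params`.
#' @param bins a `bin_table` for the karyotype's genome.
#' @param bin_i,bin_j global bin indices (vectors, recycled).
#' @param calibration optional result of [calibrate_simulation()] (computed
#'   on the fly if missing).
#' @return numeric vector of expected counts.
#' @export
expected_contact <- function(karyotype, params, bins, bin_i, bin_j,
                             calibration = NULL) {
  stopifnot(inherits(bins, "bin_table"))
  nb <- nrow(bins$bins)
  if (any(c(bin_i, bin_j) < 1L) || any(c(bin_i, bin_j) > nb))
    stop("bin index outside the bin table")
  if (is.null(calibration)) calibration <- calibrate_simulation(karyotype, params)
  k <- max(length(bin_i), length(bin_j))
  bin_i <- rep_len(bin_i, k); bin_j <- rep_len(bin_j, k)
  sel <- unique(c(bin_i, bin_j))
  bs <- build_struct(karyotype, params, bins$bins, sel = sel)
  lp <- lambda_pixels(bins$bins, sel, bs$struct, bs$ncomp,
                      calibration$Bt, calibration$scale, params$cis_scale)
  q <- data.table(bin1 = pmin(bin_i, bin_j), bin2 = pmax(bin_i, bin_j))
  lp[q, on = .(bin1, bin2), lambda]
}

#' Simulate a sparse Hi-C contact matrix
#'
#' Draws independent Poisson pixel counts from the expected intensities of
#' the generative model (see [simulation_params()]), genome-wide or
#' restricted to regions.  Deterministic given `seed`.
#'
#' @param karyotype a `derivative_karyotype`.
#' @param params a `simulation_params`.
#' @param bin_size bin size in bp.
#' @param regions optional data.table/data.frame (`chrom`, `start`, `end`):
#'   only pixels with both ends in a region are simulated (the bin table
#'   still covers the whole genome).
#' @param calibration optional precomputed [calibrate_simulation()] result.
#' @param seed RNG seed (default `params$seed`).
#' @return a `contact_matrix`.
#' @export
simulate_map <- function(karyotype, params, bin_size,
                         regions = NULL, calibration = NULL,
                         seed = params$seed) {
  genome <- karyotype$genome
  bt <- bin_table(genome, bin_size)
  bins <- bt$bins
  sel <- if (is.null(regions)) bins$gbin else {
    rg <- as.data.table(regions)
    mid <- bins[, (start + end) / 2]
    unique(unlist(lapply(seq_len(nrow(rg)), function(k)
      bins[chrom == rg$chrom[k] & mid >= rg$start[k] & mid < rg$end[k], gbin])))
  }
  if (!length(sel)) stop("regions select no bins")
  if (is.null(calibration)) calibration <- calibrate_simulation(karyotype, params)
  bs <- build_struct(karyotype, params, bins, sel = sel)
  lp <- lambda_pixels(bins, sel, bs$struct, bs$ncomp,
                      calibration$Bt, calibration$scale, params$cis_scale)
  withr::with_seed(seed, {
    lp[, count := rpois(.N, lambda)]
  })
  contact_matrix(bt, lp[count > 0, .(bin1, bin2, count)])
}

#' On-demand fine-resolution simulator
#'
#' Returns a fetch function `f(chromA, startA, endA, chromB, startB, endB)`
#' producing a `contact_matrix` at `refine_bin` restricted to the union of
#' the two regions.  Each region draws fresh Poisson noise from the same
#' calibrated model (seeded deterministically from the region coordinates),
#' emulating multi-resolution access to a deep contact map without
#' materializing the genome at fine resolution.
#'
#' @param karyotype a `derivative_karyotype`.
#' @param params a `simulation_params`.
#' @param refine_bin fine bin size in bp (default 5 kb).
#' @return a function; see Details.
#' @export
hic_fetcher <- function(karyotype, params, refine_bin = 5e3) {
  calibration <- calibrate_simulation(karyotype, params)
  force(karyotype); force(params)
  function(chromA, startA, endA, chromB, startB, endB) {
    rg <- data.table(chrom = c(chromA, chromB),
                     start = c(startA, startB), end = c(endA, endB))
    h <- sum(c(startA, endA, startB, endB) / refine_bin) +
      sum(utf8ToInt(paste0(chromA, chromB)))
    seed <- (params$seed + as.integer(h %% 1e6) * 1009L) %% .Machine$integer.max
    simulate_map(karyotype, params, refine_bin, regions = rg,
                 calibration = calibration, seed = as.integer(seed))
  }
}
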