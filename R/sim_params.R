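#' Simulation parameters for synthetic Hi-C maps
#'
#' The generative model is a continuous contact-density model evaluated at
#' bin midpoints.  Within each cell-population component (see
#' `het_mixture_weight`), two loci that are co-resident on one derivative
#' chromosome at derivative-coordinate separation `s` contact at density
#'
#'   `B * (s + s0)^(-alpha) * (1 + delta * e_i * e_j) * (1 + tau)^k`
#'
#' per bp^2, where `e` is the compartment sign track, `k` the number of
#' planted domains containing both loci, and `B = cis_scale`.  Copy pairs
#' never co-resident (different derivative chromosomes, including
#' homologues) contact at the flat background `B_t = trans_background`.
#' Expected pixel counts are the density times the bin areas, scaled so the
#' genome-wide total is `total_contacts`, and counts are independent Poisson
#' draws.
#'
#' Heterozygosity is modeled as a two-population cell mixture: a fraction
#' `w = het_mixture_weight` of cells carries the edited (derivative) diploid
#' karyotype, the remaining `1 - w` the unedited one, so residual wild-type
#' signal survives every rearrangement.  An edit placed on one haplotype of
#' the derivative karyotype is therefore heterozygous even at `w = 1`.
#'
#' @param decay_exponent alpha, power-law exponent of cis distance decay
#'   (dimensionless, default 1).
#' @param decay_offset s0 in bp (default 10 kb), regularizes the decay at
#'   zero separation (sub-fragment scale).
#' @param cis_scale B, relative cis contact density (default 1; absolute
#'   scale is set by `total_contacts`).
#' @param trans_background B_t, flat background density.  The default
#'   `"auto"` calibrates B_t so that the unedited genome has an expected
#'   genome-wide cis/trans contact ratio of `cis_trans_target`.
#' @param cis_trans_target expected cis/trans ratio used by the `"auto"`
#'   background (default 1.9, the center of the 1.6-2.3 band typical of
#'   low-noise chicken Hi-C libraries).
#' @param compartment_strength delta in `[0, 1)` (default 0.3).
#' @param compartment_block bp length of the alternating A/B blocks used
#'   when no explicit track is given (default 500 kb, i.e. ten 50 kb bins).
#' @param compartment_track optional data.table (`chrom`, `start`, `end`,
#'   `e`) with a signed compartment signal; overrides the alternating track.
#' @param tad_boost tau >= 0 (default 0): within-domain contact boost for
#'   the planted domains in `tads`.
#' @param tads optional data.table (`chrom`, `start`, `end`) of planted
#'   domains; may be nested (hierarchical boost).
#' @param het_mixture_weight w in `[0, 1]`: fraction of cells carrying the
#'   derivative karyotype (default 0.5).
#' @param total_contacts target genome-wide contact sum (default 3e8,
#'   a combined-replicate avian Hi-C library).
#' @param seed RNG seed for [simulate_map()].
#' @return a `simulation_params` object.
#' @export
simulation_params <- function(decay_exponent = 1,
                              decay_offset = 1e4,
                              cis_scale = 1,
                              trans_background = "auto",
                              cis_trans_target = 1.9,
                              compartment_strength = 0.3,
                              compartment_block = 5e5,
                              compartment_track = NULL,
                              tad_boost = 0,
                              tads = NULL,
                              het_mixture_weight = 0.5,
                              total_contacts = 3e8,
                              seed = 1L) {
  stopifnot(decay_exponent > 0, decay_offset > 0, cis_scale > 0,
            compartment_strength >= 0, compartment_strength < 1,
            tad_boost >= 0,
            het_mixture_weight >= 0, het_mixture_weight <= 1,
            total_contacts > 0)
  if (!identical(trans_background, "auto"))
    stopifnot(is.numeric(trans_background), trans_background >= 0)
  if (!is.null(tads)) tads <- as.data.table(tads)
  if (!is.null(compartment_track)) compartment_track <- as.data.table(compartment_track)
  structure(list(decay_exponent = decay_exponent, decay_offset = decay_offset,
                 cis_scale = cis_scale, trans_background = trans_background,
                 cis_trans_target = cis_trans_target,
                 compartment_strength = compartment_strength,
                 compartment_block = compartment_block,
                 compartment_track = compartment_track,
                 tad_boost = tad_boost, tads = tads,
                 het_mixture_weight = het_mixture_weight,
                 total_contacts = total_contacts, seed = as.integer(seed)),
            class = "simulation_params")
}

# compartment sign at reference positions (vectorized)
comp_signal <- function(params, chrom, pos) {
  if (!is.null(params$compartment_track)) {
    tr <- params$compartment_track
    q <- data.table(chrom = chrom, pos = pos, idx = seq_along(pos))
    hit <- tr[q, on = .(chrom, start <= pos, end > pos), .(idx = i.idx, e = x.e)]
    e <- rep(0, length(pos))
    e[hit$idx] <- hit$e
    e
  } else {
    ifelse(floor(pos / params$compartment_block) %% 2 == 0, 1, -1)
  }
}
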