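test_that("identity maps yield no trans-SV calls (false-positive control)", {
  fp <- fx_fp_counts()
  expect_gte(mean(fp == 0L), 0.95)
})

test_that("a planted translocation produces one well-placed block", {
  fx <- fx_t12()
  expect_equal(nrow(fx$blocks), 1L)
  bl <- fx$blocks
  # donor-axis interval overlaps the planted segment generously
  inter <- max(0, min(bl$endA, 194260000) - max(bl$startA, 180580000))
  expect_gt(inter / (194260000 - 180580000), 0.3)
  expect_gte(bl$mean_z, detection_params()$enrichment_z_min)

  # axis order only mirrors the block
  sw <- trans_enrichment(fx$map, "chr2", "chr1", detection_params())
  expect_equal(sw[, .(startA, endA, startB, endB)],
               bl[, .(startA = startB, endA = endB, startB = startA, endB = endA)])

  # raising the z threshold never increases the number of blocks
  n_lo <- nrow(trans_enrichment(fx$map, "chr1", "chr2",
                                detection_params(enrichment_z_min = 4)))
  n_hi <- nrow(trans_enrichment(fx$map, "chr1", "chr2",
                                detection_params(enrichment_z_min = 50)))
  expect_lte(n_hi, n_lo)
})

test_that("gradient localization recovers the planted junction to one fine bin", {
  fx <- fx_t12()
  cl <- fx$call
  bp1 <- cl[, ifelse(chrom_donor == "chr1", bp_donor, insertion_bp)]
  bp2 <- cl[, ifelse(chrom_donor == "chr2", bp_donor, insertion_bp)]
  expect_lte(abs(bp1 - 180580000), 5e3)
  expect_lte(abs(bp2 - 149470000), 5e3)
  expect_equal(cl$uncertainty_bp, 5e3)
  expect_false(cl$low_confidence)
})

test_that("breakpoints are recovered within one bin in >= 90% of seeded runs", {
  fx <- fx_bp_recovery()
  calls <- fx$calls
  expect_gte(nrow(calls), 9L)
  # an interior insertion has two genuine junctions (segment start and
  # end); either donor coordinate is a correct localization
  bpB <- calls[, ifelse(chrom_donor == "chrB", bp_donor, insertion_bp)]
  bpA <- calls[, ifelse(chrom_donor == "chrA", bp_donor, insertion_bp)]
  hit <- pmin(abs(bpB - 2e6), abs(bpB - 6e6)) <= 25e3 & abs(bpA - 15e6) <= 25e3
  expect_gte(mean(hit), 0.9)
  # the fusion-adjacent depth precondition of this property actually holds
  p <- simulation_params(seed = 201, total_contacts = 2e8,
                         het_mixture_weight = 1)
  bt <- bin_table(fx$genome, 25e3)
  iA <- bt$bins[chrom == "chrA" & start == 15e6 - 25e3, gbin]
  iB <- bt$bins[chrom == "chrB" & start == 2e6, gbin]
  expect_gte(expected_contact(fx$kar, p, bt, iA, iB), 20)
})

test_that("flipping the planted orientation flips the call, not the segment", {
  g <- two_chrom_genome()
  mk <- function(ori) {
    kar <- apply_edits(g, list(
      karyotype_edit("translocation", "chrB", 2e6, 6e6, orientation = ori,
                     acceptor_chrom = "chrA", insertion = 15e6,
                     haplotype = 1L)))
    p <- simulation_params(seed = 77, total_contacts = 2e8,
                           het_mixture_weight = 1, trans_background = 1e-8)
    m <- simulate_map(kar, p, 250e3)
    f <- hic_fetcher(kar, p, refine_bin = 25e3)
    dp <- detection_params(refine_bin = 25e3)
    bl <- trans_enrichment(m, "chrA", "chrB", dp)
    localize_breakpoint(bl[1], m, dp, refine = f)
  }
  plus <- mk("+"); minus <- mk("-")
  expect_equal(plus$chrom_donor, "chrB")
  expect_equal(minus$chrom_donor, "chrB")
  expect_equal(plus$orientation, "+")
  expect_equal(minus$orientation, "-")
  expect_equal(plus$seg_start, minus$seg_start, tolerance = 0.1)
  expect_equal(plus$seg_end, minus$seg_end, tolerance = 0.1)
  # either genuine junction end is acceptable; it stays on the segment edge
  expect_lte(min(abs(plus$bp_donor - c(2e6, 6e6))), 25e3)
  expect_lte(min(abs(minus$bp_donor - c(2e6, 6e6))), 25e3)
})

test_that("classification separates duplication, balanced and fusion geometry", {
  g <- two_chrom_genome()
  p <- simulation_params(seed = 88, total_contacts = 1e8,
                         het_mixture_weight = 1)
  dp <- detection_params()

  # translocated duplication: donor coverage rises to ~3 copies
  kd <- apply_edits(g, list(
    karyotype_edit("translocation", "chrA", 25e6, 30e6,
                   acceptor_chrom = "chrB", insertion = "ter:q",
                   mode = "duplicated")))
  md <- simulate_map(kd, p, 250e3)
  cd <- detect_translocations(md, dp, coverage = coverage_track(md), genome = g)
  expect_equal(nrow(cd), 1L)
  expect_equal(cd$classification, "translocated_duplication")

  # balanced reciprocal exchange: two complementary blocks, both balanced
  # (low explicit background: the auto background of a 50 Mb two-chromosome
  # toy genome is as high as mid-range cis decay and would blur the
  # quadrant geometry)
  kb <- apply_edits(g, list(
    karyotype_edit("translocation", "chrA", 20e6, 30e6,
                   acceptor_chrom = "chrB", insertion = 8e6,
                   balanced = TRUE)))
  pb <- simulation_params(seed = 88, total_contacts = 1e8,
                          het_mixture_weight = 1, trans_background = 1e-8)
  mb <- simulate_map(kb, pb, 250e3)
  cb <- detect_translocations(mb, dp, coverage = coverage_track(mb), genome = g)
  expect_equal(nrow(cb), 2L)
  expect_true(all(cb$classification == "balanced"))

  # whole-microchromosome terminal fusion, on the multi-chromosome toy
  # genome so the trans background comes from unrearranged pairs
  gt <- toy_chicken_genome()
  kf <- apply_edits(gt, list(
    karyotype_edit("translocation", "chr7", 0, 10e6,
                   acceptor_chrom = "chr1", insertion = "ter:q")))
  pf <- simulation_params(seed = 89, het_mixture_weight = 1)
  mf <- simulate_map(kf, pf, 250e3)
  cf <- detect_translocations(mf, dp, genome = gt)
  expect_equal(nrow(cf), 1L)
  expect_equal(cf$kind, "terminal_fusion")
  expect_equal(cf$chrom_donor, "chr7")
})

test_that("a reference map vetoes shared blocks", {
  fx <- fx_t12()
  calls <- detect_translocations(fx$map, detection_params(),
                                 reference = fx$map, genome = fx$genome)
  expect_equal(nrow(calls), 0L)
})

test_that("no call's block violates the minimum-segment filter", {
  hd3 <- fx_hd3_run()
  ok <- hd3$calls[, pmax(endA - startA, endB - startB) >=
                    detection_params()$min_segment_bp]
  expect_true(all(ok))
})
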