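test_that("genome construction validates its input", {
  g <- toy_chicken_genome()
  expect_s3_class(g, "genome_model")
  expect_equal(nrow(g$chromosomes), 17L)
  expect_equal(sum(g$chromosomes$chrom_class == "macro"), 5L)
  expect_equal(sum(g$chromosomes$chrom_class == "micro"), 10L)
  # assembly-magnitude sizes are accepted as-is
  gg <- make_genome(data.frame(name = c("chr1", "chr2"),
                               length = c(196202544, 149560735)))
  expect_equal(chrom_length(gg, "chr2"), 149560735)
  expect_error(make_genome(data.frame(name = "chr1", length = 0)), "positive")
  expect_error(make_genome(data.frame(name = c("a", "a"), length = c(1e6, 2e6))),
               "duplicate")
  expect_error(make_genome(data.frame(name = "a", length = 1e6,
                                      centromere = 2e6)), "centromere")
})

test_that("chrom.sizes round-trips", {
  g <- toy_chicken_genome()
  path <- tempfile(fileext = ".chrom.sizes")
  write_chrom_sizes(g, path)
  g2 <- read_chrom_sizes(path)
  expect_equal(g2$chromosomes$name, g$chromosomes$name)
  expect_equal(g2$chromosomes$length, g$chromosomes$length)
})

test_that("edits rearrange haplotypes and the copy-number track follows", {
  g <- two_chrom_genome()
  # unbalanced moved translocation: copy number unchanged (segment moved,
  # not lost), acceptor haplotype gains a segment
  kar <- apply_edits(g, list(
    karyotype_edit("translocation", "chrB", 2e6, 6e6,
                   acceptor_chrom = "chrA", insertion = 15e6)))
  seg <- karyotype_segments(kar)
  expect_equal(nrow(seg[hap == 1 & dchrom == "chrA.1"]), 3L)
  cn <- copy_number_track(kar, 1e6)
  expect_true(all(cn$copy == 2L))

  # deletion on one haplotype drops copy number 2 -> 1
  kd <- apply_edits(g, list(karyotype_edit("deletion", "chrA", 10e6, 13e6)))
  cnd <- copy_number_track(kd, 1e6)
  expect_equal(cnd[chrom == "chrA" & start >= 10e6 & end <= 13e6, unique(copy)], 1L)
  expect_equal(cnd[chrom == "chrB", unique(copy)], 2L)

  # translocated duplication keeps the donor and adds a third copy
  kdup <- apply_edits(g, list(
    karyotype_edit("translocation", "chrA", 25e6, 30e6,
                   acceptor_chrom = "chrB", insertion = "ter:q",
                   mode = "duplicated")))
  cnu <- copy_number_track(kdup, 1e6)
  expect_equal(cnu[chrom == "chrA" & start >= 25e6, unique(copy)], 3L)

  # whole-chromosome gain
  kg <- apply_edits(g, list(karyotype_edit("whole_chrom_gain", "chrB")))
  cng <- copy_number_track(kg, 1e6)
  expect_equal(cng[chrom == "chrB", unique(copy)], 3L)
  expect_equal(chromosome_count(kg), 5L)

  # conflicting edits on the same interval are rejected with the edit named
  expect_error(apply_edits(g, list(
    karyotype_edit("translocation", "chrB", 2e6, 6e6,
                   acceptor_chrom = "chrA", insertion = 15e6),
    karyotype_edit("translocation", "chrB", 3e6, 8e6,
                   acceptor_chrom = "chrA", insertion = 20e6))),
    "chrB:3000000-8000000")
})

test_that("an inversion applied twice restores the identity karyotype", {
  g <- two_chrom_genome()
  kar <- apply_edits(g, list(
    karyotype_edit("inversion", "chrA", 15e6, 20e6, haplotype = 1L),
    karyotype_edit("inversion", "chrA", 15e6, 20e6, haplotype = 1L)))
  expect_equal(karyotype_segments(kar), karyotype_segments(identity_karyotype(g)))
  # copy-number track integrates to total haplotype length
  cn <- copy_number_track(kar, 1e6)
  expect_equal(cn[, sum(copy * (end - start))],
               2 * sum(g$chromosomes$length))
})

test_that("expected_contact matches the stated model", {
  g <- two_chrom_genome()
  kar <- identity_karyotype(g)
  p <- simulation_params(seed = 1, compartment_strength = 0.3)
  bt <- bin_table(g, 1e6)
  cal <- calibrate_simulation(kar, p)
  # adjacent cis pixel: power law times compartment factor, both copies
  lam1 <- expected_contact(kar, p, bt, 5L, 6L, cal)
  mid <- bt$bins[gbin %in% 5:6, (start + end) / 2]
  e <- comp_signal(p, c("chrA", "chrA"), mid)
  area <- 1e12
  # two co-resident copy pairs (power law) + two cross-homologue pairs
  # (flat background)
  manual <- cal$scale * area *
    (2 * (diff(mid) + p$decay_offset)^(-1) * (1 + 0.3 * e[1] * e[2]) +
       2 * cal$Bt)
  expect_equal(lam1, manual, tolerance = 1e-10)
  # unedited trans pixel: flat background over the four copy pairs
  gB <- bt$bins[chrom == "chrB", gbin[1]]
  lam_t <- expected_contact(kar, p, bt, 5L, gB, cal)
  expect_equal(lam_t, cal$scale * cal$Bt * 4 * area, tolerance = 1e-10)
  # symmetry
  expect_equal(expected_contact(kar, p, bt, gB, 5L, cal), lam_t)
})

test_that("fused chromosome ends contact like cis neighbours and decay monotonically", {
  g <- two_chrom_genome()
  kar <- apply_edits(g, list(
    karyotype_edit("translocation", "chrB", 0, 20e6,
                   acceptor_chrom = "chrA", insertion = "ter:q")))
  # background switched off to isolate the structural term
  p <- simulation_params(seed = 1, het_mixture_weight = 1,
                         compartment_strength = 0, trans_background = 0)
  bt <- bin_table(g, 1e6)
  cal <- calibrate_simulation(kar, p)
  lastA <- max(bt$bins[chrom == "chrA", gbin])
  firstB <- min(bt$bins[chrom == "chrB", gbin])
  # trans pixel adjacent to the fusion equals the cis value at 1-bin
  # separation (single co-resident copy each side)
  fus <- expected_contact(kar, p, bt, lastA, firstB, cal)
  cis1 <- expected_contact(kar, p, bt, lastA - 2L, lastA - 1L, cal) / 2
  expect_equal(fus, cis1, tolerance = 1e-10)
  # monotone decay away from the fusion point on the chrB side
  lams <- expected_contact(kar, p, bt, lastA, firstB + 0:9, cal)
  expect_true(all(diff(lams) < 0))
})

test_that("simulation is seed-deterministic and depth-calibrated", {
  fx <- fx_toy_identity()
  m1 <- fx$map
  m2 <- simulate_map(fx$kar, fx$params, 250e3)
  expect_equal(m1$pixels, m2$pixels)
  m3 <- simulate_map(fx$kar, fx$params, 250e3, seed = 999)
  expect_false(isTRUE(all.equal(m1$pixels, m3$pixels)))
  expect_equal(sum(m1$pixels$count), fx$params$total_contacts, tolerance = 0.02)
})

test_that("flat simulation has uniform coverage (law of large numbers)", {
  g <- two_chrom_genome()
  kar <- identity_karyotype(g)
  p <- simulation_params(seed = 3, compartment_strength = 0, tad_boost = 0,
                         total_contacts = 5e7)
  m <- simulate_map(kar, p, 500e3)
  cov <- coverage_track(m, normalize = FALSE)
  # drop edge bins (shorter bins and one-sided decay)
  inner <- cov[, .SD[3:(.N - 2)], by = chrom]
  cv <- inner[, stats::sd(value) / mean(value), by = chrom]$V1
  expect_true(all(cv < 0.1))
})
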