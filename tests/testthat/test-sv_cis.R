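# reference and rearranged maps for cis-SV detection at 100 kb
fx_cis_maps <- function() fixture("cis_maps", {
  g <- two_chrom_genome()
  idk <- identity_karyotype(g)
  p <- simulation_params(seed = 71, total_contacts = 4e7,
                         het_mixture_weight = 1)
  ref <- simulate_map(idk, p, 100e3, seed = 999)
  list(genome = g, idk = idk, params = p, ref = ref)
})

test_that("coverage segmentation recovers planted deletions and amplifications", {
  fx <- fx_cis_maps()
  g <- fx$genome; p <- fx$params
  rcov <- coverage_track(fx$ref, genome = g)

  # heterozygous deletion carried by all cells: log2 ratio ~ -1
  kd <- apply_edits(g, list(karyotype_edit("deletion", "chrA", 10e6, 13e6)))
  md <- simulate_map(kd, p, 100e3)
  cnv <- cnv_segments(coverage_track(md, genome = g), rcov)
  expect_equal(nrow(cnv), 1L)
  expect_equal(cnv$state, "deletion_het")
  expect_lte(abs(cnv$start - 10e6), 100e3)  # start within one bin
  expect_lte(abs(cnv$end - 13e6), 100e3)
  expect_equal(cnv$log2_ratio, -1, tolerance = 0.15)

  # ~1 Mb terminal amplification with 4 extra copies: log2((2+4)/2) ~ 1.58
  ka <- apply_edits(g, list(karyotype_edit("duplication", "chrB", 19e6, 20e6,
                                           copies = 4L)))
  ma <- simulate_map(ka, p, 100e3)
  cnva <- cnv_segments(coverage_track(ma, genome = g), rcov)
  cnva <- cnva[state == "amplification"]
  expect_equal(nrow(cnva), 1L)
  expect_equal(cnva$chrom, "chrB")
  expect_gte(cnva$start, 18.5e6)   # at the chromosome end
  expect_equal(cnva$end, 20e6)

  # flat coverage: no calls; scale invariance of the segmentation
  cov0 <- coverage_track(fx$ref, genome = g)
  expect_equal(nrow(cnv_segments(cov0, rcov)), 0L)
  cov_scaled <- copy(cov0)[, value := value * 17]
  expect_equal(cnv_segments(cov_scaled, rcov), cnv_segments(cov0, rcov))
})

test_that("segmentation matches the exhaustive change-point oracle on short tracks", {
  # oracle: best penalized fit with 0, 1 or 2 change-points by enumeration
  oracle <- function(y, pen, sigma2) {
    n <- length(y)
    rss <- function(seg) sum((seg - mean(seg))^2)
    best <- list(cost = rss(y), cps = integer())
    for (k1 in 1:(n - 1)) {
      c1 <- rss(y[1:k1]) + rss(y[(k1 + 1):n]) + pen * sigma2
      if (c1 < best$cost) best <- list(cost = c1, cps = k1)
      if (k1 < n - 1) for (k2 in (k1 + 1):(n - 1)) {
        c2 <- rss(y[1:k1]) + rss(y[(k1 + 1):k2]) + rss(y[(k2 + 1):n]) +
          2 * pen * sigma2
        if (c2 < best$cost) best <- list(cost = c2, cps = c(k1, k2))
      }
    }
    best$cps
  }
  withr::with_seed(72, {
    for (trial in 1:20) {
      n <- sample(12:30, 1)
      # segments of >= 3 bins: greedy binary splitting is not guaranteed
      # to isolate single-bin spikes, and planted CNVs span several bins
      repeat {
        cps_true <- sort(sample(3:(n - 3), 2))
        if (diff(cps_true) >= 3) break
      }
      mu <- c(0, sample(c(-2, 2, 3), 1), 0)
      y <- rep(mu, c(cps_true[1], diff(cps_true), n - cps_true[2])) +
        rnorm(n, sd = 0.1)
      sigma2 <- max(var(diff(y)) / 2, 1e-6)
      pen <- 2 * log(n)
      got <- karyohic:::binary_segment(y, sigma2, pen)
      expect_equal(got, oracle(y, pen, sigma2))
    }
  })
})

test_that("inversions are recovered with a reference map and scale with w", {
  fx <- fx_cis_maps()
  g <- fx$genome
  inv_ed <- list(karyotype_edit("inversion", "chrA", 15e6, 20e6, haplotype = 1L),
                 karyotype_edit("inversion", "chrA", 15e6, 20e6, haplotype = 2L))
  kar <- apply_edits(g, inv_ed)
  m1 <- simulate_map(kar, fx$params, 100e3)  # w irrelevant at hom+w=1
  iv <- detect_inversion(m1, fx$ref, "chrA")
  expect_equal(nrow(iv), 1L)
  # breakpoints within 2 coarse grid steps (5 bins each) of the planted ends
  expect_lte(abs(iv$start - 15e6), 2 * 5 * 100e3)
  expect_lte(abs(iv$end - 20e6), 2 * 5 * 100e3)

  # heterozygous mixture: detected with a smaller score (monotone in w)
  p5 <- simulation_params(seed = 71, total_contacts = 4e7,
                          het_mixture_weight = 0.5)
  m5 <- simulate_map(kar, p5, 100e3)
  iv5 <- detect_inversion(m5, fx$ref, "chrA")
  expect_equal(nrow(iv5), 1L)
  expect_lt(iv5$score, iv$score)

  # identity vs itself: nothing; reference is mandatory
  expect_equal(nrow(detect_inversion(fx$ref, fx$ref, "chrA")), 0L)
  expect_error(detect_inversion(m1, NULL, "chrA"), "reference")
})

test_that("cis deletions combine coverage loss with gap-bridging contacts", {
  fx <- fx_cis_maps()
  g <- fx$genome
  # homozygous 2 Mb (20-bin) deletion
  kh <- apply_edits(g, list(
    karyotype_edit("deletion", "chrB", 8e6, 10e6, haplotype = 1L),
    karyotype_edit("deletion", "chrB", 8e6, 10e6, haplotype = 2L)))
  mh <- simulate_map(kh, fx$params, 100e3)
  dh <- detect_cis_deletion(mh, fx$ref, "chrB")
  expect_equal(nrow(dh), 1L)
  expect_equal(dh$state, "deletion_hom")
  jac <- {
    inter <- min(dh$end, 10e6) - max(dh$start, 8e6)
    inter / (max(dh$end, 10e6) - min(dh$start, 8e6))
  }
  expect_gt(jac, 0.8)
  expect_gt(dh$bridge_score, 0)

  # heterozygous deletion: flagged het via the coverage ratio
  kt <- apply_edits(g, list(karyotype_edit("deletion", "chrB", 8e6, 10e6)))
  mt <- simulate_map(kt, fx$params, 100e3)
  dt_ <- detect_cis_deletion(mt, fx$ref, "chrB")
  expect_equal(dt_$state, "deletion_het")
  expect_equal(dt_$log2_ratio, -1, tolerance = 0.2)

  # no deletion: empty
  expect_equal(nrow(detect_cis_deletion(fx$ref, fx$ref, "chrB")), 0L)
})
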