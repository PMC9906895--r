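# exhaustive segmentation oracle: enumerate all 2^(n-1) boundary
# placements; blocks shorter than min_domain_bins or with q <= 0 count as
# gaps (contribution 0), matching the DP's objective
oracle_best_score <- function(M, gamma, params) {
  n <- nrow(M)
  q <- karyohic:::armatus_q(M, gamma, Lmax = n)
  best <- -Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    cuts <- which(bitwAnd(mask, 2^(0:(n - 2))) > 0)
    bounds <- c(0L, cuts, n)
    sc <- 0
    for (b in seq_len(length(bounds) - 1L)) {
      i <- bounds[b] + 1L; j <- bounds[b + 1L]
      len <- j - i + 1L
      qq <- q[i, len]
      if (len >= params$min_domain_bins && !is.na(qq) && qq > 0) sc <- sc + qq
    }
    best <- max(best, sc)
  }
  best
}

test_that("window quality matches direct evaluation on a toy matrix", {
  withr::with_seed(51, M <- matrix(rpois(36, 10), 6))
  M <- M + t(M)
  gamma <- 0.25
  for (i in 1:6) for (j in i:6) {
    s <- sum(M[i:j, i:j][upper.tri(M[i:j, i:j], diag = TRUE)])
    l <- j - i
    # mean over all windows of the same length
    sg <- vapply(seq_len(6 - l), function(a)
      sum(M[a:(a + l), a:(a + l)][upper.tri(matrix(0, l + 1, l + 1), diag = TRUE)]),
      0) / (l + 1)^gamma
    expect_equal(domain_quality(M, NULL, i, j, gamma),
                 s / (l + 1)^gamma - mean(sg), tolerance = 1e-10)
  }
  # constant matrix: every window scores ~0
  K <- matrix(3, 8, 8)
  expect_equal(max(abs(domain_quality(K, NULL, rep(1:4, 2), c(2:5, 4:7), 0.3))),
               0, tolerance = 1e-12)
})

test_that("the segmentation DP equals the exhaustive oracle (n <= 12)", {
  params <- domain_params(bin_size = 50e3)
  withr::with_seed(52, {
    for (trial in 1:200) {
      n <- sample(6:12, 1)
      M <- matrix(rpois(n * n, sample(c(3, 10, 30), 1)), n)
      M <- M + t(M)
      gamma <- sample(c(0.2, 0.25, 0.3, 0.5), 1)
      ds <- armatus_segment(M, NULL, gamma, params)
      expect_equal(attr(ds, "opt_score"), oracle_best_score(M, gamma, params),
                   tolerance = 1e-9)
      # domains never overlap within one segmentation
      if (nrow(ds) > 1L)
        expect_true(all(ds$start_bin[-1] > ds$end_bin[-nrow(ds)]))
    }
  })
})

test_that("clean block-diagonal structure is segmented exactly", {
  n <- 20
  M <- matrix(1, n, n)
  M[3:7, 3:7] <- 30
  M[10:14, 10:14] <- 30
  ds <- armatus_segment(M, NULL, 0.25, domain_params())
  expect_true(nrow(ds) >= 2L)
  expect_true(any(ds$start_bin == 3 & ds$end_bin == 7))
  expect_true(any(ds$start_bin == 10 & ds$end_bin == 14))
  # uniform matrix: no positive-quality window
  expect_equal(nrow(armatus_segment(matrix(5, 15, 15), NULL, 0.25)), 0L)
})

test_that("consensus over the gamma grid keeps both hierarchy scales", {
  fx <- fx_tad_maps()
  params <- domain_params()
  cons <- consensus_domains(fx$m1, "chrB", params)
  # single-gamma grid equals the plain segmentation
  one <- consensus_domains(fx$m1, "chrB", domain_params(gamma_grid = 0.25))
  seg <- armatus_segment(fx$m1, "chrB", 0.25, params)
  expect_equal(one[, .(chrom, start_bin, end_bin)],
               seg[, .(chrom, start_bin, end_bin)])
  # gamma order is irrelevant
  rev_grid <- consensus_domains(fx$m1, "chrB",
                                domain_params(gamma_grid = c(0.3, 0.2, 0.25)))
  expect_equal(cons[, .(start_bin, end_bin)],
               consensus_domains(fx$m1, "chrB",
                                 domain_params(gamma_grid = c(0.2, 0.25, 0.3))
                                 )[, .(start_bin, end_bin)])
  expect_equal(cons[, .(start_bin, end_bin)], rev_grid[, .(start_bin, end_bin)])
  # planted boundaries (parent edges at bins 21/81, children at 25/45 and
  # 53/73, standalone domain at 101/131) appear among the consensus
  # boundaries within 2 bins
  bnd <- karyohic:::domain_boundaries(cons)
  planted <- c(21, 25, 45, 53, 73, 81, 101, 131)
  expect_true(all(vapply(planted, function(b) any(abs(bnd - b) <= 2), TRUE)))
  # hierarchy retained: a coarse-gamma domain (child scale, >= 15 bins)
  # contains at least two finer domains from a larger gamma
  coarse <- cons[end_bin - start_bin >= 15]
  expect_true(nrow(coarse) >= 1L)
  fine <- cons[end_bin - start_bin < 15]
  nested <- vapply(seq_len(nrow(coarse)), function(k)
    sum(fine$start_bin >= coarse$start_bin[k] &
        fine$end_bin <= coarse$end_bin[k]), 0L)
  expect_true(any(nested >= 2L))
})

test_that("boundary overlap follows its definition and tolerances", {
  mk <- function(s, e) {
    d <- data.table(chrom = "c", start_bin = s, end_bin = e,
                    gamma = 0.25, q = 1)
    setattr(d, "n_bins", 100L); setattr(d, "bin_size", 50e3)
    setattr(d, "class", c("domain_set", class(d)))
    d
  }
  d1 <- mk(c(10L, 30L), c(20L, 40L))
  expect_equal(boundary_overlap(d1, d1), 1.0)
  d2 <- mk(c(11L, 31L), c(21L, 41L))   # all boundaries offset by one bin
  expect_equal(boundary_overlap(d1, d2, tol_bins = 1), 1.0)
  expect_equal(boundary_overlap(d1, d2, tol_bins = 0), 0.0)
  # monotone in tolerance
  d3 <- mk(c(13L, 33L), c(23L, 43L))
  ov <- vapply(0:4, function(t) boundary_overlap(d1, d3, t), 0)
  expect_true(all(diff(ov) >= 0))
  expect_error(boundary_overlap(mk(integer(), integer()), d1), "no domains")
})

test_that("independent replicates of the same planted domains agree", {
  fx <- fx_tad_maps()
  params <- domain_params()
  d1 <- armatus_segment(fx$m1, "chrB", 0.2, params)
  d2 <- armatus_segment(fx$m2, "chrB", 0.2, params)
  expect_gt(boundary_overlap(d1, d2, tol_bins = 1), 0.8)
  expect_lt(variation_of_information(d1, d2),
            variation_of_information(d1, mk_empty <- {
              e <- d1[0]; setattr(e, "n_bins", attr(d1, "n_bins")); e
            }))
})

test_that("variation of information is a partition metric", {
  mk <- function(s, e, n = 4L) {
    d <- data.table(chrom = "c", start_bin = s, end_bin = e,
                    gamma = 0.25, q = 1)
    setattr(d, "n_bins", n); setattr(d, "class", c("domain_set", class(d)))
    d
  }
  a <- mk(c(1L, 3L), c(2L, 4L))
  b <- mk(1L, 4L)
  expect_equal(variation_of_information(a, a), 0)
  # {1,2}{3,4} vs {1,2,3,4}: VI = 1 bit (closed form: H splits by half)
  expect_equal(variation_of_information(a, b), 1.0)
  expect_equal(variation_of_information(a, b), variation_of_information(b, a))
  # zero iff equal: different partitions have VI > 0
  cpart <- mk(c(1L, 2L), c(1L, 4L))
  expect_gt(variation_of_information(a, cpart), 0)
})
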