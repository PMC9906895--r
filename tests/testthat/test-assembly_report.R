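mk_call <- function(donor, ds, de, ori, acc, ins, score = 10,
                    kind = "translocation") {
  data.table(kind = kind, chrom_donor = donor, bp_donor = ds,
             seg_start = ds, seg_end = de, orientation = ori,
             chrom_acceptor = acc,
             insertion_bp = if (is.character(ins)) NA_real_ else ins,
             insertion = as.character(ins), classification = "unbalanced",
             score = score, uncertainty_bp = 5e3, low_confidence = FALSE,
             startA = ds, endA = de, startB = 0, endB = 1,
             chromA = donor, chromB = acc)
}

test_that("the breakpoint graph cuts chromosomes and wires adjacencies", {
  g <- two_chrom_genome()
  calls <- mk_call("chrB", 2e6, 6e6, "+", "chrA", 15e6)
  bg <- build_breakpoint_graph(calls, g)
  # one t(A;B): both chromosomes cut -> 2 + 3 segments, one novel edge
  expect_equal(nrow(bg$nodes), 5L)
  expect_equal(nrow(bg$edges), 1L)
  expect_false(any(bg$edges$conflict))

  # empty call set: only reference segments, no edges
  bg0 <- build_breakpoint_graph(localize_skeleton(), g)
  expect_equal(nrow(bg0$nodes), 2L)
  expect_equal(nrow(bg0$edges), 0L)

  # contradictory evidence for one adjacency: both kept, flagged
  calls2 <- rbind(mk_call("chrB", 2e6, 6e6, "+", "chrA", 15e6),
                  mk_call("chrB", 2e6, 6e6, "-", "chrA", 15e6, score = 4))
  bg2 <- build_breakpoint_graph(calls2, g)
  expect_true(any(bg2$edges$conflict))
  expect_equal(nrow(bg2$edges), 2L)
})

test_that("derivative reconstruction follows evidence paths and ranks them", {
  g3 <- make_genome(data.table(name = c("c1", "c2", "c3"),
                               length = c(30e6, 20e6, 10e6)))
  # chain: c2 head joins c1 at 25 Mb; c3 head joins the far end of the
  # translocated c2 segment
  calls <- rbind(
    mk_call("c2", 0, 5e6, "+", "c1", 25e6, score = 12),
    mk_call("c3", 0, 4e6, "+", "c2", 5e6, score = 9))
  bg <- build_breakpoint_graph(calls, g3)
  der <- reconstruct_derivatives(bg)
  expect_gte(length(der), 1L)
  # the top-ranked reconstruction is the full 3-chromosome path
  chroms_in <- unique(der[[1]]$segments$chrom)
  expect_setequal(chroms_in, c("c1", "c2", "c3"))
  expect_equal(nrow(der[[1]]$segments), 3L)
  expect_equal(attr(der, "unresolvable"), 0L)

  # a single fusion of two whole chromosomes: one derivative, two segments
  gf <- two_chrom_genome()
  fus <- mk_call("chrB", 0, 20e6, "+", "chrA", "ter:q")
  derf <- reconstruct_derivatives(build_breakpoint_graph(fus, gf))
  expect_equal(length(derf), 1L)
  expect_equal(nrow(derf[[1]]$segments), 2L)

  # conflicting branch: at least two ranked alternatives share the donor
  confl <- rbind(mk_call("chrB", 0, 20e6, "+", "chrA", "ter:q", score = 10),
                 mk_call("chrB", 0, 20e6, "+", "chrA", 10e6, score = 6))
  derc <- reconstruct_derivatives(build_breakpoint_graph(confl, gf))
  expect_gte(length(derc), 2L)
  scores <- vapply(derc, `[[`, 0, "score")
  expect_true(all(diff(scores) <= 0))
})

test_that("chromosome-number estimation does the fusion arithmetic", {
  g <- toy_chicken_genome()   # 17 chromosomes, W haploid
  gd <- make_genome(copy(g$chromosomes)[, ploidy := 2L])  # fully diploid
  expect_equal(estimate_chromosome_count(list(), gd), 34L)
  expect_equal(estimate_chromosome_count(list(), g), 33L)

  # one unbalanced fusion of two whole chromosomes on one haplotype
  fus <- list(list(name = "der(chr6;chr7)",
                   segments = data.table(chrom = c("chr6", "chr7"),
                                         start = 0, end = c(12e6, 10e6),
                                         orientation = "+"),
                   score = 10))
  expect_equal(estimate_chromosome_count(fus, gd), 33L)

  # whole-chromosome gain visible in the copy-number track
  kg <- apply_edits(g, list(karyotype_edit("whole_chrom_gain", "chrW")))
  cn <- copy_number_track(kg, 1e6)
  expect_equal(estimate_chromosome_count(list(), g, copy_number = cn), 34L)
  expect_equal(chromosome_count(kg), 34L)
})

test_that("writers emit valid, round-trippable text outputs", {
  out <- tempfile("results")
  g <- two_chrom_genome()
  calls <- mk_call("chrB", 2e6, 6e6, "+", "chrA", 15e6)
  der <- list(list(name = "der(chrA;chrB)",
                   segments = data.table(chrom = c("chrA", "chrB"),
                                         start = c(0, 2e6), end = c(15e6, 6e6),
                                         orientation = c("+", "+")),
                   score = 10))
  files <- write_outputs(list(calls = calls, derivatives = der,
                              seed = 42, params = list(bin = 250e3)), out)
  expect_true(all(file.exists(files)))

  # BEDPE round trip preserves the calls
  pe <- fread(file.path(out, "translocations.bedpe"))
  expect_equal(pe$chrom1, calls$chrom_donor)
  expect_equal(pe$start1, calls$seg_start)
  expect_equal(pe$strand1, calls$orientation)

  # AGP: component coordinates tile the derivative without gaps
  agp <- read_agp(file.path(out, "derivatives.agp"))
  expect_equal(length(agp), 1L)
  expect_equal(agp[[1]]$segments[, sum(end - start)],
               der[[1]]$segments[, sum(end - start)])
  expect_equal(agp[[1]]$segments[, .(chrom, start, end)],
               der[[1]]$segments[, .(chrom, start, end)])

  # manifest is valid JSON carrying the seed
  man <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(man$seed, 42L)

  # empty results still produce valid headered files
  out2 <- tempfile("empty")
  files2 <- write_outputs(list(), out2)
  expect_true(all(file.exists(files2)))
  expect_equal(nrow(fread(file.path(out2, "translocations.bedpe"))), 0L)
})
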