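library(data.table)

# fixtures shared across test files (test_dir runs everything in one
# session, so heavy simulations are built once)
.fx <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

# two-chromosome toy genome for per-chromosome analyses
two_chrom_genome <- function()
  make_genome(data.table(name = c("chrA", "chrB"), length = c(30e6, 20e6)))

# identity simulation of the toy chicken genome at scan resolution
fx_toy_identity <- function() fixture("toy_identity", {
  g <- toy_chicken_genome()
  kar <- identity_karyotype(g)
  p <- simulation_params(seed = 101)
  list(genome = g, kar = kar, params = p, map = simulate_map(kar, p, 250e3))
})

# false-positive control: 20 seeded identity runs through the trans-SV
# detector with default thresholds
fx_fp_counts <- function() fixture("fp_counts", {
  g <- toy_chicken_genome()
  kar <- identity_karyotype(g)
  cal <- calibrate_simulation(kar, simulation_params(seed = 1))
  vapply(1:20, function(s) {
    p <- simulation_params(seed = s)
    m <- simulate_map(kar, p, 250e3, calibration = cal)
    nrow(detect_translocations(m, detection_params(), genome = g))
  }, 1L)
})

# the full rearranged-karyotype run: every tabulated interchromosomal
# event planted on the assembly-scale genome, scanned at 250 kb and
# refined at 5 kb
fx_hd3_run <- function() fixture("hd3_run", {
  g <- galgal_like_genome()
  kar <- apply_edits(g, hd3_like_edits(include_intra = FALSE))
  p <- simulation_params(seed = 7)
  m <- simulate_map(kar, p, 250e3)
  f <- hic_fetcher(kar, p, refine_bin = 5e3)
  calls <- detect_translocations(m, detection_params(), refine = f, genome = g)
  list(genome = g, kar = kar, params = p, calls = calls)
})

# two-chromosome planted t(1;2)-style event at the tabulated coordinates
fx_t12 <- function() fixture("t12", {
  gg <- galgal_like_genome()
  g2 <- make_genome(gg$chromosomes[name %in% c("chr1", "chr2")])
  ed <- list(karyotype_edit("translocation", "chr1", 180580000, 194260000,
                            acceptor_chrom = "chr2", insertion = 149470000,
                            mode = "moved", haplotype = 1L))
  kar <- apply_edits(g2, ed)
  p <- simulation_params(seed = 11)
  m <- simulate_map(kar, p, 250e3)
  f <- hic_fetcher(kar, p, refine_bin = 5e3)
  bl <- trans_enrichment(m, "chr1", "chr2", detection_params())
  call <- localize_breakpoint(bl[1], m, detection_params(), refine = f)
  list(genome = g2, kar = kar, params = p, map = m, blocks = bl, call = call)
})

# two replicate maps with the same planted nested domains, independent
# noise
fx_tad_maps <- function() fixture("tad_maps", {
  g <- two_chrom_genome()
  kar <- identity_karyotype(g)
  # a 3 Mb parent containing two ~1 Mb children, plus a standalone domain
  tads <- data.table(chrom = "chrB",
                     start = c(1e6, 1.2e6, 2.6e6, 5e6),
                     end = c(4e6, 2.2e6, 3.6e6, 6.5e6))
  p1 <- simulation_params(seed = 61, total_contacts = 6e7,
                          compartment_strength = 0, tad_boost = 1.5,
                          tads = tads)
  p2 <- simulation_params(seed = 62, total_contacts = 6e7,
                          compartment_strength = 0, tad_boost = 1.5,
                          tads = tads)
  list(genome = g, tads = tads,
       m1 = simulate_map(kar, p1, 50e3), m2 = simulate_map(kar, p2, 50e3))
})

# breakpoint-recovery ensemble: planted unbalanced translocation with a
# 160-bin segment at 25 kb refine resolution, ten seeds
fx_bp_recovery <- function() fixture("bp_recovery", {
  g <- two_chrom_genome()
  ed <- list(karyotype_edit("translocation", "chrB", 2e6, 6e6,
                            acceptor_chrom = "chrA", insertion = 15e6,
                            haplotype = 1L))
  kar <- apply_edits(g, ed)
  dp <- detection_params(refine_bin = 25e3)
  res <- lapply(1:10, function(s) {
    p <- simulation_params(seed = 200 + s, total_contacts = 2e8,
                           het_mixture_weight = 1, trans_background = 1e-8)
    m <- simulate_map(kar, p, 250e3)
    f <- hic_fetcher(kar, p, refine_bin = 25e3)
    bl <- trans_enrichment(m, "chrA", "chrB", dp)
    if (!nrow(bl)) return(NULL)
    localize_breakpoint(bl[1], m, dp, refine = f)
  })
  list(kar = kar, genome = g, calls = rbindlist(res[!vapply(res, is.null, TRUE)]))
})

# simulation with a planted compartment checkerboard at delta = 0.4
fx_comp <- function() fixture("comp_maps", {
  g <- two_chrom_genome()
  kar <- identity_karyotype(g)
  p <- simulation_params(seed = 31, total_contacts = 4e7,
                         compartment_strength = 0.4)
  p0 <- simulation_params(seed = 32, total_contacts = 4e7,
                          compartment_strength = 0)
  list(genome = g, kar = kar, params = p,
       map = simulate_map(kar, p, 50e3),
       map0 = simulate_map(kar, p0, 50e3))
})

# planted t(21;5)-style terminal-segment event at tabulated coordinates
fx_t21 <- function() fixture("t21", {
  gg <- galgal_like_genome()
  g2 <- make_genome(gg$chromosomes[name %in% c("chr5", "chr21")])
  ed <- list(karyotype_edit("translocation", "chr21", 0, 325000,
                            acceptor_chrom = "chr5", insertion = 5000,
                            mode = "moved", haplotype = 1L))
  kar <- apply_edits(g2, ed)
  p <- simulation_params(seed = 13)
  m <- simulate_map(kar, p, 250e3)
  f <- hic_fetcher(kar, p, refine_bin = 5e3)
  calls <- detect_translocations(m, detection_params(), refine = f, genome = g2)
  list(genome = g2, kar = kar, params = p, calls = calls)
})
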