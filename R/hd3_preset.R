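#' Edit list emulating the HD3-like rearranged chicken karyotype
#'
#' A curated set of karyotype edits that plants, on a
#' [galgal_like_genome()], the 26 large (>= 200 kb) interchromosomal
#' rearrangements reported for the chicken HD3 erythroblast cell line, as
#' chains of derivative chromosomes: e.g. der(5) = 5 + 4p + 7p,
#' der(6) = 6 + 19 + 4q.1, der(23) = 23 + 12 + 21, plus the many
#' microchromosomal terminal fusions.  Multiway donors that cannot coexist
#' on one haplotype are planted as translocated duplications or on the
#' second haplotype, mirroring the heterogeneity of the real cell line.
#' Also included: the heterozygous GGA2-interstitial deletion, the ~1 Mb
#' terminal amplification on GGA11 and the W-chromosome gain seen in
#' coverage.
#'
#' Each of the 26 rearranged chromosome pairs acquires exactly one
#' contact-enrichment region, so a trans-SV scan of the simulated map
#' should return 26 interchromosomal calls.
#'
#' @param include_intra also plant the intrachromosomal events (default
#'   TRUE).
#' @return list of [karyotype_edit()]s.
#' @export
hd3_like_edits <- function(include_intra = TRUE) {
  tl <- function(dc, ds, de, ac, ins, mode = "moved", hap = 1L, ori = "+")
    karyotype_edit("translocation", dc, ds, de, acceptor_chrom = ac,
                   insertion = ins, mode = mode, haplotype = hap,
                   orientation = ori)
  ed <- list(
    # haplotype 1 -----------------------------------------------------
    # der(2): translocated duplication of 1q-ter into 2q near qter
    tl("chr1", 180580000, 194260000, "chr2", 149470000, mode = "duplicated"),
    # der(33) = 33 + 7p-part (duplicated before 7p is broken up below)
    tl("chr7", 4110000, 36905000, "chr33", "ter:q", mode = "duplicated"),
    # der(5) = 5 + 7p-part + 4p (both stacked at 5qter breakpoint; guest
    # order keeps every pairwise separation small enough to detect)
    tl("chr7", 0, 6310000, "chr5", 59820000),
    tl("chr4", 0, 16835000, "chr5", 59820000),
    # der(6) = 6(p-stub) + 19 + 4q.1 + 6(rest)
    tl("chr19", 0, 9985000, "chr6", 500000),
    tl("chr4", 18835000, 51490000, "chr6", 500000),
    # der(17) = 17 + 4q.2
    tl("chr4", 51505000, 91280000, "chr17", 10950000),
    # der(23) = 23 + 21 + 28-terminus + 12: one chain covers all six
    # pairwise interactions, each within detectable separation
    tl("chr21", 0, 6860000, "chr23", 5785000),
    # der(28) = 28 + 13-part, then the 28 terminus moves onto der(23)
    tl("chr13", 500000, 18400000, "chr28", "ter:q"),
    tl("chr28", 0, 1140000, "chr23", 5785000),
    tl("chr12", 0, 19945000, "chr23", 5785000),
    # der(3) = 18 + 3
    tl("chr18", 0, 11040000, "chr3", 0),
    # haplotype 2 -----------------------------------------------------
    # der(33b) = 28 + 33 + 17-part
    tl("chr17", 505000, 10950000, "chr33", "ter:q", mode = "duplicated", hap = 2L),
    tl("chr28", 0, 4970000, "chr33", "ter:p", mode = "duplicated", hap = 2L),
    # der(28b) = 28 + 17-part
    tl("chr17", 505000, 10950000, "chr28", "ter:q", hap = 2L),
    # der(9) = 9 + 5 (whole-chromosome fusion), 21-terminus duplicated in
    tl("chr5", 0, 59820000, "chr9", "ter:q", hap = 2L),
    tl("chr21", 0, 325000, "chr5", 5000, mode = "duplicated", hap = 2L),
    # der(27) = 27 + 7p-part; its p-terminus duplicated onto 23
    tl("chr7", 6145000, 36905000, "chr27", "ter:q", hap = 2L),
    tl("chr27", 0, 5035000, "chr23", "ter:p", mode = "duplicated", hap = 2L),
    # der(3b) = 3 + 24
    tl("chr24", 0, 6270000, "chr3", 2200000, hap = 2L)
  )
  if (include_intra) {
    ed <- c(ed, list(
      karyotype_edit("deletion", "chr2", 54325000, 61685000, haplotype = 1L),
      karyotype_edit("duplication", "chr11", 18960000, 19960000,
                     copies = 4L, haplotype = 1L),
      karyotype_edit("whole_chrom_gain", "chrW", haplotype = 1L)
    ))
  }
  ed
}

#' The 26 rearranged chromosome pairs planted by [hd3_like_edits()]
#'
#' @return data.table (`chrom1`, `chrom2`), one row per expected
#'   interchromosomal enrichment region.
#' @export
hd3_like_pairs <- function() {
  p <- rbind(
    c("chr1", "chr2"), c("chr4", "chr5"), c("chr5", "chr7"), c("chr4", "chr7"),
    c("chr4", "chr6"), c("chr4", "chr19"), c("chr6", "chr19"),
    c("chr4", "chr17"), c("chr5", "chr9"), c("chr12", "chr23"),
    c("chr12", "chr21"), c("chr21", "chr23"), c("chr23", "chr28"),
    c("chr3", "chr18"), c("chr13", "chr28"), c("chr17", "chr33"),
    c("chr28", "chr33"), c("chr17", "chr28"), c("chr5", "chr21"),
    c("chr9", "chr21"), c("chr7", "chr33"), c("chr7", "chr27"),
    c("chr21", "chr28"), c("chr12", "chr28"), c("chr23", "chr27"),
    c("chr3", "chr24"))
  data.table(chrom1 = p[, 1], chrom2 = p[, 2])
}
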