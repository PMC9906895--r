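#' Genome-wide cis/trans contact ratio
#'
#' The ratio of intra- to interchromosomal contact sums (diagonal included
#' in cis), a standard proxy for random-ligation noise in Hi-C libraries:
#' low-noise avian libraries typically fall in the 1.6-2.3 band.
#'
#' @param m a `contact_matrix` covering at least two chromosomes.
#' @return a single number; `Inf` (with a warning) when no trans contacts.
#' @export
cis_trans_ratio <- function(m) {
  if (length(matrix_genome_chroms(m)) < 2L)
    stop("cis/trans ratio needs at least two chromosomes")
  px <- pixel_chroms(m)
  cis <- px[chrom1 == chrom2, sum(count)]
  trans <- px[chrom1 != chrom2, sum(count)]
  if (trans == 0) {
    warning("no trans contacts: cis/trans ratio is infinite")
    return(Inf)
  }
  cis / trans
}

#' Fraction of contacts that are interchromosomal
#'
#' @param m a `contact_matrix`.
#' @return trans / total, in `[0, 1]`.
#' @export
trans_fraction <- function(m) {
  px <- pixel_chroms(m)
  tot <- px[, sum(count)]
  if (tot == 0) stop("empty contact matrix")
  px[chrom1 != chrom2, sum(count)] / tot
}

#' Pearson correlation between two contact maps
#'
#' Both maps are coarsened to `bin_size`, and the correlation is computed on
#' log1p raw counts over the union of pixels that are non-zero in either
#' map (zeros in the other map included).
#'
#' @param m1,m2 `contact_matrix` objects on the same genome.
#' @param bin_size comparison bin size (default 50 kb).
#' @return Pearson r in `[-1, 1]`.
#' @export
replicate_correlation <- function(m1, m2, bin_size = 50e3) {
  c1 <- coarsen_matrix(m1, bin_size); c2 <- coarsen_matrix(m2, bin_size)
  if (!isTRUE(all.equal(c1$bins$bins[, .(chrom, start, end)],
                        c2$bins$bins[, .(chrom, start, end)])))
    stop("matrices are on different genomes")
  u <- merge(c1$pixels, c2$pixels, by = c("bin1", "bin2"), all = TRUE,
             suffixes = c("1", "2"))
  u[is.na(count1), count1 := 0]; u[is.na(count2), count2 := 0]
  cor(log1p(u$count1), log1p(u$count2))
}

#' Per-bin coverage (marginal contact sum)
#'
#' The marginal sum of each bin's contacts; with `normalize = TRUE` divided
#' by the autosomal median so that a normal diploid bin sits near 1 --
#' the coverage track used for read-depth CNV analysis.
#'
#' @param m a `contact_matrix`.
#' @param normalize divide by the autosomal median (default TRUE).
#' @param genome optional `genome_model` carrying `chrom_class`; when given,
#'   sex chromosomes are excluded from the normalizing median.
#' @return data.table (`chrom`, `start`, `end`, `gbin`, `value`) of class
#'   `coverage_track` (attribute `bin_size`).
#' @export
coverage_track <- function(m, normalize = TRUE, genome = NULL) {
  b <- copy(m$bins$bins)
  px <- m$pixels
  v <- numeric(nrow(b))
  if (nrow(px)) {
    s1 <- px[, .(s = sum(count)), by = bin1]
    s2 <- px[bin1 != bin2, .(s = sum(count)), by = bin2]
    v[s1$bin1] <- v[s1$bin1] + s1$s
    if (nrow(s2)) v[s2$bin2] <- v[s2$bin2] + s2$s
  }
  b[, value := v]
  if (normalize) {
    auto <- if (!is.null(genome))
      genome$chromosomes[chrom_class %in% c("macro", "micro"), name]
    else unique(b$chrom)
    med <- b[chrom %in% auto & value > 0, median(value)]
    if (!is.finite(med) || med == 0) stop("cannot normalize all-zero coverage")
    b[, value := value / med]
  }
  setattr(b, "bin_size", m$bins$bin_size)
  setattr(b, "class", c("coverage_track", class(b)))
  b[]
}

#' Write a per-bin track as bedGraph
#'
#' @param track a data.table with `chrom`, `start`, `end` and a value column.
#' @param path output file.
#' @param value_col name of the value column (default `"value"`).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value_col = "value") {
  dt <- as.data.table(track)[, .(chrom, start = as.integer(start),
                                 end = as.integer(end),
                                 value = get(value_col))]
  fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
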