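#' Genome bin table
#'
#' Tiles each chromosome with fixed-size bins (0-based, half-open; the last
#' bin of a chromosome may be short) and assigns a strictly increasing global
#' bin index `gbin` (1-based).
#'
#' @param genome a `genome_model`.
#' @param bin_size bin size in bp.
#' @return list of class `bin_table` with elements `bins` (data.table:
#'   `chrom`, `start`, `end`, `gbin`) and `bin_size`.
#' @export
bin_table <- function(genome, bin_size) {
  stopifnot(bin_size >= 1)
  ch <- genome$chromosomes
  bins <- ch[, {
    n <- ceiling(length / bin_size)
    s <- (seq_len(n) - 1) * bin_size
    .(start = s, end = pmin(s + bin_size, length))
  }, by = .(chrom = name)]
  bins[, gbin := .I]
  structure(list(bins = bins[], bin_size = bin_size), class = "bin_table")
}

#' Sparse binned contact matrix
#'
#' Stores the upper triangle (`bin1 <= bin2`, global bin indices) of a
#' symmetric genome-wide contact matrix.
#'
#' @param bins a `bin_table`.
#' @param pixels data.table/data.frame with columns `bin1`, `bin2`, `count`.
#' @return an object of class `contact_matrix`.
#' @export
contact_matrix <- function(bins, pixels) {
  stopifnot(inherits(bins, "bin_table"))
  px <- as.data.table(pixels)
  stopifnot(all(c("bin1", "bin2", "count") %in% names(px)))
  n <- nrow(bins$bins)
  if (nrow(px)) {
    if (any(px$bin1 < 1L | px$bin2 > n)) stop("pixel references a bin outside the bin table")
    if (any(!is.finite(px$count) | px$count < 0)) stop("counts must be finite and >= 0")
    swap <- px$bin1 > px$bin2
    if (any(swap)) px[swap, `:=`(bin1 = pixels$bin2[swap], bin2 = pixels$bin1[swap])]
    px <- px[, .(count = sum(count)), by = .(bin1, bin2)]
    setkey(px, bin1, bin2)
  }
  structure(list(bins = bins, pixels = px[]), class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %d bins @ %s bp, %d non-zero pixels, %.3g contacts\n",
              nrow(x$bins$bins), format(x$bins$bin_size, scientific = FALSE),
              nrow(x$pixels), sum(x$pixels$count)))
  invisible(x)
}

matrix_genome_chroms <- function(m) unique(m$bins$bins$chrom)

# annotate pixels with chromosome of each end
pixel_chroms <- function(m) {
  b <- m$bins$bins
  px <- copy(m$pixels)
  px[, chrom1 := b$chrom[bin1]]
  px[, chrom2 := b$chrom[bin2]]
  px
}

#' Coarsen a contact matrix to a larger bin size
#'
#' @param m a `contact_matrix`.
#' @param bin_size new bin size; must be a multiple of the current one.
#' @return a `contact_matrix` at the new resolution.
#' @export
coarsen_matrix <- function(m, bin_size) {
  old <- m$bins$bin_size
  if (bin_size == old) return(m)
  if (bin_size %% old != 0) stop("new bin size must be a multiple of the old one")
  genome <- make_genome(m$bins$bins[, .(length = max(end)), by = .(name = chrom)])
  bt <- bin_table(genome, bin_size)
  b <- m$bins$bins
  map <- bt$bins[b[, .(chrom, pos = start)], on = .(chrom, start <= pos, end > pos),
                 x.gbin]
  px <- m$pixels[, .(bin1 = map[bin1], bin2 = map[bin2], count)]
  contact_matrix(bt, px)
}

# dense matrix for the rectangle rows x cols (global bin indices), symmetric
# expansion included
dense_block <- function(m, rows, cols) {
  px <- m$pixels
  out <- matrix(0, length(rows), length(cols))
  ri <- integer(nrow(m$bins$bins)); ri[rows] <- seq_along(rows)
  ci <- integer(nrow(m$bins$bins)); ci[cols] <- seq_along(cols)
  sel <- px[(bin1 %between% range(rows) & bin2 %between% range(cols)) |
            (bin1 %between% range(cols) & bin2 %between% range(rows))]
  if (nrow(sel)) {
    a <- ri[sel$bin1]; b <- ci[sel$bin2]
    ok <- a > 0L & b > 0L
    if (any(ok)) {
      idx <- cbind(a[ok], b[ok])
      out[idx] <- out[idx] + sel$count[ok]
    }
    a2 <- ri[sel$bin2]; b2 <- ci[sel$bin1]
    ok2 <- a2 > 0L & b2 > 0L & sel$bin1 != sel$bin2
    if (any(ok2)) {
      idx2 <- cbind(a2[ok2], b2[ok2])
      out[idx2] <- out[idx2] + sel$count[ok2]
    }
  }
  out
}

# dense symmetric cis matrix for one chromosome
dense_chrom <- function(m, chr) {
  g <- m$bins$bins[chrom == chr, gbin]
  dense_block(m, g, g)
}

chrom_gbins <- function(m, chr) m$bins$bins[chrom == chr, gbin]

#' Write / read a contact matrix as COO triplet text
#'
#' Writes two files: `<prefix>.pixels.tsv` (bin1, bin2, count; 1-based global
#' bin indices, upper triangle) and `<prefix>.bins.tsv` (chrom, start, end).
#'
#' @param m a `contact_matrix`.
#' @param prefix output path prefix.
#' @return the two file paths, invisibly.
#' @export
write_coo <- function(m, prefix) {
  pb <- paste0(prefix, ".bins.tsv"); pp <- paste0(prefix, ".pixels.tsv")
  fwrite(m$bins$bins[, .(chrom, start, end)], pb, sep = "\t")
  fwrite(m$pixels, pp, sep = "\t")
  invisible(c(pb, pp))
}

#' @rdname write_coo
#' @export
read_coo <- function(prefix) {
  b <- fread(paste0(prefix, ".bins.tsv"))
  px <- fread(paste0(prefix, ".pixels.tsv"))
  genome <- make_genome(b[, .(length = max(end)), by = .(name = chrom)])
  bs <- as.numeric(names(sort(table(b$end - b$start), decreasing = TRUE))[1L])
  bt <- bin_table(genome, bs)
  if (nrow(bt$bins) != nrow(b)) stop("bins file does not tile its genome evenly")
  contact_matrix(bt, px)
}
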