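#' Build a genome model
#'
#' A genome model is the reference coordinate system for everything else in
#' the package: an ordered set of named chromosomes with lengths (bp), a
#' chromosome class (avian genomes mix a few large macrochromosomes with many
#' small, typically acrocentric microchromosomes, plus the Z/W sex pair), an
#' optional centromere position and a per-chromosome copy number (ploidy).
#'
#' @param chromosomes a data.frame (or data.table) with columns `name` and
#'   `length`, and optionally `chrom_class` (`"macro"`, `"micro"`, `"sexZ"`,
#'   `"sexW"`), `centromere` (bp or NA) and `ploidy` (integer copies; default
#'   2, except 1 for `sexW`).
#' @return an object of class `genome_model`.
#' @export
make_genome <- function(chromosomes) {
  ch <- as.data.table(chromosomes)
  if (!all(c("name", "length") %in% names(ch)) || nrow(ch) < 1L)
    stop("genome spec needs >= 1 chromosome with columns 'name' and 'length'")
  ch[, name := as.character(name)]
  ch[, length := as.numeric(length)]
  if (anyDuplicated(ch$name))
    stop("duplicate chromosome names: ",
         paste(unique(ch$name[duplicated(ch$name)]), collapse = ", "))
  if (any(!is.finite(ch$length) | ch$length <= 0))
    stop("chromosome lengths must be positive")
  if (!"chrom_class" %in% names(ch)) ch[, chrom_class := "macro"]
  ok <- ch$chrom_class %in% c("macro", "micro", "sexZ", "sexW")
  if (!all(ok)) stop("unknown chrom_class: ", paste(ch$chrom_class[!ok], collapse = ", "))
  if (!"centromere" %in% names(ch)) ch[, centromere := NA_real_]
  bad <- !is.na(ch$centromere) & (ch$centromere <= 0 | ch$centromere >= ch$length)
  if (any(bad)) stop("centromere must lie strictly inside the chromosome")
  if (!"ploidy" %in% names(ch))
    ch[, ploidy := fifelse(chrom_class == "sexW", 1L, 2L)]
  ch[, ploidy := as.integer(ploidy)]
  if (any(ch$ploidy < 1L)) stop("ploidy must be >= 1")
  g <- structure(list(chromosomes = ch[]), class = "genome_model")
  g
}

#' @export
print.genome_model <- function(x, ...) {
  ch <- x$chromosomes
  cat(sprintf("<genome_model> %d chromosomes, %.1f Mb total\n",
              nrow(ch), sum(ch$length) / 1e6))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(ch$chrom_class)),
                            as.integer(table(ch$chrom_class))), collapse = " ")))
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chromosomes$name)
  if (anyNA(i)) stop("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$chromosomes$length[i]
}

#' Toy chicken-like genome preset
#'
#' A small genome with the architecture of the chicken karyotype -- a few
#' macrochromosomes, many microchromosomes, and the Z/W sex pair (single W) --
#' scaled down so that genome-wide simulations run in seconds.  Five
#' macrochromosomes (30-80 Mb), ten microchromosomes (1.2-12 Mb), Z and W.
#'
#' @return a `genome_model` with 17 chromosomes.
#' @export
toy_chicken_genome <- function() {
  macro <- data.table(
    name = paste0("chr", 1:5),
    length = c(80e6, 61e6, 45e6, 38e6, 30e6),
    chrom_class = "macro")
  micro <- data.table(
    name = paste0("chr", 6:15),
    length = c(12, 10, 8, 6.5, 5, 4, 3, 2.5, 1.8, 1.2) * 1e6,
    chrom_class = "micro")
  sex <- data.table(
    name = c("chrZ", "chrW"),
    length = c(43e6, 7e6),
    chrom_class = c("sexZ", "sexW"))
  ch <- rbind(macro, micro, sex)
  ch[, centromere := fifelse(chrom_class == "micro", 0.05 * length, 0.4 * length)]
  make_genome(ch)
}

#' Chicken genome at reference-assembly magnitudes
#'
#' Chromosome lengths at the magnitude of the chicken reference assembly
#' (GalGal5-scale), covering the macro- and microchromosomes that are well
#' assembled and mappable (the NOR-bearing and smallest microchromosomes are
#' left out, as is standard for chicken Hi-C analyses).  Lengths are rounded
#' to 5 kb multiples.
#'
#' @return a `genome_model` with 29 chromosomes (1-15, 17-24, 26-28, 33, Z, W).
#' @export
galgal_like_genome <- function() {
  ch <- data.table(
    name = paste0("chr", c(1:15, 17:24, 26:28, 33, "Z", "W")),
    length = c(
      196205000, 149565000, 110855000, 91285000, 59830000,   # 1-5
      35465000, 36950000, 29965000, 24095000, 20390000,      # 6-10
      19960000, 20275000, 18410000, 15595000, 12765000,      # 11-15
      10960000, 11055000, 9985000, 14110000, 6865000,        # 17-21
      4080000, 5790000, 6285000,                             # 22-24
      5070000, 5315000, 4975000,                             # 26-28
      1650000,                                               # 33
      82365000, 6815000))                                    # Z, W
  ch[, chrom_class := "micro"]
  ch[name %in% paste0("chr", 1:10), chrom_class := "macro"]
  ch[name == "chrZ", chrom_class := "sexZ"]
  ch[name == "chrW", chrom_class := "sexW"]
  ch[, centromere := fifelse(chrom_class == "micro", 0.05 * length, 0.4 * length)]
  make_genome(ch)
}

#' Write / read a two-column chrom.sizes file
#'
#' @param genome a `genome_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  fwrite(genome$chromosomes[, .(name, length = as.integer64ish(length))],
         path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# lengths fit in doubles; write as plain integers without scientific notation
as.integer64ish <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' @rdname write_chrom_sizes
#' @param path a chrom.sizes file (name, length).
#' @export
read_chrom_sizes <- function(path) {
  ch <- fread(path, header = FALSE, col.names = c("name", "length"))
  make_genome(ch)
}
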