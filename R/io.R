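#' Write analysis results to standard text formats
#'
#' Writes whatever result tables are supplied: BEDPE for translocations and
#' inversions, BED for CNV calls, domains and compartment segments,
#' bedGraph for eigenvector and coverage tracks, AGP v2.1 for derivative
#' reconstructions, a Table-style TSV summary of translocations and a JSON
#' run manifest.  Missing elements produce valid empty (headered) files.
#'
#' @param results list with any of: `calls` (sv_calls), `inversions`,
#'   `cnv`, `tads` (domain_set), `compartments` (compartment_track),
#'   `coverage` (coverage_track), `derivatives`
#'   ([reconstruct_derivatives()] output), `params` (list), `seed`.
#' @param out_dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(results, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  written <- character()
  w <- function(path) { written <<- c(written, path); path }

  calls <- results$calls %||% localize_skeleton()
  bedpe <- data.table(
    chrom1 = calls$chrom_donor, start1 = calls$seg_start, end1 = calls$seg_end,
    chrom2 = calls$chrom_acceptor,
    start2 = calls$insertion_bp, end2 = calls$insertion_bp + calls$uncertainty_bp,
    name = paste0(calls$kind, ":", calls$classification),
    score = calls$score, strand1 = calls$orientation, strand2 = ".",
    uncertainty_bp = calls$uncertainty_bp)
  fwrite(bedpe, w(file.path(out_dir, "translocations.bedpe")), sep = "\t")

  tsv <- data.table(chrom1 = calls$chrom_donor,
                    start = calls$seg_start, end = calls$seg_end,
                    chrom2 = calls$chrom_acceptor,
                    insertion_site = calls$insertion,
                    orientation = calls$orientation,
                    classification = calls$classification,
                    score = calls$score)
  fwrite(tsv, w(file.path(out_dir, "translocation_table.tsv")), sep = "\t")

  inv <- results$inversions %||% inversion_skeleton()
  invpe <- data.table(chrom1 = inv$chrom, start1 = inv$start, end1 = inv$start,
                      chrom2 = inv$chrom, start2 = inv$end, end2 = inv$end,
                      name = "inversion", score = inv$score,
                      strand1 = "+", strand2 = "-")
  fwrite(invpe, w(file.path(out_dir, "inversions.bedpe")), sep = "\t")

  cnv <- results$cnv %||% data.table(chrom = character(), start = numeric(),
                                     end = numeric(), state = character(),
                                     log2_ratio = numeric())
  fwrite(cnv[, .(chrom, start, end, name = state, score = log2_ratio)],
         w(file.path(out_dir, "cnv.bed")), sep = "\t")

  if (!is.null(results$tads)) {
    td <- as.data.table(results$tads)
    bs <- attr(results$tads, "bin_size") %||% 1
    gam <- if ("gammas" %in% names(td)) td$gammas else as.character(td$gamma)
    fwrite(data.table(chrom = td$chrom, start = (td$start_bin - 1) * bs,
                      end = td$end_bin * bs, name = paste0("gamma=", gam),
                      score = td$q),
           w(file.path(out_dir, "domains.bed")), sep = "\t")
  }
  if (!is.null(results$compartments)) {
    ct <- as.data.table(results$compartments)
    write_bedgraph(ct[!is.na(value)], w(file.path(out_dir, "eigenvector.bedgraph")))
    seg <- ct[!is.na(label)][, .(chrom, start, end, name = label)]
    fwrite(seg, w(file.path(out_dir, "compartments.bed")), sep = "\t")
  }
  if (!is.null(results$coverage))
    write_bedgraph(as.data.table(results$coverage),
                   w(file.path(out_dir, "coverage.bedgraph")))

  write_agp(results$derivatives %||% list(),
            w(file.path(out_dir, "derivatives.agp")))

  manifest <- list(package = "karyohic",
                   version = as.character(utils::packageVersion("karyohic")),
                   seed = results$seed %||% NA,
                   params = results$params %||% list(),
                   n_translocations = nrow(calls),
                   written = basename(written),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, w(file.path(out_dir, "run_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(written)
}

#' Write derivative reconstructions as AGP v2.1
#'
#' One object per derivative; every component is a `W` (WGS contig-like)
#' line citing the reference interval it derives from.
#'
#' @param derivatives list of reconstructions (`name`, `segments`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_agp <- function(derivatives, path) {
  con <- file(path, "w")
  writeLines("##agp-version\t2.1", con)
  for (d in derivatives) {
    segs <- d$segments
    pos <- 0
    for (k in seq_len(nrow(segs))) {
      len <- segs$end[k] - segs$start[k]
      writeLines(paste(d$name, format(pos + 1, scientific = FALSE, trim = TRUE),
                       format(pos + len, scientific = FALSE, trim = TRUE),
                       k, "W", segs$chrom[k],
                       format(segs$start[k] + 1, scientific = FALSE, trim = TRUE),
                       format(segs$end[k], scientific = FALSE, trim = TRUE),
                       segs$orientation[k], sep = "\t"), con)
      pos <- pos + len
    }
  }
  close(con)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#")]
  if (!length(ln)) return(list())
  dt <- as.data.table(do.call(rbind, strsplit(ln, "\t")))
  setnames(dt, c("object", "obeg", "oend", "part", "type", "chrom",
                 "cbeg", "cend", "orientation"))
  lapply(split(dt, by = "object", sorted = FALSE), function(s)
    list(name = s$object[1L],
         segments = s[, .(chrom, start = as.numeric(cbeg) - 1,
                          end = as.numeric(cend), orientation)]))
}
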