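# Plain-text readers/writers: truth tables, BED/BEDPE, bedGraph, manifests.

write_tsv <- function(df, file) {
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

read_tsv <- function(file) {
  read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Write a truth table to a directory of TSV files
#'
#' Emits `boundaries.tsv`, `loops.tsv`, `enhancers.tsv`, `gene_modes.tsv`,
#' `ctcf_sites.tsv` and a small JSON manifest with the conditions and
#' generator parameters.
#'
#' @param truth A [generate_truth()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv(truth$boundaries, file.path(dir, "boundaries.tsv"))
  write_tsv(truth$loops, file.path(dir, "loops.tsv"))
  write_tsv(truth$enhancers, file.path(dir, "enhancers.tsv"))
  write_tsv(truth$gene_modes, file.path(dir, "gene_modes.tsv"))
  write_tsv(truth$ctcf_sites, file.path(dir, "ctcf_sites.tsv"))
  jsonlite::write_json(
    list(conditions = truth$conditions, params = truth$params),
    file.path(dir, "truth_manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a truth table written by [write_truth()]
#' @param dir Directory containing the truth TSV files.
#' @return A `truth_table` object.
#' @export
read_truth <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "truth_manifest.json"),
                             simplifyVector = TRUE)
  structure(
    list(boundaries = read_tsv(file.path(dir, "boundaries.tsv")),
         loops = read_tsv(file.path(dir, "loops.tsv")),
         enhancers = read_tsv(file.path(dir, "enhancers.tsv")),
         gene_modes = read_tsv(file.path(dir, "gene_modes.tsv")),
         ctcf_sites = read_tsv(file.path(dir, "ctcf_sites.tsv")),
         conditions = man$conditions, params = man$params),
    class = "truth_table"
  )
}

#' Write peaks as 5-column BED
#'
#' Columns chrom, start, end, name, signal; 0-based half-open coordinates.
#'
#' @param peaks data.frame with chrom, start, end, name, signal.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_peaks_bed <- function(peaks, file) {
  write.table(peaks[, c("chrom", "start", "end", "name", "signal")], file,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' Read a 5-column BED peak file
#' @param file Path to a BED file written by [write_peaks_bed()].
#' @return data.frame with chrom, start, end, name, signal.
#' @export
read_peaks_bed <- function(file) {
  df <- read.table(file, sep = "\t", stringsAsFactors = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "signal")[seq_len(ncol(df))]
  df
}

#' Write HiChIP bin-pair counts as BEDPE
#'
#' One file per condition with 0-based half-open anchor intervals and one
#' count column per replicate.
#'
#' @param sim A [generate_hichip()] result.
#' @param dir Output directory.
#' @param bin_size Bin width (taken from `sim`).
#' @return Character vector of written paths, invisibly.
#' @export
write_hichip_bedpe <- function(sim, dir, bin_size = sim$bin_size) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(sim$conditions, function(cond) {
    df <- data.frame(
      chrom1 = sim$pairs$chrom,
      start1 = bin_start(sim$pairs$bin1, bin_size),
      end1 = bin_start(sim$pairs$bin1, bin_size) + bin_size,
      chrom2 = sim$pairs$chrom,
      start2 = bin_start(sim$pairs$bin2, bin_size),
      end2 = bin_start(sim$pairs$bin2, bin_size) + bin_size)
    df <- cbind(df, as.data.frame(sim$counts[[cond]]))
    f <- file.path(dir, sprintf("hichip_%s.bedpe", cond))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    f
  }, character(1))
  invisible(paths)
}

#' Read a BEDPE count table written by [write_hichip_bedpe()]
#' @param file Path to the BEDPE file.
#' @param bin_size Bin width in bp.
#' @return List with `pairs` (chrom, bin1, bin2, span) and `counts` matrix.
#' @export
read_hichip_bedpe <- function(file, bin_size = 10000L) {
  df <- read.table(file, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  pairs <- data.frame(chrom = df$chrom1,
                      bin1 = pos_to_bin(df$start1, bin_size),
                      bin2 = pos_to_bin(df$start2, bin_size))
  pairs$span <- (pairs$bin2 - pairs$bin1) * bin_size
  counts <- as.matrix(df[, -(1:6), drop = FALSE])
  list(pairs = pairs, counts = counts)
}

#' Write a per-bin track as bedGraph
#'
#' `NA` bins are skipped.
#'
#' @param values Numeric per-bin vector (1-based bins).
#' @param chrom Chromosome name.
#' @param bin_size Bin width in bp.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_bedgraph <- function(values, chrom, bin_size, file) {
  keep <- which(!is.na(values))
  df <- data.frame(chrom = chrom, start = bin_start(keep, bin_size),
                   end = bin_start(keep, bin_size) + bin_size,
                   value = values[keep])
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' Write boundary calls as BED
#'
#' One bin-wide 0-based half-open interval per boundary, strength in the
#' score column.
#'
#' @param calls data.frame from [call_boundaries()].
#' @param bin_size Bin width in bp.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_boundaries_bed <- function(calls, bin_size, file) {
  df <- data.frame(chrom = calls$chrom,
                   start = bin_start(calls$bin, bin_size),
                   end = bin_start(calls$bin, bin_size) + bin_size,
                   name = sprintf("boundary_%03d", seq_len(nrow(calls))),
                   score = calls$strength)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
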