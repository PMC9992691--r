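# Shared helpers: bin arithmetic, seed derivation, interval conversion.

#' Map a genomic position to its bin index
#'
#' Bins are fixed-width, 1-based: bin `i` covers the 0-based half-open
#' interval `[(i-1)*bin_size, i*bin_size)`.
#'
#' @param pos 0-based genomic position (bp).
#' @param bin_size Bin width in bp.
#' @return Integer bin index (1-based).
#' @export
pos_to_bin <- function(pos, bin_size) {
  as.integer(floor(pos / bin_size)) + 1L
}

#' 0-based start coordinate of a bin
#' @param bin 1-based bin index.
#' @param bin_size Bin width in bp.
#' @return 0-based start position.
#' @export
bin_start <- function(bin, bin_size) {
  (as.numeric(bin) - 1) * bin_size
}

# Derive a per-stage seed from a pipeline-level seed by a fixed offset.
# Kept below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101L + offset * 7919L) %% 2147483629)
}

# data.frame of 0-based half-open intervals -> GRanges (1-based closed)
df_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

# anchors (chrom, bin) -> GRanges of the 10-kb (or bin_size) anchor intervals
anchors_to_granges <- function(chrom, bin, bin_size) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(
      start = bin_start(bin, bin_size) + 1,
      end = bin_start(bin, bin_size) + bin_size
    )
  )
}

anchor_key <- function(chrom, bin) paste0(chrom, ":", bin)

stop_if_not_df <- function(x, cols, what) {
  if (!is.data.frame(x) || !all(cols %in% names(x))) {
    stop(sprintf("%s must be a data.frame with columns: %s",
                 what, paste(cols, collapse = ", ")), call. = FALSE)
  }
}
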