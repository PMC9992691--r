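# Binned contact matrix container and text I/O.

#' Construct a binned contact matrix
#'
#' A symmetric, non-negative per-chromosome contact matrix at fixed bin size.
#' Bin `i` covers the 0-based interval `[(i-1)*bin_size, i*bin_size)`; a
#' trailing partial bin is kept.
#'
#' @param counts Square symmetric numeric matrix of non-negative finite
#'   counts.
#' @param chrom Chromosome identifier.
#' @param bin_size Bin width in bp.
#' @param normalized Logical flag recording whether balancing has been run.
#' @return An object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, chrom, bin_size, normalized = FALSE) {
  counts <- as.matrix(counts)
  dimnames(counts) <- NULL
  if (nrow(counts) != ncol(counts)) stop("counts must be square")
  if (any(!is.finite(counts))) stop("counts must be finite")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (max(abs(counts - t(counts))) > 1e-8 * max(1, max(abs(counts)))) {
    stop("counts must be symmetric")
  }
  if (bin_size <= 0) stop("bin_size must be positive")
  structure(
    list(chrom = as.character(chrom), bin_size = as.integer(bin_size),
         counts = counts, normalized = isTRUE(normalized)),
    class = "contact_matrix"
  )
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("<contact_matrix> %s: %d bins @ %d bp, total %.4g%s\n",
              x$chrom, nrow(x$counts), x$bin_size, sum(x$counts),
              if (x$normalized) " (balanced)" else ""))
  invisible(x)
}

#' Number of bins covering a chromosome
#' @param chrom_length Chromosome length in bp.
#' @param bin_size Bin width in bp.
#' @return Integer bin count (a trailing partial bin counts as one bin).
#' @export
n_bins <- function(chrom_length, bin_size) {
  as.integer(ceiling(chrom_length / bin_size))
}

#' Write a contact matrix as text
#'
#' `coo` writes a 3-column coordinate list (`bin_i`, `bin_j`, `count`;
#' upper triangle including the diagonal, 1-based bins) with a `#` header
#' carrying chrom/bin_size; `dense` writes the full tab-separated matrix.
#'
#' @param m A [contact_matrix()].
#' @param file Output path.
#' @param format `"coo"` or `"dense"`.
#' @return `file`, invisibly.
#' @export
write_contact_matrix <- function(m, file, format = c("coo", "dense")) {
  format <- match.arg(format)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s bin_size=%d n_bins=%d format=%s",
                     m$chrom, m$bin_size, nrow(m$counts), format), con)
  if (format == "coo") {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    df <- data.frame(bin_i = idx[, 1], bin_j = idx[, 2],
                     count = m$counts[idx])
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    write.table(m$counts, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(file)
}

#' Read a contact matrix written by [write_contact_matrix()]
#' @param file Path to a coo or dense text matrix.
#' @return A [contact_matrix()].
#' @export
read_contact_matrix <- function(file) {
  hdr <- readLines(file, n = 1L)
  get <- function(key) sub(sprintf(".*%s=(\\S+).*", key), "\\1", hdr)
  chrom <- get("chrom")
  bin_size <- as.integer(get("bin_size"))
  nb <- as.integer(get("n_bins"))
  fmt <- get("format")
  dat <- read.table(file, sep = "\t", comment.char = "#")
  if (fmt == "coo") {
    counts <- matrix(0, nb, nb)
    counts[cbind(dat[[1]], dat[[2]])] <- dat[[3]]
    counts[cbind(dat[[2]], dat[[1]])] <- dat[[3]]
  } else {
    counts <- as.matrix(dat)
    dimnames(counts) <- NULL
  }
  contact_matrix(counts, chrom, bin_size)
}

#' Rebin a contact matrix to a coarser resolution
#'
#' Sums counts in blocks; the new bin size must be an integer multiple of
#' the old one.
#'
#' @param m A [contact_matrix()].
#' @param new_bin_size Target bin width (bp).
#' @return A [contact_matrix()] at the coarser resolution.
#' @export
rebin_matrix <- function(m, new_bin_size) {
  k <- new_bin_size / m$bin_size
  if (k != round(k) || k < 1) {
    stop("new_bin_size must be an integer multiple of the current bin size")
  }
  k <- as.integer(k)
  if (k == 1L) return(m)
  grp <- (seq_len(nrow(m$counts)) - 1L) %/% k + 1L
  agg <- rowsum(m$counts, grp)
  agg <- t(rowsum(t(agg), grp))
  contact_matrix(agg, m$chrom, new_bin_size)
}
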