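# Negative-binomial differential engine and threshold-based classification
# of loops, enhancer anchors, and genes.

#' Classification thresholds
#'
#' The default thresholds: the constant/constitutive band is
#' `|log2FC| < log2(1.3)` (0.378512) with `P > 0.5`; changing loops need
#' `P < 0.1` and `|log2FC| > log2(1.5)` (0.584963); changing enhancers need
#' `P < 0.1` and `|log2FC| > log2(1.3)`; differential expression uses
#' BH-adjusted `p < 0.05` and a per-contrast fold threshold.
#'
#' @param p_change P-value cutoff for gained/lost/inducible/repressed calls.
#' @param p_constant P-value floor for constant/constitutive calls.
#' @param lfc_constant_band Absolute log2FC bound of the constant band.
#' @param lfc_loop_change Log2FC cutoff for gained/lost loops.
#' @param lfc_enhancer_change Log2FC cutoff for inducible/repressed
#'   enhancers.
#' @param rna_fdr Adjusted-p cutoff for differential expression.
#' @param rna_fc Fold-change cutoff for differential expression (e.g. 2.0
#'   for a stimulation contrast, 1.3 for a knockout contrast).
#' @return A named list of class `threshold_set`.
#' @export
threshold_set <- function(p_change = 0.1, p_constant = 0.5,
                          lfc_constant_band = log2(1.3),
                          lfc_loop_change = log2(1.5),
                          lfc_enhancer_change = log2(1.3),
                          rna_fdr = 0.05, rna_fc = 1.3) {
  structure(list(p_change = p_change, p_constant = p_constant,
                 lfc_constant_band = lfc_constant_band,
                 lfc_loop_change = lfc_loop_change,
                 lfc_enhancer_change = lfc_enhancer_change,
                 rna_fdr = rna_fdr, rna_fc = rna_fc),
            class = "threshold_set")
}

# median-of-ratios size factors; falls back to total-count ratios when
# geometric means vanish
estimate_size_factors <- function(cnt) {
  lg <- rowMeans(log(cnt))
  ok <- is.finite(lg)
  if (sum(ok) >= 5) {
    sf <- apply(cnt, 2, function(x) median(x[ok] / exp(lg[ok])))
  } else {
    tot <- colSums(cnt)
    sf <- tot / exp(mean(log(pmax(tot, 1))))
  }
  sf / exp(mean(log(sf)))
}

#' Negative-binomial Wald test between two replicate groups
#'
#' Counts are normalized by median-of-ratios size factors (total-count
#' fallback). Per-feature dispersion is moment-estimated from within-group
#' variances (floor 1e-4) and shrunk toward the pooled mean dispersion with
#' weight `shrink_weight`. The log2 fold-change (B over A) uses shrunken
#' group means with a 0.5-count pseudo-expectation; the two-sided p-value
#' comes from the Wald statistic against a standard normal. All-zero
#' features get log2FC 0, p 1, and a flag.
#'
#' @param counts_a,counts_b Non-negative count matrices (features x
#'   replicates, >= 2 replicates each) or vectors for a single feature.
#' @param size_factors Optional per-sample size factors (columns of A then
#'   B); estimated when `NULL`.
#' @param dispersion_floor Lower bound on the moment dispersion estimate.
#' @param shrink_weight Weight of the pooled-trend dispersion in the
#'   shrunken estimate (0 = per-feature only, 1 = pooled only). The default
#'   0.75 keeps the null tail calibrated at two replicates per group.
#' @return data.frame: feature_id, base_mean, log2fc, se, stat, p, all_zero.
#' @export
nb_wald <- function(counts_a, counts_b, size_factors = NULL,
                    dispersion_floor = 1e-4, shrink_weight = 0.75) {
  if (is.vector(counts_a)) counts_a <- matrix(counts_a, nrow = 1)
  if (is.vector(counts_b)) counts_b <- matrix(counts_b, nrow = 1)
  if (nrow(counts_a) != nrow(counts_b)) stop("feature sets must align")
  if (ncol(counts_a) < 2 || ncol(counts_b) < 2) {
    stop("at least 2 replicates per group are required")
  }
  if (any(counts_a < 0) || any(counts_b < 0)) {
    stop("counts must be non-negative")
  }
  cnt <- cbind(counts_a, counts_b)
  na <- ncol(counts_a); nb_ <- ncol(counts_b)
  sf <- if (is.null(size_factors)) estimate_size_factors(cnt) else size_factors
  if (length(sf) == 1) sf <- rep(sf, ncol(cnt))
  k <- sweep(cnt, 2, sf, "/")
  a <- k[, seq_len(na), drop = FALSE]
  b <- k[, na + seq_len(nb_), drop = FALSE]
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- apply(a, 1, var); v_b <- apply(b, 1, var)
  v_w <- ((na - 1) * v_a + (nb_ - 1) * v_b) / (na + nb_ - 2)
  mu <- rowMeans(k)
  raw <- (v_w - mu) / mu^2
  raw[!is.finite(raw)] <- dispersion_floor
  raw <- pmax(raw, dispersion_floor)
  trend <- mean(raw)
  disp <- (1 - shrink_weight) * raw + shrink_weight * trend
  lfc <- log2((m_b + 0.5) / (m_a + 0.5))
  v_log <- (1 + disp * m_a) / (na * (m_a + 0.5)) +
    (1 + disp * m_b) / (nb_ * (m_b + 0.5))
  se <- sqrt(v_log) / log(2)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  all_zero <- rowSums(cnt) == 0
  lfc[all_zero] <- 0; p[all_zero] <- 1; stat[all_zero] <- 0
  ids <- rownames(counts_a)
  if (is.null(ids)) ids <- sprintf("feature_%d", seq_len(nrow(cnt)))
  data.frame(feature_id = ids, base_mean = mu, log2fc = lfc, se = se,
             stat = stat, p = p, all_zero = all_zero, row.names = NULL)
}

#' Classify differential loop records
#'
#' Constant: `P > 0.5` and `|log2FC| < lfc_constant_band`. Gained / lost:
#' `P < 0.1` and `log2FC` above / below `+-lfc_loop_change`. Records meeting
#' neither rule are `unclassified`. The partition is exhaustive and
#' disjoint.
#'
#' @param records data.frame with columns `p` and `log2fc`.
#' @param thresholds A [threshold_set()].
#' @return `records` with an added `class` column.
#' @export
classify_loop_records <- function(records, thresholds = threshold_set()) {
  t <- thresholds
  cls <- rep("unclassified", nrow(records))
  cls[records$p > t$p_constant &
        abs(records$log2fc) < t$lfc_constant_band] <- "constant"
  cls[records$p < t$p_change & records$log2fc > t$lfc_loop_change] <- "gained"
  cls[records$p < t$p_change & records$log2fc < -t$lfc_loop_change] <- "lost"
  records$class <- cls
  records
}

#' Classify differential enhancer-anchor records
#'
#' Inducible / repressed: `P < 0.1` and `log2FC` above / below
#' `+-lfc_enhancer_change`. Constitutive: `P > 0.5` and
#' `|log2FC| < lfc_constant_band`. Others are `unclassified`.
#'
#' @inheritParams classify_loop_records
#' @return `records` with an added `class` column.
#' @export
classify_enhancer_records <- function(records, thresholds = threshold_set()) {
  t <- thresholds
  cls <- rep("unclassified", nrow(records))
  cls[records$p > t$p_constant &
        abs(records$log2fc) < t$lfc_constant_band] <- "constitutive"
  cls[records$p < t$p_change &
        records$log2fc > t$lfc_enhancer_change] <- "inducible"
  cls[records$p < t$p_change &
        records$log2fc < -t$lfc_enhancer_change] <- "repressed"
  records$class <- cls
  records
}

#' Sum peak signal within anchors
#'
#' The signal of an anchor is the sum of the signal of all peaks overlapping
#' its `bin_size` interval by >= 1 bp (0 when none). A peak straddling two
#' anchors contributes to both.
#'
#' @param anchors data.frame with chrom, bin.
#' @param peaks data.frame with chrom, start, end, signal.
#' @param bin_size Anchor width in bp.
#' @return Numeric vector of summed signal aligned with `anchors`.
#' @export
anchor_signal <- function(anchors, peaks, bin_size = 10000L) {
  out <- numeric(nrow(anchors))
  if (is.null(peaks) || nrow(peaks) == 0) return(out)
  gr <- anchors_to_granges(anchors$chrom, anchors$bin, bin_size)
  ov <- GenomicRanges::findOverlaps(gr, df_to_granges(peaks), minoverlap = 1L)
  if (length(ov)) {
    s <- tapply(peaks$signal[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), sum)
    out[as.integer(names(s))] <- as.numeric(s)
  }
  out
}

#' Differential expression with BH correction
#'
#' Runs the NB Wald engine gene-wise and adjusts p-values by
#' Benjamini-Hochberg. A gene is differentially expressed when
#' `padj < rna_fdr` and `|log2FC| > log2(rna_fc)`.
#'
#' @param count_matrix Integer matrix genes x samples with rownames.
#' @param group Character vector of per-column condition labels.
#' @param contrast Length-2 character vector (reference, treatment); the
#'   log2FC is treatment over reference.
#' @param thresholds A [threshold_set()].
#' @return data.frame: feature_id, base_mean, log2fc, se, stat, p, padj, de
#'   (logical), direction ("up"/"down"/"unchanged").
#' @export
differential_expression <- function(count_matrix, group,
                                    contrast = NULL,
                                    thresholds = threshold_set()) {
  if (is.null(contrast)) contrast <- unique(group)[1:2]
  a <- count_matrix[, group == contrast[1], drop = FALSE]
  b <- count_matrix[, group == contrast[2], drop = FALSE]
  res <- nb_wald(a, b)
  res$padj <- p.adjust(res$p, method = "BH")
  res$de <- res$padj < thresholds$rna_fdr &
    abs(res$log2fc) > log2(thresholds$rna_fc)
  res$direction <- ifelse(!res$de, "unchanged",
                          ifelse(res$log2fc > 0, "up", "down"))
  res
}
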