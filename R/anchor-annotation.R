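# Regulatory elements, super-enhancer stitching, anchor labels and loop
# classes. All interval work goes through GenomicRanges/IRanges; external
# coordinates are 0-based half-open.

#' Build regulatory elements from genes and peaks
#'
#' Promoters are TSS +/- 2.5 kb (`[tss - 2500, tss + 2500)`). Enhancers are
#' H3K27ac peaks that do not overlap any promoter by one or more bp.
#' Super-enhancers are stitched from the enhancer list (see
#' [stitch_super_enhancers()]).
#'
#' @param genes data.frame with gene_id, chrom, strand, tss (one TSS per
#'   gene). Genes with a missing TSS are skipped with a warning.
#' @param h3k27ac_peaks data.frame with chrom, start, end, name, signal.
#' @param ctcf_peaks data.frame with chrom, start, end (signal optional).
#' @param promoter_flank Promoter half-width in bp (default 2500).
#' @param stitch Super-enhancer stitching distance in bp (default 12.5 kb).
#' @return Object of class `regulatory_elements` with `promoters`,
#'   `enhancers`, `super_enhancers` (stitched regions with `se` flag),
#'   `ctcf_sites`.
#' @export
build_elements <- function(genes, h3k27ac_peaks, ctcf_peaks = NULL,
                           promoter_flank = 2500L, stitch = 12500L) {
  stop_if_not_df(genes, c("gene_id", "chrom", "tss"), "genes")
  bad <- is.na(genes$tss)
  if (any(bad)) {
    warning(sprintf("%d gene(s) without a TSS skipped", sum(bad)))
    genes <- genes[!bad, , drop = FALSE]
  }
  promoters <- data.frame(
    chrom = genes$chrom,
    start = pmax(0, genes$tss - promoter_flank),
    end = genes$tss + promoter_flank,
    gene_id = genes$gene_id)
  enhancers <- h3k27ac_peaks
  if (nrow(h3k27ac_peaks)) {
    ov <- IRanges::countOverlaps(df_to_granges(h3k27ac_peaks),
                                       df_to_granges(promoters),
                                       minoverlap = 1L)
    enhancers <- h3k27ac_peaks[ov == 0, , drop = FALSE]
  }
  enhancers <- enhancers[order(enhancers$chrom, enhancers$start), ]
  rownames(enhancers) <- NULL
  se <- stitch_super_enhancers(enhancers, stitch = stitch)
  structure(
    list(promoters = promoters, enhancers = enhancers,
         super_enhancers = se,
         ctcf_sites = if (is.null(ctcf_peaks)) {
           data.frame(chrom = character(), start = numeric(), end = numeric())
         } else ctcf_peaks),
    class = "regulatory_elements"
  )
}

#' Stitch enhancers into super-enhancer candidates
#'
#' Enhancers within the stitching distance are merged; stitched regions are
#' ranked by summed signal, both axes are scaled to `[0, 1]`, and the
#' super-enhancer cutoff is the signal at the rank where the scaled curve's
#' tangent slope reaches 1 (equivalently, the point of maximum gap below the
#' diagonal). Regions with signal above the cutoff are flagged.
#'
#' @param enhancers data.frame with chrom, start, end, signal.
#' @param stitch Maximum gap merged (bp; default 12.5 kb).
#' @return data.frame of stitched regions: chrom, start, end, n_peaks,
#'   signal, rank, se (logical). With fewer than 3 regions all are flagged
#'   non-SE with a warning.
#' @export
stitch_super_enhancers <- function(enhancers, stitch = 12500L) {
  if (nrow(enhancers) == 0) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_peaks = integer(),
                      signal = numeric(), rank = integer(), se = logical()))
  }
  gr <- df_to_granges(enhancers)
  red <- GenomicRanges::reduce(gr, min.gapwidth = stitch + 1L,
                               with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  signal <- vapply(revmap, function(ii) sum(enhancers$signal[ii]), numeric(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    n_peaks = lengths(revmap),
    signal = signal)
  n <- nrow(out)
  out$rank <- rank(out$signal, ties.method = "first")
  if (n < 3) {
    warning("fewer than 3 stitched regions; none flagged as super-enhancer")
    out$se <- FALSE
    return(out)
  }
  s <- sort(out$signal)
  if (max(s) == min(s)) {
    out$se <- FALSE
    return(out)
  }
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / (max(s) - min(s))
  cut_idx <- which.max(x - y)  # slope-1 tangent point of the scaled curve
  cutoff <- s[cut_idx]
  out$se <- out$signal > cutoff
  attr(out, "cutoff") <- cutoff
  out
}

#' Annotate loop anchors with regulatory-element labels
#'
#' Each anchor (a `bin_size` interval) receives exactly one label by the
#' precedence promoter > enhancer > ctcf > other, using >= 1 bp overlap.
#' Gene ids of promoters at the anchor and a super-enhancer flag are
#' attached.
#'
#' @param anchors data.frame with chrom, bin (1-based bin indices).
#' @param elements A [build_elements()] result.
#' @param bin_size Anchor width in bp (default 10 kb).
#' @return data.frame: chrom, bin, anchor_id, label, gene_ids
#'   (comma-separated, "" if none), se_flag.
#' @export
annotate_anchors <- function(anchors, elements, bin_size = 10000L) {
  stop_if_not_df(anchors, c("chrom", "bin"), "anchors")
  gr <- anchors_to_granges(anchors$chrom, anchors$bin, bin_size)
  hit_any <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(rep(FALSE, length(gr)))
    IRanges::overlapsAny(gr, df_to_granges(df), minoverlap = 1L)
  }
  has_prom <- hit_any(elements$promoters)
  has_enh <- hit_any(elements$enhancers)
  has_ctcf <- hit_any(elements$ctcf_sites)
  se_regions <- elements$super_enhancers
  has_se <- if (!is.null(se_regions) && nrow(se_regions)) {
    IRanges::overlapsAny(
      gr, df_to_granges(se_regions[se_regions$se, , drop = FALSE]),
      minoverlap = 1L)
  } else rep(FALSE, length(gr))
  label <- ifelse(has_prom, "promoter",
                  ifelse(has_enh, "enhancer",
                         ifelse(has_ctcf, "ctcf", "other")))
  gene_ids <- rep("", length(gr))
  if (nrow(elements$promoters)) {
    ov <- GenomicRanges::findOverlaps(gr, df_to_granges(elements$promoters),
                                      minoverlap = 1L)
    if (length(ov)) {
      ids <- tapply(elements$promoters$gene_id[S4Vectors::subjectHits(ov)],
                    S4Vectors::queryHits(ov),
                    function(g) paste(sort(unique(g)), collapse = ","))
      gene_ids[as.integer(names(ids))] <- as.character(ids)
    }
  }
  data.frame(chrom = anchors$chrom, bin = anchors$bin,
             anchor_id = anchor_key(anchors$chrom, anchors$bin),
             label = label, gene_ids = gene_ids, se_flag = has_se)
}

#' Classify loops by the element labels of their anchors
#'
#' The class is the unordered pair of anchor labels: `P-P`, `P-E`, `E-E`,
#' `P-CTCF`, `E-CTCF`, `CTCF-CTCF`, or `other-involving` when either anchor
#' is unlabeled.
#'
#' @param calls Loop data.frame with chrom, bin1, bin2.
#' @param annotations An [annotate_anchors()] result covering both anchors.
#' @return `calls` with an added `loop_class` column; attribute
#'   `class_table` tabulates classes (sums to `nrow(calls)`).
#' @export
classify_loops_by_anchors <- function(calls, annotations) {
  lab <- setNames(annotations$label, annotations$anchor_id)
  l1 <- lab[anchor_key(calls$chrom, calls$bin1)]
  l2 <- lab[anchor_key(calls$chrom, calls$bin2)]
  short <- c(promoter = "P", enhancer = "E", ctcf = "CTCF", other = "other")
  s1 <- short[l1]; s2 <- short[l2]
  cls <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    if (is.na(s1[i]) || is.na(s2[i]) || s1[i] == "other" || s2[i] == "other") {
      cls[i] <- "other-involving"
    } else {
      pr <- c(P = 1, E = 2, CTCF = 3)
      pair <- sort(c(pr[s1[i]], pr[s2[i]]))
      cls[i] <- paste(names(pr)[pair], collapse = "-")
    }
  }
  calls$loop_class <- cls
  attr(calls, "class_table") <- table(cls)
  calls
}
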