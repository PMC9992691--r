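# Regulatory-mode assignment, mode-vs-expression testing, cross-boundary
# loop analysis, loop-based TF target assignment, and region-set enrichment.

# (loop class, distal enhancer class) -> regulatory mode
mode_map <- function(loop_class, enh_class) {
  key <- paste(loop_class, enh_class, sep = "|")
  map <- c("gained|inducible" = "i",
           "constant|inducible" = "ii",
           "gained|constitutive" = "iii",
           "lost|constitutive" = "iv",
           "constant|repressed" = "v",
           "lost|repressed" = "vi",
           "constant|constitutive" = "control")
  out <- unname(map[key])
  out[is.na(out)] <- "unassigned"
  out
}

#' Assign regulatory modes to gene-loop-enhancer triplets
#'
#' A loop qualifies when one anchor is promoter-labeled and the other is
#' enhancer-labeled (the distal enhancer). The mode is determined by the
#' loop's differential class and the distal anchor's enhancer class:
#' (gained, inducible) is mode i; (constant, inducible) ii;
#' (gained, constitutive) iii; (lost, constitutive) iv;
#' (constant, repressed) v; (lost, repressed) vi;
#' (constant, constitutive) is the control wiring; anything else is
#' unassigned. Every gene at the promoter anchor yields one assignment per
#' qualifying loop, so a gene can carry several assignments.
#'
#' @param loop_records data.frame with chrom, bin1, bin2, and a loop `class`
#'   column (from [classify_loop_records()]); a `loop_id` column is used if
#'   present.
#' @param enhancer_classes data.frame with `anchor_id` and `class` (from
#'   [classify_enhancer_records()] on anchor signal).
#' @param annotations An [annotate_anchors()] result covering all loop
#'   anchors.
#' @return data.frame: gene_id, loop_id, distal_anchor_id, loop_class,
#'   enh_class, mode. Loops without a promoter anchor are skipped; attribute
#'   `n_skipped` counts them.
#' @export
assign_modes <- function(loop_records, enhancer_classes, annotations) {
  ann <- annotations
  lab <- setNames(ann$label, ann$anchor_id)
  genes <- setNames(ann$gene_ids, ann$anchor_id)
  ecls <- setNames(enhancer_classes$class, enhancer_classes$anchor_id)
  if (!"loop_id" %in% names(loop_records)) {
    loop_records$loop_id <- sprintf("loop_%05d", seq_len(nrow(loop_records)))
  }
  out <- vector("list", nrow(loop_records))
  n_skipped <- 0L
  for (i in seq_len(nrow(loop_records))) {
    a1 <- anchor_key(loop_records$chrom[i], loop_records$bin1[i])
    a2 <- anchor_key(loop_records$chrom[i], loop_records$bin2[i])
    l1 <- lab[[a1]]; l2 <- lab[[a2]]
    if (is.null(l1) || is.null(l2) || is.na(l1) || is.na(l2)) next
    if (l1 == "promoter" && l2 == "enhancer") {
      prom <- a1; dist <- a2
    } else if (l2 == "promoter" && l1 == "enhancer") {
      prom <- a2; dist <- a1
    } else {
      n_skipped <- n_skipped + 1L
      next
    }
    gids <- strsplit(genes[[prom]], ",", fixed = TRUE)[[1]]
    gids <- gids[nzchar(gids)]
    if (length(gids) == 0) { n_skipped <- n_skipped + 1L; next }
    ec <- ecls[[dist]]
    if (is.null(ec) || is.na(ec)) ec <- "unclassified"
    out[[i]] <- data.frame(
      gene_id = gids, loop_id = loop_records$loop_id[i],
      distal_anchor_id = dist, loop_class = loop_records$class[i],
      enh_class = ec, mode = mode_map(loop_records$class[i], ec))
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene_id = character(), loop_id = character(),
                      distal_anchor_id = character(),
                      loop_class = character(), enh_class = character(),
                      mode = character())
  }
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  res
}

#' Compare expression changes across regulatory modes
#'
#' For each mode i-vi the genes assigned to it (deduplicated within mode)
#' are compared with the control genes by a Welch two-sided t-test on RNA
#' log2 fold-changes.
#'
#' @param assignments An [assign_modes()] result.
#' @param de_records data.frame with `feature_id` and `log2fc` per gene
#'   (e.g. from [differential_expression()]).
#' @return data.frame: mode, n, mean_lfc, t, p (control row has `NA` t/p).
#' @export
mode_expression_test <- function(assignments, de_records) {
  lfc <- setNames(de_records$log2fc, de_records$feature_id)
  modes <- c("i", "ii", "iii", "iv", "v", "vi", "control")
  control_genes <- unique(assignments$gene_id[assignments$mode == "control"])
  ctrl_lfc <- lfc[intersect(control_genes, names(lfc))]
  rows <- lapply(modes, function(m) {
    g <- unique(assignments$gene_id[assignments$mode == m])
    v <- lfc[intersect(g, names(lfc))]
    if (m == "control" || length(v) < 2 || length(ctrl_lfc) < 2) {
      return(data.frame(mode = m, n = length(v),
                        mean_lfc = mean(v), t = NA_real_, p = NA_real_))
    }
    tt <- t.test(v, ctrl_lfc, alternative = "two.sided", var.equal = FALSE)
    data.frame(mode = m, n = length(v), mean_lfc = mean(v),
               t = unname(tt$statistic), p = tt$p.value)
  })
  do.call(rbind, rows)
}

#' Does a loop cross a TAD boundary?
#'
#' `TRUE` when some boundary bin `b` lies strictly between the anchors:
#' `bin1 < b < bin2`. A boundary inside an anchor bin does not separate the
#' anchors.
#'
#' @param loops data.frame with chrom, bin1, bin2.
#' @param boundaries data.frame with chrom, bin (e.g. WT boundary calls).
#' @return Logical vector aligned with `loops`.
#' @export
crosses_boundary <- function(loops, boundaries) {
  bnd <- lapply(split(boundaries$bin, boundaries$chrom), sort)
  vapply(seq_len(nrow(loops)), function(i) {
    b <- bnd[[loops$chrom[i]]]
    if (is.null(b)) return(FALSE)
    # boundaries strictly inside (bin1, bin2)
    sum(b <= loops$bin2[i] - 1L) - sum(b <= loops$bin1[i]) > 0L
  }, logical(1))
}

#' Cross-boundary report for gained loops
#'
#' Splits gained loops into those crossing a reference-condition boundary
#' and those contained within boundaries, and cross-tabulates the RNA
#' direction of their target genes (all genes at the promoter anchor).
#'
#' @param gained_loops data.frame with chrom, bin1, bin2 (gained loops).
#' @param boundaries Reference boundary calls (chrom, bin).
#' @param de_records [differential_expression()] output (needs feature_id,
#'   direction).
#' @param annotations [annotate_anchors()] output covering the loop anchors.
#' @return List: `fraction_across`, `n_across`, `n_within`, `gene_table`
#'   (category x up/down/unchanged counts), `loops` (input with `across`
#'   flag).
#' @export
boundary_crossing_report <- function(gained_loops, boundaries, de_records,
                                     annotations) {
  across <- crosses_boundary(gained_loops, boundaries)
  gained_loops$across <- across
  n_across <- sum(across); n_within <- sum(!across)
  frac <- if (n_across + n_within > 0) n_across / (n_across + n_within) else 0
  genes <- setNames(annotations$gene_ids, annotations$anchor_id)
  dirn <- setNames(de_records$direction, de_records$feature_id)
  tab <- lapply(c(across = TRUE, within = FALSE), function(fl) {
    sel <- gained_loops[gained_loops$across == fl, , drop = FALSE]
    g <- unlist(lapply(seq_len(nrow(sel)), function(i) {
      g1 <- genes[[anchor_key(sel$chrom[i], sel$bin1[i])]]
      g2 <- genes[[anchor_key(sel$chrom[i], sel$bin2[i])]]
      strsplit(paste(c(g1, g2), collapse = ","), ",", fixed = TRUE)[[1]]
    }))
    g <- unique(g[nzchar(g)])
    d <- dirn[intersect(g, names(dirn))]
    c(up = sum(d == "up"), down = sum(d == "down"),
      unchanged = sum(d == "unchanged"))
  })
  gene_table <- do.call(rbind, tab)
  list(fraction_across = frac, n_across = n_across, n_within = n_within,
       gene_table = gene_table, loops = gained_loops)
}

#' Assign TF target genes through loops
#'
#' A gene is `promoter_only` when a TF peak overlaps its promoter but no
#' loop connects its promoter anchor to a TF-bound enhancer anchor;
#' `promoter_and_distal` when both hold; `distal_only` when the promoter is
#' TF-free but at least one loop connects the gene's promoter anchor to a
#' TF-bound enhancer-labeled anchor.
#'
#' @param tf_peaks data.frame with chrom, start, end.
#' @param elements A [build_elements()] result.
#' @param loops Loop calls (chrom, bin1, bin2).
#' @param annotations [annotate_anchors()] output covering the loop anchors.
#' @param bin_size Anchor width in bp.
#' @return data.frame: gene_id, class (one row per gene with TF evidence).
#' @export
assign_tf_targets <- function(tf_peaks, elements, loops, annotations,
                              bin_size = 10000L) {
  prom_hit <- IRanges::overlapsAny(df_to_granges(elements$promoters),
                                         df_to_granges(tf_peaks),
                                         minoverlap = 1L)
  prom_genes <- unique(elements$promoters$gene_id[prom_hit])
  # TF-bound anchors
  ann <- annotations
  tf_anchor <- IRanges::overlapsAny(
    anchors_to_granges(ann$chrom, ann$bin, bin_size),
    df_to_granges(tf_peaks), minoverlap = 1L)
  tf_enh_anchor <- ann$anchor_id[tf_anchor & ann$label == "enhancer"]
  lab <- setNames(ann$label, ann$anchor_id)
  genes <- setNames(ann$gene_ids, ann$anchor_id)
  distal_genes <- character(0)
  for (i in seq_len(nrow(loops))) {
    a1 <- anchor_key(loops$chrom[i], loops$bin1[i])
    a2 <- anchor_key(loops$chrom[i], loops$bin2[i])
    for (pp in list(c(a1, a2), c(a2, a1))) {
      if (!is.na(lab[pp[1]]) && lab[pp[1]] == "promoter" &&
          pp[2] %in% tf_enh_anchor) {
        g <- strsplit(genes[[pp[1]]], ",", fixed = TRUE)[[1]]
        distal_genes <- c(distal_genes, g[nzchar(g)])
      }
    }
  }
  distal_genes <- unique(distal_genes)
  all_g <- union(prom_genes, distal_genes)
  if (length(all_g) == 0) {
    return(data.frame(gene_id = character(), class = character()))
  }
  cls <- ifelse(all_g %in% prom_genes & all_g %in% distal_genes,
                "promoter_and_distal",
                ifelse(all_g %in% prom_genes, "promoter_only", "distal_only"))
  data.frame(gene_id = sort(all_g),
             class = cls[order(all_g)], row.names = NULL)
}

#' Fisher region-set enrichment
#'
#' Builds the 2x2 table over universe regions (overlaps the reference
#' yes/no x in the query yes/no) and reports the one-sided (enrichment)
#' Fisher exact p-value, i.e. the hypergeometric upper-tail sum, and the
#' odds ratio with a Haldane 0.5 correction when any cell is zero. A query
#' covering the whole universe carries no contrast; its odds ratio is
#' reported as 1 (and p = 1).
#'
#' @param query_regions,reference_set,universe_regions data.frames with
#'   chrom, start, end (0-based half-open).
#' @return List: `odds_ratio`, `p`, `table` (2x2 counts a, b, c, d).
#' @export
region_set_enrichment <- function(query_regions, reference_set,
                                  universe_regions) {
  u <- df_to_granges(universe_regions)
  in_q <- IRanges::overlapsAny(u, df_to_granges(query_regions),
                                     minoverlap = 1L)
  in_r <- IRanges::overlapsAny(u, df_to_granges(reference_set),
                                     minoverlap = 1L)
  a <- sum(in_q & in_r); b <- sum(in_q & !in_r)
  c_ <- sum(!in_q & in_r); d <- sum(!in_q & !in_r)
  p <- fisher_tail_p(a, b, c_, d)
  if (c_ + d == 0) {
    or <- 1
  } else if (min(a, b, c_, d) == 0) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  } else {
    or <- (a * d) / (b * c_)
  }
  list(odds_ratio = or, p = p,
       table = matrix(c(a, b, c_, d), 2, 2, byrow = TRUE,
                      dimnames = list(c("query", "not_query"),
                                      c("ref", "not_ref"))))
}

#' One-sided Fisher exact (hypergeometric upper-tail) p-value
#'
#' `P(X >= a)` for the 2x2 table `(a, b, c, d)` under fixed margins --
#' the enrichment-side Fisher exact test.
#'
#' @param a,b,c_,d Cell counts: a = query & reference, b = query only,
#'   c_ = reference only, d = neither. Vectorized.
#' @return Numeric p-value(s).
#' @export
fisher_tail_p <- function(a, b, c_, d) {
  phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
}
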