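# Synthetic genome model and planted truth table.

#' Generate a synthetic genome model
#'
#' Places genes uniformly along each chromosome with a guaranteed minimum
#' spacing, keeping a margin from the chromosome ends so that distal loop
#' anchors and insulation windows always fit.
#'
#' @param n_chroms Number of chromosomes.
#' @param chrom_length Chromosome length in bp (>= 5 Mb).
#' @param n_genes Total number of genes.
#' @param bin_size Bin width in bp (default 10 kb).
#' @param min_spacing Minimum TSS-to-TSS spacing in bp (default 30 kb).
#' @param edge_margin Gene-free margin at each chromosome end (bp).
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @return Object of class `genome_model`: `chroms` (chrom, length),
#'   `bin_size`, `genes` (gene_id, chrom, strand, tss).
#' @export
generate_genome <- function(n_chroms = 1L, chrom_length = 30e6,
                            n_genes = 100L, bin_size = 10000L,
                            min_spacing = 30000L, edge_margin = 500000L,
                            seed = 1L) {
  if (chrom_length < 5e6) stop("chrom_length must be at least 5 Mb")
  if (n_genes < 1) stop("n_genes must be at least 1")
  chroms <- sprintf("chr%d", seq_len(n_chroms))
  per <- rep(n_genes %/% n_chroms, n_chroms)
  if (n_genes %% n_chroms > 0) {
    per[seq_len(n_genes %% n_chroms)] <- per[seq_len(n_genes %% n_chroms)] + 1L
  }
  usable <- chrom_length - 2 * edge_margin
  if (any(per * min_spacing > usable)) {
    stop(sprintf(
      "cannot place %d genes with %d bp spacing in %.3g bp of usable sequence",
      max(per), min_spacing, usable))
  }
  genes <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_chroms), function(ci) {
      n <- per[ci]
      slack <- usable - n * min_spacing
      pos <- edge_margin + sort(runif(n, 0, slack)) +
        (seq_len(n) - 1) * min_spacing + min_spacing / 2
      data.frame(chrom = chroms[ci],
                 strand = sample(c("+", "-"), n, replace = TRUE),
                 tss = round(pos))
    }))
  })
  genes <- genes[order(genes$chrom, genes$tss), ]
  genes$gene_id <- sprintf("gene_%04d", seq_len(nrow(genes)))
  genes <- genes[, c("gene_id", "chrom", "strand", "tss")]
  rownames(genes) <- NULL
  structure(
    list(chroms = data.frame(chrom = chroms, length = chrom_length),
         bin_size = as.integer(bin_size), genes = genes),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("<genome_model> %d chrom(s) x %.3g bp, %d genes, %d bp bins\n",
              nrow(x$chroms), x$chroms$length[1], nrow(x$genes), x$bin_size))
  invisible(x)
}

# mode -> (loop class, distal enhancer class) wiring
mode_wiring <- function() {
  data.frame(
    mode = c("i", "ii", "iii", "iv", "v", "vi", "control"),
    loop_class = c("gained", "constant", "gained", "lost", "constant",
                   "lost", "constant"),
    enh_class = c("inducible", "inducible", "constitutive", "constitutive",
                  "repressed", "repressed", "constitutive"),
    stringsAsFactors = FALSE
  )
}

#' Plant a ground-truth table on a genome
#'
#' Wires genes into the six regulatory modes (plus a control set), placing
#' for each wired gene one loop from its TSS anchor to a distal enhancer
#' anchor, with per-condition loop-strength multipliers and enhancer signal
#' ratios chosen by the mode's loop/enhancer classes. TAD boundaries are
#' planted evenly along each chromosome; a configurable fraction of
#' gained-class loops is deliberately placed across a boundary by assigning
#' gained modes preferentially to genes near boundaries. Extra unwired loops
#' (for caller recovery experiments), stand-alone enhancers, super-enhancer
#' clusters, CTCF sites at boundaries, and TF binding flags complete the
#' truth.
#'
#' @param genome A [generate_genome()] result.
#' @param n_boundaries Planted boundaries per chromosome.
#' @param genes_per_mode Genes planted in each of modes i-vi.
#' @param n_control_genes Genes planted as (constant loop, constitutive
#'   enhancer) controls.
#' @param n_extra_loops Additional unwired constant loops.
#' @param n_extra_enhancers Stand-alone constitutive enhancers.
#' @param n_se_clusters Clusters of 5 strong enhancers within stitching
#'   distance (planted super-enhancers).
#' @param loop_base_strength Planted loop enrichment over matched-distance
#'   background.
#' @param gained_multiplier Condition multiplier for gained loops (lost loops
#'   use its reciprocal).
#' @param inducible_ratio Enhancer signal ratio for inducible enhancers
#'   (repressed use the reciprocal).
#' @param mode_log2fc Named planted RNA log2 fold-changes per mode.
#' @param enhancer_mean_signal Baseline enhancer signal (expected tag count).
#' @param span_range Loop span range in bp (log-uniform sampling).
#' @param cross_boundary_fraction Target fraction of gained loops placed
#'   across a planted boundary.
#' @param tf_enhancer_prob,tf_promoter_prob Probability that an enhancer /
#'   a wired gene promoter is TF-bound.
#' @param conditions Two condition labels, reference first.
#' @param seed Integer seed.
#' @return Object of class `truth_table` with `boundaries`, `loops`,
#'   `enhancers`, `gene_modes`, `ctcf_sites`, `conditions`, `params`.
#' @export
generate_truth <- function(genome, n_boundaries = 5L, genes_per_mode = 10L,
                           n_control_genes = 40L, n_extra_loops = 0L,
                           n_extra_enhancers = 20L, n_se_clusters = 2L,
                           loop_base_strength = 10, gained_multiplier = 4,
                           inducible_ratio = 4,
                           mode_log2fc = c(i = 1.5, ii = 1.0, iii = 0.8,
                                           iv = -0.8, v = -1.0, vi = -1.5),
                           enhancer_mean_signal = 200,
                           span_range = c(40000, 200000),
                           cross_boundary_fraction = 1 / 3,
                           tf_enhancer_prob = 0.5, tf_promoter_prob = 0.3,
                           conditions = c("ctrl", "stim"), seed = 1L) {
  bs <- genome$bin_size
  wiring <- mode_wiring()
  modes <- c("i", "ii", "iii", "iv", "v", "vi")
  n_wired <- genes_per_mode * length(modes) + n_control_genes
  if (n_wired > nrow(genome$genes)) {
    stop("not enough genes in the genome for the requested wiring")
  }
  withr::with_seed(seed, {
    # --- boundaries, evenly spaced, away from the ends
    boundaries <- if (n_boundaries > 0) {
      do.call(rbind, lapply(seq_len(nrow(genome$chroms)), function(ci) {
        nb <- n_bins(genome$chroms$length[ci], bs)
        data.frame(chrom = genome$chroms$chrom[ci],
                   bin = as.integer(round(nb * seq_len(n_boundaries) /
                                            (n_boundaries + 1))),
                   present_in = "both")
      }))
    } else {
      data.frame(chrom = character(), bin = integer(),
                 present_in = character())
    }

    genes <- genome$genes
    genes$tss_bin <- pos_to_bin(genes$tss, bs)
    bnd_by_chrom <- split(boundaries$bin, boundaries$chrom)
    nearest_bnd_dist <- vapply(seq_len(nrow(genes)), function(i) {
      b <- bnd_by_chrom[[genes$chrom[i]]]
      if (is.null(b) || !length(b)) return(Inf)
      min(abs(b - genes$tss_bin[i]))
    }, numeric(1))

    d_min <- max(4L, as.integer(round(span_range[1] / bs)))
    d_max <- as.integer(round(span_range[2] / bs))

    # --- assign modes to genes; gained modes preferentially near boundaries
    n_gained <- 2L * genes_per_mode  # modes i and iii
    n_cross <- min(round(cross_boundary_fraction * n_gained),
                   sum(nearest_bnd_dist >= 6 & nearest_bnd_dist <= d_max - 2))
    eligible <- which(nearest_bnd_dist >= 6 & nearest_bnd_dist <= d_max - 2)
    cross_genes <- if (n_cross > 0) sample(eligible, n_cross) else integer(0)
    rest <- setdiff(seq_len(nrow(genes)), cross_genes)
    rest <- sample(rest, n_wired - n_cross)
    mode_of <- rep(NA_character_, nrow(genes))
    gained_slots <- rep(c("i", "iii"), each = genes_per_mode)
    other_slots <- c(rep(c("ii", "iv", "v", "vi"), each = genes_per_mode),
                     rep("control", n_control_genes))
    mode_of[cross_genes] <- gained_slots[seq_along(cross_genes)]
    pool <- c(if (n_cross < n_gained) gained_slots[(n_cross + 1):n_gained],
              other_slots)
    mode_of[rest] <- sample(pool)

    # --- place one loop + distal enhancer per wired gene
    loops <- list(); enhancers <- list()
    enh_id <- 0L
    tss_all <- split(genes$tss, genes$chrom)
    for (gi in which(!is.na(mode_of))) {
      g <- genes[gi, ]
      m <- mode_of[gi]
      w <- wiring[wiring$mode == m, ]
      chrom_len <- genome$chroms$length[genome$chroms$chrom == g$chrom]
      nb <- n_bins(chrom_len, bs)
      bnd <- bnd_by_chrom[[g$chrom]]
      force_cross <- gi %in% cross_genes && w$loop_class == "gained"
      placed <- FALSE
      for (try in seq_len(60)) {
        if (force_cross && try <= 30) {
          bsel <- bnd[which.min(abs(bnd - g$tss_bin))]
          dir <- sign(bsel - g$tss_bin); if (dir == 0) dir <- 1
          gap <- abs(bsel - g$tss_bin)
          d <- min(d_max, gap + sample(2:6, 1))
          if (d < d_min) d <- d_min
        } else {
          d <- as.integer(round(exp(runif(1, log(d_min), log(d_max)))))
          dir <- sample(c(-1L, 1L), 1)
        }
        distal <- g$tss_bin + dir * d
        if (distal < 2L || distal > nb - 1L) { distal <- g$tss_bin - dir * d }
        if (distal < 2L || distal > nb - 1L) next
        e_start <- bin_start(distal, bs) + bs / 2 - 1000
        e_end <- e_start + 2000
        # distal anchor must stay clear of every promoter (+-2.5 kb)
        tvec <- tss_all[[g$chrom]]
        anchor_lo <- bin_start(distal, bs); anchor_hi <- anchor_lo + bs
        if (any(tvec + 2500 > anchor_lo & tvec - 2500 < anchor_hi)) next
        placed <- TRUE
        break
      }
      if (!placed) {
        stop(sprintf("could not place a distal enhancer for gene %s",
                     g$gene_id))
      }
      enh_id <- enh_id + 1L
      b1 <- min(g$tss_bin, distal); b2 <- max(g$tss_bin, distal)
      mult <- switch(w$loop_class,
        gained = c(1, gained_multiplier),
        lost = c(1, 1 / gained_multiplier),
        constant = c(1, 1))
      sig <- switch(w$enh_class,
        inducible = c(1, inducible_ratio),
        repressed = c(1, 1 / inducible_ratio),
        constitutive = c(1, 1)) * enhancer_mean_signal
      crosses <- !is.null(bnd) && any(bnd > b1 & bnd < b2)
      loops[[length(loops) + 1L]] <- data.frame(
        chrom = g$chrom, bin1 = b1, bin2 = b2, span = (b2 - b1) * bs,
        base_strength = loop_base_strength,
        mult_a = mult[1], mult_b = mult[2], class = w$loop_class,
        gene_id = g$gene_id, enh_id = sprintf("enh_%04d", enh_id),
        crosses_boundary = crosses)
      enhancers[[length(enhancers) + 1L]] <- data.frame(
        enh_id = sprintf("enh_%04d", enh_id), chrom = g$chrom,
        start = e_start, end = e_end, class = w$enh_class,
        signal_a = sig[1], signal_b = sig[2],
        tf_bound = runif(1) < tf_enhancer_prob, se_cluster = NA_character_)
    }

    # --- extra unwired loops (constant class)
    for (k in seq_len(n_extra_loops)) {
      ci <- sample(nrow(genome$chroms), 1)
      chrom <- genome$chroms$chrom[ci]
      nb <- n_bins(genome$chroms$length[ci], bs)
      d <- as.integer(round(exp(runif(1, log(d_min), log(d_max)))))
      b1 <- sample(seq.int(10L, nb - d - 10L), 1)
      b2 <- b1 + d
      bnd <- bnd_by_chrom[[chrom]]
      loops[[length(loops) + 1L]] <- data.frame(
        chrom = chrom, bin1 = b1, bin2 = b2, span = d * bs,
        base_strength = loop_base_strength, mult_a = 1, mult_b = 1,
        class = "constant", gene_id = NA_character_,
        enh_id = NA_character_,
        crosses_boundary = !is.null(bnd) && any(bnd > b1 & bnd < b2))
    }

    # --- stand-alone enhancers and super-enhancer clusters
    place_clear <- function(chrom, width) {
      chrom_len <- genome$chroms$length[genome$chroms$chrom == chrom]
      tvec <- tss_all[[chrom]]
      for (try in seq_len(200)) {
        s <- round(runif(1, 6e5, chrom_len - 6e5 - width))
        if (!any(tvec + 2500 > s - 1000 & tvec - 2500 < s + width + 1000)) {
          return(s)
        }
      }
      stop("could not place a stand-alone enhancer clear of promoters")
    }
    for (k in seq_len(n_extra_enhancers)) {
      chrom <- sample(genome$chroms$chrom, 1)
      s <- place_clear(chrom, 2000)
      enh_id <- enh_id + 1L
      enhancers[[length(enhancers) + 1L]] <- data.frame(
        enh_id = sprintf("enh_%04d", enh_id), chrom = chrom,
        start = s, end = s + 2000, class = "constitutive",
        signal_a = enhancer_mean_signal, signal_b = enhancer_mean_signal,
        tf_bound = runif(1) < tf_enhancer_prob, se_cluster = NA_character_)
    }
    for (k in seq_len(n_se_clusters)) {
      chrom <- sample(genome$chroms$chrom, 1)
      s <- place_clear(chrom, 5 * 2000 + 4 * 8000)
      for (j in seq_len(5)) {
        enh_id <- enh_id + 1L
        st <- s + (j - 1) * 10000  # 2 kb peaks, 8 kb gaps (< 12.5 kb stitch)
        enhancers[[length(enhancers) + 1L]] <- data.frame(
          enh_id = sprintf("enh_%04d", enh_id), chrom = chrom,
          start = st, end = st + 2000, class = "constitutive",
          signal_a = 5 * enhancer_mean_signal,
          signal_b = 5 * enhancer_mean_signal,
          tf_bound = FALSE, se_cluster = sprintf("se_%02d", k))
      }
    }

    loops <- if (length(loops)) do.call(rbind, loops) else
      data.frame(chrom = character(), bin1 = integer(), bin2 = integer(),
                 span = numeric(), base_strength = numeric(),
                 mult_a = numeric(), mult_b = numeric(), class = character(),
                 gene_id = character(), enh_id = character(),
                 crosses_boundary = logical())
    loops$loop_id <- if (nrow(loops)) sprintf("loop_%04d", seq_len(nrow(loops))) else character(0)
    enhancers <- if (length(enhancers)) do.call(rbind, enhancers) else
      data.frame(enh_id = character(), chrom = character(),
                 start = numeric(), end = numeric(), class = character(),
                 signal_a = numeric(), signal_b = numeric(),
                 tf_bound = logical(), se_cluster = character())
    names(loops)[names(loops) == "mult_a"] <- paste0("mult_", conditions[1])
    names(loops)[names(loops) == "mult_b"] <- paste0("mult_", conditions[2])
    names(enhancers)[names(enhancers) == "signal_a"] <-
      paste0("signal_", conditions[1])
    names(enhancers)[names(enhancers) == "signal_b"] <-
      paste0("signal_", conditions[2])

    gene_modes <- data.frame(
      gene_id = genes$gene_id,
      mode = ifelse(is.na(mode_of), "none", mode_of),
      planted_log2fc = 0,
      tf_promoter = FALSE)
    for (m in names(mode_log2fc)) {
      gene_modes$planted_log2fc[gene_modes$mode == m] <- mode_log2fc[[m]]
    }
    wired <- gene_modes$mode != "none"
    gene_modes$tf_promoter[wired] <-
      runif(sum(wired)) < tf_promoter_prob

    ctcf <- data.frame(
      chrom = boundaries$chrom,
      start = bin_start(boundaries$bin, bs) + bs / 2 - 500,
      end = bin_start(boundaries$bin, bs) + bs / 2 + 500)

    structure(
      list(boundaries = boundaries, loops = loops, enhancers = enhancers,
           gene_modes = gene_modes, ctcf_sites = ctcf,
           conditions = conditions,
           params = list(loop_base_strength = loop_base_strength,
                         gained_multiplier = gained_multiplier,
                         inducible_ratio = inducible_ratio,
                         enhancer_mean_signal = enhancer_mean_signal,
                         span_range = span_range, seed = seed)),
      class = "truth_table"
    )
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf(
    "<truth_table> %d boundaries, %d loops, %d enhancers, %d wired genes\n",
    nrow(x$boundaries), nrow(x$loops), nrow(x$enhancers),
    sum(x$gene_modes$mode != "none")))
  invisible(x)
}
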