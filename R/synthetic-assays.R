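# Synthetic Hi-C matrices, HiChIP replicate counts, ChIP peaks and RNA
# counts, all driven by a planted truth table.

#' Simulate a binned Hi-C contact matrix
#'
#' Expected counts follow a power-law distance decay
#' `depth * max(d, 0.5)^decay_exponent` (d in bins); bin pairs inside the
#' same planted TAD block are multiplied by `tad_enrichment`, and an
#' optional A/B compartment profile adds a checkerboard factor
#' `1 + compartment_strength * s_i * s_j`. Counts are Poisson-sampled
#' (symmetric, integer) unless `noise = "none"`.
#'
#' @param genome A [generate_genome()] result (single chromosome is
#'   simulated per call; `chrom` selects which).
#' @param boundaries Integer vector of boundary bin indices (1-based).
#' @param decay_exponent Distance-decay exponent (< 0; default -1).
#' @param tad_enrichment Within-TAD contact multiplier (> 1).
#' @param depth Expected count at one-bin distance.
#' @param noise `"poisson"` or `"none"` (expected values, real-valued).
#' @param compartment_profile Optional per-bin vector in `{-1, +1}`.
#' @param compartment_strength Checkerboard amplitude (default 0.3).
#' @param chrom Chromosome to simulate (default the first).
#' @param seed Integer seed.
#' @return A [contact_matrix()].
#' @export
generate_hic <- function(genome, boundaries, decay_exponent = -1,
                         tad_enrichment = 3, depth = 100,
                         noise = c("poisson", "none"),
                         compartment_profile = NULL,
                         compartment_strength = 0.3,
                         chrom = genome$chroms$chrom[1], seed = 1L) {
  noise <- match.arg(noise)
  if (decay_exponent >= 0) stop("decay_exponent must be negative")
  if (tad_enrichment <= 1) stop("tad_enrichment must be greater than 1")
  len <- genome$chroms$length[genome$chroms$chrom == chrom]
  nb <- n_bins(len, genome$bin_size)
  boundaries <- as.integer(boundaries)
  if (length(boundaries) && (min(boundaries) < 1 || max(boundaries) > nb)) {
    stop("boundary bin index out of range")
  }
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  expected <- depth * pmax(d, 0.5)^decay_exponent
  if (length(boundaries)) {
    block <- findInterval(seq_len(nb), sort(boundaries) + 0.5)
    same <- outer(block, block, "==")
    expected[same] <- expected[same] * tad_enrichment
  }
  if (!is.null(compartment_profile)) {
    s <- compartment_profile
    if (length(s) != nb) stop("compartment_profile must have one value per bin")
    expected <- expected * (1 + compartment_strength * outer(s, s))
  }
  counts <- if (noise == "poisson") {
    withr::with_seed(seed, {
      up <- upper.tri(expected, diag = TRUE)
      x <- matrix(0, nb, nb)
      x[up] <- rpois(sum(up), expected[up])
      x + t(x) - diag(diag(x))
    })
  } else {
    expected
  }
  contact_matrix(counts, chrom, genome$bin_size)
}

# all intra-chromosomal bin pairs with spans in [min_span, max_span]
all_bin_pairs <- function(genome, min_span, max_span) {
  bs <- genome$bin_size
  d_lo <- as.integer(ceiling(min_span / bs))
  d_hi <- as.integer(floor(max_span / bs))
  do.call(rbind, lapply(seq_len(nrow(genome$chroms)), function(ci) {
    nb <- n_bins(genome$chroms$length[ci], bs)
    dd <- seq.int(d_lo, min(d_hi, nb - 1L))
    do.call(rbind, lapply(dd, function(d) {
      b1 <- seq_len(nb - d)
      data.frame(chrom = genome$chroms$chrom[ci], bin1 = b1, bin2 = b1 + d)
    }))
  }))
}

#' Simulate HiChIP replicate contact counts
#'
#' Background counts decay with distance and are modulated by a
#' multiplicative per-anchor coverage bias (log-normal, shared across
#' replicates and conditions). Planted loops multiply the background mean by
#' `base_strength` times the per-condition multiplier from the truth table.
#' Counts are negative-binomial with the given dispersion.
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [generate_truth()] result; every planted loop span must
#'   lie in `[min_span, max_span]` or an error is raised.
#' @param n_replicates Replicates per condition (>= 2).
#' @param library_size Expected total background contacts per replicate (default 1e6, chosen so a 10x-enriched loop is detectable across the whole span range).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param bias_sd Standard deviation of the log-normal anchor bias.
#' @param min_span,max_span Span range of simulated bin pairs (bp).
#' @param seed Integer seed.
#' @return Object of class `hichip_sim`: `pairs` (chrom, bin1, bin2, span),
#'   `counts` (list per condition of integer matrices, one column per
#'   replicate), `bias` (per-anchor), `conditions`, `truth_idx` (row index
#'   into `pairs` for each planted loop).
#' @export
generate_hichip <- function(genome, truth, n_replicates = 2L,
                            library_size = 1e6, dispersion = 0.1,
                            bias_sd = 0.25, min_span = 20000L,
                            max_span = 2000000L, seed = 1L) {
  if (n_replicates < 2) stop("at least 2 replicates per condition required")
  bs <- genome$bin_size
  loops <- truth$loops
  if (any(loops$span < min_span | loops$span > max_span)) {
    stop("planted loop span outside the [min_span, max_span] range")
  }
  conditions <- truth$conditions
  pairs <- all_bin_pairs(genome, min_span, max_span)
  pairs$span <- (pairs$bin2 - pairs$bin1) * bs
  d <- pairs$bin2 - pairs$bin1
  base <- d^-1
  base <- base * library_size / sum(base)

  withr::with_seed(seed, {
    keys <- unique(c(anchor_key(pairs$chrom, pairs$bin1),
                     anchor_key(pairs$chrom, pairs$bin2)))
    bias <- setNames(rlnorm(length(keys), 0, bias_sd), keys)
    b1 <- bias[anchor_key(pairs$chrom, pairs$bin1)]
    b2 <- bias[anchor_key(pairs$chrom, pairs$bin2)]
    mu0 <- base * b1 * b2

    key_pairs <- paste(pairs$chrom, pairs$bin1, pairs$bin2)
    truth_idx <- match(paste(loops$chrom, loops$bin1, loops$bin2), key_pairs)
    if (anyNA(truth_idx)) stop("planted loop outside the simulated pair set")

    counts <- lapply(conditions, function(cond) {
      mult <- rep(1, nrow(pairs))
      mult[truth_idx] <- loops$base_strength *
        loops[[paste0("mult_", cond)]]
      mu <- mu0 * mult
      mat <- vapply(seq_len(n_replicates), function(r) {
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
      }, numeric(nrow(pairs)))
      colnames(mat) <- sprintf("%s_rep%d", cond, seq_len(n_replicates))
      storage.mode(mat) <- "integer"
      mat
    })
    names(counts) <- conditions

    structure(
      list(pairs = pairs, counts = counts, bias = bias,
           conditions = conditions, truth_idx = truth_idx,
           bin_size = bs,
           params = list(n_replicates = n_replicates,
                         library_size = library_size,
                         dispersion = dispersion, bias_sd = bias_sd,
                         min_span = min_span, max_span = max_span,
                         seed = seed)),
      class = "hichip_sim"
    )
  })
}

#' @export
print.hichip_sim <- function(x, ...) {
  cat(sprintf(
    "<hichip_sim> %d bin pairs, %d planted loops, %s x %d replicates\n",
    nrow(x$pairs), length(x$truth_idx),
    paste(x$conditions, collapse = "/"), x$params$n_replicates))
  invisible(x)
}

#' Simulate condition-specific ChIP peaks
#'
#' Emits H3K27ac peaks (planted enhancers plus promoter peaks at wired
#' genes), CTCF peaks at planted boundaries, and TF peaks at TF-bound
#' enhancers/promoters. Peak signal is an NB draw around the truth table's
#' per-condition mean, so replicate peak sets are obtained by calling with
#' per-replicate seeds.
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [generate_truth()] result.
#' @param condition One of `truth$conditions`.
#' @param dispersion NB dispersion of peak signal.
#' @param promoter_signal Expected H3K27ac signal at wired-gene promoters.
#' @param ctcf_signal,tf_signal Expected CTCF / TF peak signals.
#' @param seed Integer seed.
#' @return List of sorted data.frames (`h3k27ac`, `ctcf`, `tf`), each with
#'   columns chrom, start, end, name, signal (0-based half-open intervals,
#'   non-negative signal).
#' @export
generate_peaks <- function(genome, truth, condition, dispersion = 0.1,
                           promoter_signal = 300, ctcf_signal = 150,
                           tf_signal = 100, seed = 1L) {
  if (!condition %in% truth$conditions) {
    stop("condition must be one of the truth table's conditions")
  }
  sigcol <- paste0("signal_", condition)
  withr::with_seed(seed, {
    enh <- truth$enhancers
    h3k <- data.frame(chrom = enh$chrom, start = enh$start, end = enh$end,
                      name = enh$enh_id,
                      signal = rnbinom(nrow(enh), mu = enh[[sigcol]],
                                       size = 1 / dispersion))
    wired <- truth$gene_modes$gene_id[truth$gene_modes$mode != "none"]
    gw <- genome$genes[genome$genes$gene_id %in% wired, ]
    prom <- data.frame(chrom = gw$chrom, start = pmax(0, gw$tss - 1000),
                       end = gw$tss + 1000,
                       name = paste0(gw$gene_id, "_prom"),
                       signal = rnbinom(nrow(gw), mu = promoter_signal,
                                        size = 1 / dispersion))
    h3k <- rbind(h3k, prom)
    ctcf <- data.frame(chrom = truth$ctcf_sites$chrom,
                       start = truth$ctcf_sites$start,
                       end = truth$ctcf_sites$end,
                       name = sprintf("ctcf_%03d", seq_len(nrow(truth$ctcf_sites))),
                       signal = rnbinom(nrow(truth$ctcf_sites),
                                        mu = ctcf_signal, size = 1 / dispersion))
    tf_e <- enh[enh$tf_bound, ]
    gm <- truth$gene_modes[truth$gene_modes$tf_promoter, ]
    gtf <- genome$genes[genome$genes$gene_id %in% gm$gene_id, ]
    tf <- rbind(
      data.frame(chrom = tf_e$chrom, start = tf_e$start, end = tf_e$end,
                 name = paste0(tf_e$enh_id, "_tf"), signal = NA_real_),
      data.frame(chrom = gtf$chrom, start = pmax(0, gtf$tss - 500),
                 end = gtf$tss + 500, name = paste0(gtf$gene_id, "_tf"),
                 signal = NA_real_))
    tf$signal <- rnbinom(nrow(tf), mu = tf_signal, size = 1 / dispersion)
    sort_bed <- function(df) {
      df <- df[order(df$chrom, df$start, df$end), ]
      rownames(df) <- NULL
      df
    }
    list(h3k27ac = sort_bed(h3k), ctcf = sort_bed(ctcf), tf = sort_bed(tf))
  })
}

#' Simulate replicate gene counts
#'
#' Gene baselines are log-normal around `base_mean`; the planted per-gene
#' log2 fold-change from the truth table is applied to the second condition.
#' Counts are NB with the given dispersion.
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [generate_truth()] result.
#' @param n_replicates Replicates per condition.
#' @param base_mean Median baseline expression (expected counts).
#' @param base_sdlog Log-normal sd of gene baselines.
#' @param dispersion NB dispersion.
#' @param seed Integer seed.
#' @return Integer matrix genes x samples with columns
#'   `<condition>_rep<k>`; attribute `conditions` gives the column grouping.
#' @export
generate_rna_counts <- function(genome, truth, n_replicates = 3L,
                                base_mean = 200, base_sdlog = 0.5,
                                dispersion = 0.1, seed = 1L) {
  conditions <- truth$conditions
  gm <- truth$gene_modes[match(genome$genes$gene_id, truth$gene_modes$gene_id), ]
  withr::with_seed(seed, {
    base <- rlnorm(nrow(gm), log(base_mean), base_sdlog)
    mu <- cbind(base, base * 2^gm$planted_log2fc)
    colnames(mu) <- conditions
    cols <- unlist(lapply(conditions, function(cond) {
      sprintf("%s_rep%d", cond, seq_len(n_replicates))
    }))
    mat <- matrix(0L, nrow(gm), length(cols),
                  dimnames = list(gm$gene_id, cols))
    for (ci in seq_along(conditions)) {
      for (r in seq_len(n_replicates)) {
        mat[, (ci - 1) * n_replicates + r] <-
          rnbinom(nrow(gm), mu = mu[, ci], size = 1 / dispersion)
      }
    }
    attr(mat, "conditions") <- rep(conditions, each = n_replicates)
    mat
  })
}
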