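# HiChIP loop significance: coverage-bias correction, distance-stratified
# background, NB upper-tail p-values, BH control.

#' Estimate a distance-stratified HiChIP background
#'
#' The expected count of a bin pair is `stratum_mean(d) * b1 * b2`, where
#' the anchor bias `b` is the anchor's marginal coverage divided by the mean
#' marginal, and strata are logarithmic distance bins (merged forward until
#' each holds at least `min_stratum_n` pairs). Stratum means are fitted so
#' the expected total equals the observed total within each stratum. Each
#' stratum also carries a moment-estimated overdispersion
#' `alpha = max(0, sum((x - mu)^2 - mu) / sum(mu^2))`, used by
#' [call_loops()] for a negative-binomial tail (alpha = 0 reduces to
#' Poisson).
#'
#' @param pairs data.frame with chrom, bin1, bin2.
#' @param counts Numeric vector of counts (one per pair), or a matrix whose
#'   rows are summed.
#' @param bin_size Bin width in bp.
#' @param strata_per_decade Number of logarithmic distance strata per decade.
#' @param min_stratum_n Minimum pairs per stratum after merging.
#' @return Object of class `hichip_background`: `strata` (d range, mean,
#'   alpha, n), `bias` (named per anchor), `expected` and `alpha` aligned
#'   with `pairs`.
#' @export
estimate_background <- function(pairs, counts, bin_size = 10000L,
                                strata_per_decade = 20L, min_stratum_n = 50L) {
  stop_if_not_df(pairs, c("chrom", "bin1", "bin2"), "pairs")
  if (is.matrix(counts)) counts <- rowSums(counts)
  if (length(counts) != nrow(pairs)) {
    stop("counts must align with pairs")
  }
  k1 <- anchor_key(pairs$chrom, pairs$bin1)
  k2 <- anchor_key(pairs$chrom, pairs$bin2)
  ak <- c(k1, k2)
  marg <- tapply(c(counts, counts), ak, sum)

  d_bp <- (pairs$bin2 - pairs$bin1) * bin_size
  lo <- log10(min(d_bp)); hi <- log10(max(d_bp))
  breaks <- 10^seq(lo, hi + 1e-9, by = 1 / strata_per_decade)
  breaks[1] <- min(d_bp) - 1
  breaks[length(breaks)] <- max(d_bp) + 1
  stratum <- findInterval(d_bp, breaks, rightmost.closed = TRUE)
  # merge sparse strata forward; a sparse trailing group joins its neighbor
  ids <- sort(unique(stratum))
  sizes <- as.integer(table(stratum)[as.character(ids)])
  grp <- integer(length(ids)); g <- 1L; acc <- 0L
  for (j in seq_along(ids)) {
    grp[j] <- g
    acc <- acc + sizes[j]
    if (acc >= min_stratum_n) { g <- g + 1L; acc <- 0L }
  }
  if (acc > 0L && g > 1L) {
    warning("merging a sparse trailing distance stratum with its neighbor")
    grp[grp == g] <- g - 1L
  }
  stratum <- grp[match(stratum, ids)]

  # anchor bias: marginal coverage over the model-expected marginal, so an
  # anchor near a chromosome end (fewer partner bins) is not deflated.
  # Solved jointly with the stratum means by a few multiplicative updates.
  bias_all <- marg / mean(marg)
  bias_all[] <- 1
  for (it in seq_len(8)) {
    b1 <- as.numeric(bias_all[k1]); b2 <- as.numeric(bias_all[k2])
    mu_s <- tapply(counts, stratum, sum) / tapply(b1 * b2, stratum, sum)
    mu_pair <- as.numeric(mu_s[as.character(stratum)])
    partner <- tapply(c(mu_pair * b2, mu_pair * b1), ak, sum)
    bias_new <- as.numeric(marg / partner)
    bias_all[names(marg)] <- bias_new / mean(bias_new)
  }
  b1 <- as.numeric(bias_all[k1]); b2 <- as.numeric(bias_all[k2])
  bb <- b1 * b2
  fit_strata <- function(use) {
    sums_x <- tapply(counts[use], stratum[use], sum)
    sums_b <- tapply(bb[use], stratum[use], sum)
    mu_s <- sums_x / sums_b
    mu_s[as.character(sort(unique(stratum)))]
  }
  # pass 1: all pairs; overdispersion with the top 0.5% of residuals
  # trimmed so genuine loops cannot inflate the background
  mu_s <- fit_strata(rep(TRUE, length(counts)))
  expected <- as.numeric(mu_s[as.character(stratum)]) * bb
  resid2 <- (counts - expected)^2 - expected
  alpha_s <- vapply(split(seq_along(stratum), stratum), function(ii) {
    r2 <- resid2[ii]
    keep <- r2 <= quantile(r2, 0.995, names = FALSE)
    max(0, sum(r2[keep]) / sum(expected[ii][keep]^2))
  }, numeric(1))
  alpha <- as.numeric(alpha_s[as.character(stratum)])
  # pass 2: drop candidate loops (NB tail p < 1e-4) and refit mean and
  # untrimmed overdispersion on the clean background
  p0 <- ifelse(alpha <= 1e-12 | expected <= 0,
               ppois(counts - 1, pmax(expected, 1e-12), lower.tail = FALSE),
               pnbinom(counts - 1, mu = pmax(expected, 1e-12),
                       size = 1 / pmax(alpha, 1e-12), lower.tail = FALSE))
  bgm <- p0 >= 1e-4
  if (sum(bgm) > length(counts) / 2) {
    mu_s <- fit_strata(bgm)
    expected <- as.numeric(mu_s[as.character(stratum)]) * bb
    resid2 <- (counts - expected)^2 - expected
    alpha_s <- vapply(split(seq_along(stratum), stratum), function(ii) {
      jj <- ii[bgm[ii]]
      if (length(jj) < 10) jj <- ii
      max(0, sum(resid2[jj]) / sum(expected[jj]^2))
    }, numeric(1))
    alpha <- as.numeric(alpha_s[as.character(stratum)])
  }

  strata_df <- data.frame(
    stratum = sort(unique(stratum)),
    d_min = as.numeric(tapply(d_bp, stratum, min)),
    d_max = as.numeric(tapply(d_bp, stratum, max)),
    n = as.integer(table(stratum)),
    mean = as.numeric(mu_s),
    alpha = as.numeric(alpha_s))
  structure(
    list(strata = strata_df, bias = bias_all, expected = expected,
         alpha = alpha, bin_size = bin_size),
    class = "hichip_background"
  )
}

#' Call significant loops from counted bin pairs
#'
#' P-values are upper tails of a negative binomial with the background's
#' expected count and stratum overdispersion (Poisson when no
#' overdispersion was detected); q-values are Benjamini-Hochberg over all
#' tested pairs in the span range, globally across chromosomes.
#'
#' @param pairs data.frame with chrom, bin1, bin2.
#' @param counts Numeric vector (or matrix, rows summed) aligned with
#'   `pairs`.
#' @param background A [estimate_background()] result for the same pairs.
#' @param fdr FDR threshold in (0, 1).
#' @param min_span,max_span Tested span range in bp (defaults 20 kb / 2 Mb).
#' @param bin_size Bin width in bp.
#' @return data.frame of significant loops (chrom, bin1, bin2, span, count,
#'   expected, p, q, neglog10q), ordered by q. Attributes: `n_tested`,
#'   `fdr`, and `tested` (the full tested table).
#' @export
call_loops <- function(pairs, counts, background, fdr = 1e-5,
                       min_span = 20000L, max_span = 2000000L,
                       bin_size = 10000L) {
  if (!is.numeric(fdr) || fdr <= 0 || fdr >= 1) {
    stop("fdr must lie strictly between 0 and 1")
  }
  if (is.matrix(counts)) counts <- rowSums(counts)
  span <- (pairs$bin2 - pairs$bin1) * bin_size
  keep <- which(span >= min_span & span <= max_span)
  x <- counts[keep]
  mu <- background$expected[keep]
  alpha <- background$alpha[keep]
  p <- numeric(length(x))
  pois <- alpha <= 1e-12 | mu <= 0
  p[pois] <- ppois(x[pois] - 1, pmax(mu[pois], 1e-12), lower.tail = FALSE)
  if (any(!pois)) {
    p[!pois] <- pnbinom(x[!pois] - 1, mu = mu[!pois],
                        size = 1 / alpha[!pois], lower.tail = FALSE)
  }
  p[mu <= 0] <- 1
  q <- p.adjust(p, method = "BH")
  tested <- data.frame(chrom = pairs$chrom[keep], bin1 = pairs$bin1[keep],
                       bin2 = pairs$bin2[keep], span = span[keep],
                       count = x, expected = mu, p = p, q = q)
  sig <- tested[tested$q < fdr, , drop = FALSE]
  sig$neglog10q <- -log10(pmax(sig$q, .Machine$double.xmin))
  sig <- sig[order(sig$q, sig$chrom, sig$bin1, sig$bin2), ]
  rownames(sig) <- NULL
  attr(sig, "n_tested") <- nrow(tested)
  attr(sig, "fdr") <- fdr
  attr(sig, "tested") <- tested
  sig
}

#' Summarize loop calls by condition
#'
#' @param calls A single call data.frame or a named list of per-condition
#'   call data.frames from [call_loops()].
#' @param span_breaks Histogram breaks for the span distribution (bp).
#' @return List with `counts` (condition, n_loops) and `span_hist`
#'   (condition, span_lo, span_hi, n).
#' @export
loop_qc_summary <- function(calls,
                            span_breaks = c(2e4, 5e4, 1e5, 2e5, 5e5, 1e6, 2e6)) {
  if (is.data.frame(calls)) calls <- list(all = calls)
  counts <- data.frame(condition = names(calls),
                       n_loops = vapply(calls, nrow, integer(1)))
  hist_list <- lapply(names(calls), function(nm) {
    sp <- calls[[nm]]$span
    if (length(sp) == 0) {
      return(data.frame(condition = character(), span_lo = numeric(),
                        span_hi = numeric(), n = integer()))
    }
    cut_idx <- findInterval(sp, span_breaks, rightmost.closed = TRUE)
    data.frame(condition = nm,
               span_lo = span_breaks[-length(span_breaks)],
               span_hi = span_breaks[-1],
               n = as.integer(tabulate(cut_idx,
                                       nbins = length(span_breaks) - 1)))
  })
  list(counts = counts, span_hist = do.call(rbind, hist_list))
}
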