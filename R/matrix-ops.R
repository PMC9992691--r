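# Contact-matrix balancing, insulation-score boundary calling, and A/B
# compartment eigenvectors.

#' Balance a contact matrix to equal row sums
#'
#' Iterative correction: the matrix is symmetrically rescaled until every
#' unmasked row sum equals the mean row sum. This pursues the same balancing
#' objective as KR normalization; the `normalized` flag on the result records
#' that iterative correction (not KR factorization) was run. Bins whose raw
#' marginal is zero are masked and left untouched.
#'
#' @param m A [contact_matrix()].
#' @param max_iter Maximum number of iterations.
#' @param tol Convergence tolerance on the maximum relative row-sum deviation.
#' @return A balanced [contact_matrix()] with attribute `mask` (logical,
#'   `TRUE` for masked all-zero bins) and `iterations`.
#' @export
normalize_matrix <- function(m, max_iter = 200L, tol = 1e-8) {
  x <- m$counts
  mask <- rowSums(x) == 0
  active <- which(!mask)
  if (length(active) == 0) stop("all bins are empty; nothing to balance")
  target <- mean(rowSums(x)[active])
  resid <- Inf
  for (it in seq_len(max_iter)) {
    r <- rowSums(x)[active] / target
    resid <- max(abs(r - 1))
    if (resid < tol) break
    s <- 1 / sqrt(r)
    x[active, active] <- x[active, active] * outer(s, s)
  }
  if (resid >= tol) {
    stop(sprintf(
      "matrix balancing did not converge in %d iterations (last residual %.3g)",
      max_iter, resid))
  }
  out <- contact_matrix(x, m$chrom, m$bin_size, normalized = TRUE)
  attr(out, "mask") <- mask
  attr(out, "iterations") <- it
  out
}

#' Insulation score along a chromosome
#'
#' For each bin `i`, the raw insulation is the mean contact count in the
#' square window `m[i-w .. i-1, i+1 .. i+w]` with `w = window_b / bin_size`
#' (contacts crossing the bin). The reported score is the log2 ratio of the
#' raw insulation to its chromosomal mean, so it is invariant to global
#' scaling of the matrix. Bins whose window does not fit inside the
#' chromosome are `NA`.
#'
#' @param m A [contact_matrix()].
#' @param window_b Window size in bp (default 500 kb); must be a multiple of
#'   the bin size.
#' @return Numeric vector of per-bin scores with attributes `chrom`,
#'   `bin_size`, `window_b` and `raw` (the unnormalized window means).
#' @export
insulation_score <- function(m, window_b = 500000L) {
  bs <- m$bin_size
  w <- window_b / bs
  if (w != round(w)) stop("window_b must be a multiple of the bin size")
  w <- as.integer(w)
  n <- nrow(m$counts)
  if (2L * w + 1L > n) stop("insulation window larger than the chromosome")
  x <- m$counts
  raw <- rep(NA_real_, n)
  for (i in seq.int(w + 1L, n - w)) {
    raw[i] <- mean(x[(i - w):(i - 1L), (i + 1L):(i + w)])
  }
  mu <- mean(raw, na.rm = TRUE)
  score <- ifelse(is.na(raw) | raw <= 0 | mu <= 0, NA_real_,
                  log2(raw / mu))
  # bins with a zero window inside an otherwise populated chromosome get the
  # most negative finite score rather than NA: they are maximally insulating
  zero_in <- which(!is.na(raw) & raw == 0)
  if (length(zero_in) && any(is.finite(score))) {
    score[zero_in] <- min(score, na.rm = TRUE) - 1
  }
  structure(score, chrom = m$chrom, bin_size = bs, window_b = window_b,
            raw = raw)
}

# delta vector: mean(score over the ids-span left of i) minus mean over the
# span right of i; NA unless both spans are fully defined
insulation_delta <- function(score, span_bins) {
  n <- length(score)
  s <- as.integer(span_bins)
  delta <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i - s < 1L || i + s > n) next
    left <- score[(i - s):(i - 1L)]
    right <- score[(i + 1L):(i + s)]
    if (anyNA(left) || anyNA(right)) next
    delta[i] <- mean(left) - mean(right)
  }
  delta
}

#' Call TAD boundaries from an insulation score
#'
#' Boundaries sit where the insulation delta (left-span mean minus
#' right-span mean) crosses zero from positive to negative, provided a local
#' insulation minimum lies within `bmoe` bins of the crossing. Boundary
#' strength is the delta swing around the crossing (the local delta maximum
#' before it minus the local delta minimum after it, within the flanking
#' delta segments); boundaries weaker than `nt` are discarded.
#'
#' @param score Insulation score vector from [insulation_score()].
#' @param delta_span_ids Delta span in bp (default 200 kb).
#' @param nt Noise threshold on boundary strength (default 0.1).
#' @param bmoe Boundary margin of error in bins (default 3).
#' @param bin_size Bin width in bp; taken from `score`'s attribute when
#'   absent.
#' @param chrom Chromosome label; taken from `score`'s attribute when absent.
#' @return data.frame with columns `chrom`, `bin`, `strength` (one row per
#'   boundary, ordered by bin). Attribute `delta` carries the delta vector.
#' @export
call_boundaries <- function(score, delta_span_ids = 200000L, nt = 0.1,
                            bmoe = 3L, bin_size = attr(score, "bin_size"),
                            chrom = attr(score, "chrom")) {
  if (is.null(bin_size)) stop("bin_size is required")
  if (is.null(chrom)) chrom <- "chr"
  s <- delta_span_ids / bin_size
  if (s != round(s)) stop("delta_span_ids must be a multiple of the bin size")
  delta <- insulation_delta(as.numeric(score), s)
  empty <- data.frame(chrom = character(), bin = integer(),
                      strength = numeric())
  if (all(is.na(delta))) {
    warning("insulation delta undefined everywhere; no boundaries called")
    attr(empty, "delta") <- delta
    return(empty)
  }
  n <- length(delta)
  # local minima of the score (ties broken toward the lower bin index)
  sc <- as.numeric(score)
  is_min <- vapply(seq_len(n), function(i) {
    if (is.na(sc[i])) return(FALSE)
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    nb <- sc[lo:hi]
    !anyNA(nb) && sc[i] <= min(nb)
  }, logical(1))
  min_bins <- which(is_min)

  cross <- which(!is.na(delta[-n]) & !is.na(delta[-1L]) &
                 delta[-n] > 0 & delta[-1L] <= 0)
  res <- list()
  for (i in cross) {
    cand <- min_bins[abs(min_bins - i) <= bmoe + 1L]
    if (length(cand) == 0) next
    b <- cand[which.min(sc[cand] + 1e-12 * cand)]  # ties -> lower index
    # delta segment limits: previous and next upward (- to +) crossings
    lo <- i
    while (lo > 1L && !is.na(delta[lo - 1L]) && delta[lo - 1L] > 0) {
      lo <- lo - 1L
    }
    hi <- i + 1L
    while (hi < n && !is.na(delta[hi + 1L]) && delta[hi + 1L] <= 0) {
      hi <- hi + 1L
    }
    strength <- max(delta[lo:i], na.rm = TRUE) -
      min(delta[(i + 1L):hi], na.rm = TRUE)
    res[[length(res) + 1L]] <- data.frame(chrom = chrom, bin = b,
                                          strength = strength)
  }
  if (length(res) == 0) {
    attr(empty, "delta") <- delta
    return(empty)
  }
  out <- do.call(rbind, res)
  # the same insulation minimum can serve several adjacent crossings
  out <- out[order(out$bin, -out$strength), ]
  out <- out[!duplicated(out$bin), ]
  out <- out[out$strength >= nt, , drop = FALSE]
  out <- out[order(out$bin), ]
  rownames(out) <- NULL
  attr(out, "delta") <- delta
  out
}

#' Pair boundary calls between two conditions
#'
#' Boundaries are greedily matched within `match_margin` bins (closest pairs
#' first); unmatched calls are reported one-sided.
#'
#' @param calls_a,calls_b Boundary data.frames from [call_boundaries()].
#' @param match_margin Maximum bin distance for a match.
#' @return List with `matched` (bin_a, bin_b, strength_a, strength_b, diff),
#'   `unmatched_a`, `unmatched_b`, and `summary` (per-set count and median
#'   strength).
#' @export
boundary_strength_compare <- function(calls_a, calls_b, match_margin = 3L) {
  pairs <- expand.grid(ia = seq_len(nrow(calls_a)), ib = seq_len(nrow(calls_b)))
  if (nrow(pairs)) {
    pairs$dist <- abs(calls_a$bin[pairs$ia] - calls_b$bin[pairs$ib])
    pairs <- pairs[pairs$dist <= match_margin, , drop = FALSE]
    pairs <- pairs[order(pairs$dist), , drop = FALSE]
  }
  used_a <- logical(nrow(calls_a)); used_b <- logical(nrow(calls_b))
  keep <- integer(0)
  for (r in seq_len(nrow(pairs))) {
    ia <- pairs$ia[r]; ib <- pairs$ib[r]
    if (!used_a[ia] && !used_b[ib]) {
      used_a[ia] <- TRUE; used_b[ib] <- TRUE
      keep <- c(keep, r)
    }
  }
  pairs <- pairs[keep, , drop = FALSE]
  matched <- data.frame(
    bin_a = calls_a$bin[pairs$ia], bin_b = calls_b$bin[pairs$ib],
    strength_a = calls_a$strength[pairs$ia],
    strength_b = calls_b$strength[pairs$ib]
  )
  matched$diff <- matched$strength_b - matched$strength_a
  list(
    matched = matched,
    unmatched_a = calls_a[!used_a, , drop = FALSE],
    unmatched_b = calls_b[!used_b, , drop = FALSE],
    summary = data.frame(
      set = c("a", "b"),
      n = c(nrow(calls_a), nrow(calls_b)),
      median_strength = c(median(calls_a$strength), median(calls_b$strength))
    )
  )
}

#' A/B compartment eigenvector
#'
#' Computes the observed/expected matrix by distance, its Pearson correlation
#' matrix, and the leading eigenvector, at 100 kb resolution by default.
#' Bins in the lowest coverage quantile (and zero-coverage bins) are masked
#' to `NA`. The sign is oriented so that bins with positive values carry the
#' higher mean of `orient_track` (active-mark coverage); without a track the
#' orientation is arbitrary but deterministic.
#'
#' @param m A [contact_matrix()]; rebinned internally when its bin size is
#'   finer than `bin_size`.
#' @param bin_size Analysis resolution in bp (default 100 kb).
#' @param orient_track Optional numeric per-bin signal at `bin_size`
#'   resolution used to orient the sign.
#' @param mask_quantile Coverage quantile below which bins are masked
#'   (default 0.05).
#' @return List of class `compartment_profile`: `chrom`, `bin_size`,
#'   `eigenvector` (unit-normalized, `NA` for masked bins), `mask`,
#'   `sign_anchor` description.
#' @export
compartment_eigenvector <- function(m, bin_size = 100000L,
                                    orient_track = NULL,
                                    mask_quantile = 0.05) {
  if (m$bin_size != bin_size) m <- rebin_matrix(m, bin_size)
  x <- m$counts
  nb <- nrow(x)
  cov <- rowSums(x)
  thr <- quantile(cov[cov > 0], mask_quantile, names = FALSE)
  mask <- cov == 0 | cov < thr
  use <- which(!mask)
  if (length(use) < 10) stop("fewer than 10 usable bins for the eigenvector")
  xx <- x[use, use]
  d <- abs(outer(seq_along(use), seq_along(use), "-"))
  # expected value per genomic distance from the mean of each diagonal
  dg <- abs(outer(use, use, "-"))
  exp_by_d <- tapply(xx, dg, mean)
  ed <- matrix(exp_by_d[as.character(dg)], nrow(xx), ncol(xx))
  oe <- xx / ed
  oe[!is.finite(oe)] <- 0
  cc <- suppressWarnings(cor(oe))
  cc[!is.finite(cc)] <- 0
  ev <- eigen(cc, symmetric = TRUE)$vectors[, 1]
  ev <- ev / sqrt(sum(ev^2))
  if (!is.null(orient_track)) {
    tr <- orient_track[use]
    pos <- mean(tr[ev > 0]); neg <- mean(tr[ev <= 0])
    if (is.finite(pos) && is.finite(neg) && pos < neg) ev <- -ev
  } else if (sum(ev) < 0) {
    ev <- -ev
  }
  full <- rep(NA_real_, nb)
  full[use] <- ev
  structure(
    list(chrom = m$chrom, bin_size = bin_size, eigenvector = full,
         mask = mask,
         sign_anchor = "positive sign carries higher mean orient_track"),
    class = "compartment_profile"
  )
}
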