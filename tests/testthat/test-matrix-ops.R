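# Matrix balancing, insulation scores, boundary calls, compartment
# eigenvectors.

test_that("balancing equalizes row sums and masks empty bins", {
  ones <- contact_matrix(matrix(1, 6, 6), "chr1", 1e4)
  b <- normalize_matrix(ones)
  expect_equal(b$counts / b$counts[1, 1], ones$counts, tolerance = 1e-10)

  set.seed(1)
  x <- matrix(runif(16, 1, 2), 4, 4)
  x <- x + t(x) + diag(8, 4)
  m <- contact_matrix(x, "chr1", 1e4)
  b2 <- normalize_matrix(m, tol = 1e-10)
  rs <- rowSums(b2$counts)
  expect_lt(max(abs(rs / mean(rs) - 1)), 1e-8)
  expect_equal(b2$counts, t(b2$counts))

  x3 <- x; x3[2, ] <- 0; x3[, 2] <- 0
  b3 <- normalize_matrix(contact_matrix(x3, "chr1", 1e4), tol = 1e-10)
  expect_true(attr(b3, "mask")[2])
  expect_true(all(b3$counts[2, ] == 0))
  rs3 <- rowSums(b3$counts)[-2]
  expect_lt(max(abs(rs3 / mean(rs3) - 1)), 1e-8)
})

test_that("insulation score matches the brute-force window oracle", {
  m <- contact_matrix(toy_two_block(), "chr1", 1e4)
  sc <- insulation_score(m, window_b = 5e4)
  expect_equal(as.numeric(sc), oracle_insulation(m$counts, 5L),
               tolerance = 1e-12)
  # unique minimum at the block junction
  expect_equal(which.min(sc), 20L)
  # NaN margins of w bins and full length
  expect_equal(length(sc), 40L)
  expect_true(all(is.na(sc[1:5])) && all(is.na(sc[36:40])))
  # uniform matrix: all interior scores are exactly 0
  u <- contact_matrix(matrix(7, 30, 30), "chr1", 1e4)
  su <- insulation_score(u, 5e4)
  expect_equal(as.numeric(su[6:25]), rep(0, 20))
  # invariance to global scaling
  m3 <- contact_matrix(3 * m$counts, "chr1", 1e4)
  expect_equal(as.numeric(insulation_score(m3, 5e4)), as.numeric(sc),
               tolerance = 1e-12)
})

test_that("insulation window contract is enforced", {
  m <- contact_matrix(matrix(1, 10, 10), "chr1", 1e4)
  expect_error(insulation_score(m, 1e5), "larger than the chromosome")
  expect_error(insulation_score(m, 15000), "multiple")
})

test_that("no boundaries are called on a monotone score", {
  sc <- structure(seq(-1, 1, length.out = 200), bin_size = 1e4,
                  chrom = "chr1")
  calls <- call_boundaries(sc, delta_span_ids = 5e4)
  expect_equal(nrow(calls), 0L)
})

test_that("a planted boundary is recovered within the margin", {
  g <- small_genome()
  m <- generate_hic(g, 500L, tad_enrichment = 3, seed = 21)
  sc <- insulation_score(m)
  calls <- call_boundaries(sc)
  expect_equal(nrow(calls), 1L)
  expect_lte(abs(calls$bin - 500L), 3L)
  # halving the enrichment weakens the boundary strength
  m2 <- generate_hic(g, 500L, tad_enrichment = 1.5, seed = 21)
  calls2 <- call_boundaries(insulation_score(m2))
  if (nrow(calls2) == 1) {
    expect_lt(calls2$strength, calls$strength)
  }
  # deterministic and stable under appending NA margins
  sc_pad <- structure(c(rep(NA_real_, 10), as.numeric(sc), rep(NA_real_, 10)),
                      bin_size = 1e4, chrom = "chr1")
  calls_pad <- call_boundaries(sc_pad)
  expect_equal(calls_pad$bin - 10L, calls$bin)
  expect_equal(calls_pad$strength, calls$strength, tolerance = 1e-12)
})

test_that("all-NA scores yield an empty result with a warning", {
  sc <- structure(rep(NA_real_, 100), bin_size = 1e4, chrom = "chr1")
  expect_warning(calls <- call_boundaries(sc), "no boundaries")
  expect_equal(nrow(calls), 0L)
})

test_that("boundary matching pairs calls and reports strengths", {
  a <- data.frame(chrom = "chr1", bin = c(100L, 200L, 300L),
                  strength = c(1, 2, 3))
  cmp <- boundary_strength_compare(a, a, match_margin = 3)
  expect_equal(nrow(cmp$matched), 3L)
  expect_equal(cmp$matched$diff, rep(0, 3))
  b <- a; b$strength <- a$strength / 2
  cmp2 <- boundary_strength_compare(a, b, match_margin = 3)
  expect_equal(median(cmp2$matched$diff), -median(a$strength) / 2)
  b3 <- a; b3$bin <- a$bin + 1L
  cmp3 <- boundary_strength_compare(a, b3, match_margin = 0)
  expect_equal(nrow(cmp3$matched), 0L)
  expect_equal(nrow(cmp3$unmatched_a), 3L)
  expect_equal(cmp3$summary$n, c(3L, 3L))
})

test_that("compartment eigenvector separates planted blocks", {
  # checkerboard: 60 bins at 100 kb, alternating 15-bin blocks
  n <- 60
  s <- rep(rep(c(1, -1), length.out = 4), each = 15)
  d <- abs(outer(1:n, 1:n, "-"))
  base <- 100 * pmax(d, 0.5)^-1
  x <- base * (1 + 0.4 * outer(s, s))
  set.seed(31)
  up <- upper.tri(x, diag = TRUE)
  cnt <- matrix(0, n, n); cnt[up] <- rpois(sum(up), x[up])
  cnt <- cnt + t(cnt) - diag(diag(cnt))
  m <- contact_matrix(cnt, "chr1", 1e5)
  prof <- compartment_eigenvector(m, bin_size = 1e5,
                                  orient_track = pmax(s, 0))
  ev <- prof$eigenvector
  expect_equal(sum(abs(ev)^2, na.rm = TRUE), 1, tolerance = 1e-6)
  agree <- sign(ev) == sign(s)
  expect_gt(mean(agree, na.rm = TRUE), 0.95)
  # orientation contract: track concentrated on block 1 makes it positive
  expect_gt(mean(ev[s > 0], na.rm = TRUE), 0)

  # independent power-iteration oracle on the same O/E correlation matrix
  oe_cor <- local({
    cov_ <- rowSums(cnt)
    use <- which(cov_ >= quantile(cov_[cov_ > 0], 0.05))
    xx <- cnt[use, use]
    dg <- abs(outer(use, use, "-"))
    ed <- matrix(tapply(xx, dg, mean)[as.character(dg)], length(use))
    oe <- xx / ed; oe[!is.finite(oe)] <- 0
    cc <- suppressWarnings(cor(oe)); cc[!is.finite(cc)] <- 0
    list(cc = cc, use = use)
  })
  v <- rep(1, nrow(oe_cor$cc)) / sqrt(nrow(oe_cor$cc))
  for (i in 1:500) {
    v <- oe_cor$cc %*% v
    v <- v / sqrt(sum(v^2))
  }
  cosang <- abs(sum(v * ev[oe_cor$use]))
  expect_gt(cosang, 0.999)
})

test_that("compartment eigenvector needs enough usable bins", {
  m <- contact_matrix(matrix(1, 5, 5), "chr1", 1e5)
  expect_error(compartment_eigenvector(m), "10 usable bins")
})
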