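# Background estimation, loop significance, and QC summaries.

test_that("single-stratum uniform data yields the global mean", {
  pairs <- data.frame(chrom = "chr1", bin1 = 1:100, bin2 = 3:102)
  counts <- rep(8, 100)
  bg <- estimate_background(pairs, counts, min_stratum_n = 10)
  expect_equal(unname(bg$expected), rep(8, 100), tolerance = 1e-6)
})

test_that("anchor bias acts multiplicatively on expected counts", {
  # one anchor with doubled counts in all of its pairs
  set.seed(41)
  pairs <- expand.grid(bin1 = seq(1, 300, by = 3), d = c(5L, 6L, 7L))
  pairs <- data.frame(chrom = "chr1", bin1 = pairs$bin1,
                      bin2 = pairs$bin1 + pairs$d)
  counts <- rpois(nrow(pairs), 20)
  hot <- pairs$bin1 == 100 | pairs$bin2 == 100
  counts[hot] <- rpois(sum(hot), 40)
  bg <- estimate_background(pairs, counts, min_stratum_n = 20)
  expect_equal(mean(bg$expected[hot]) / mean(bg$expected[!hot]), 2,
               tolerance = 0.25)
})

test_that("stratum means track a planted decay curve", {
  g <- small_genome()
  tr <- generate_truth(g, n_boundaries = 0, genes_per_mode = 0,
                       n_control_genes = 0, n_extra_loops = 0,
                       n_extra_enhancers = 0, n_se_clusters = 0, seed = 42)
  sim <- generate_hichip(g, tr, library_size = 4e5, bias_sd = 0, seed = 43)
  pooled <- rowSums(sim$counts$ctrl)
  bg <- estimate_background(sim$pairs, pooled)
  d <- sim$pairs$bin2 - sim$pairs$bin1
  planted <- 2 * 4e5 * (1 / d) / sum((1 / d))
  rel <- bg$expected / planted
  expect_lt(quantile(abs(rel - 1), 0.9), 0.1 + 3 * 0.25)  # bias off: tight
  # with bias off the stratum means themselves sit within 10%
  sel <- d %in% c(5, 20, 50, 100)
  agg <- tapply(bg$expected[sel] / planted[sel], d[sel], mean)
  expect_true(all(abs(agg - 1) < 0.1))
})

test_that("null data produce no loops at stringent FDR", {
  zero_calls <- vapply(1:3, function(s) {
    g <- small_genome(seed = s)
    tr <- generate_truth(g, n_boundaries = 0, genes_per_mode = 0,
                         n_control_genes = 0, n_extra_loops = 0,
                         n_extra_enhancers = 0, n_se_clusters = 0, seed = s)
    sim <- generate_hichip(g, tr, library_size = 4e5, seed = s + 7)
    pooled <- rowSums(sim$counts$ctrl)
    bg <- estimate_background(sim$pairs, pooled)
    nrow(call_loops(sim$pairs, pooled, bg, fdr = 1e-5))
  }, numeric(1))
  expect_true(all(zero_calls == 0))
})

test_that("strong planted loops are called and weak spans excluded", {
  g <- small_genome(seed = 4)
  tr <- generate_truth(g, n_boundaries = 0, genes_per_mode = 0,
                       n_control_genes = 0, n_extra_loops = 50,
                       n_extra_enhancers = 0, n_se_clusters = 0,
                       loop_base_strength = 10, seed = 44)
  sim <- generate_hichip(g, tr, library_size = 4e5, seed = 45)
  pooled <- rowSums(sim$counts$ctrl)
  bg <- estimate_background(sim$pairs, pooled)
  calls <- call_loops(sim$pairs, pooled, bg, fdr = 1e-5)
  key <- paste(calls$chrom, calls$bin1, calls$bin2)
  tk <- paste(tr$loops$chrom, tr$loops$bin1, tr$loops$bin2)
  expect_gte(sum(tk %in% key), 45)
  expect_lte(nrow(calls), 55)
  expect_true(all(calls$span >= 20000 & calls$span <= 2000000))
  expect_true(all(calls$q >= calls$p))
  expect_equal(calls$neglog10q, -log10(calls$q), tolerance = 1e-10)

  # a sub-minimum span is excluded regardless of its count
  pairs2 <- rbind(sim$pairs[, c("chrom", "bin1", "bin2")],
                  data.frame(chrom = "chr1", bin1 = 10L, bin2 = 11L))
  counts2 <- c(pooled, 10000)
  bg2 <- estimate_background(pairs2, counts2)
  calls2 <- call_loops(pairs2, counts2, bg2, fdr = 1e-5)
  expect_false(any(calls2$bin1 == 10L & calls2$bin2 == 11L))
  expect_true(all(calls2$span >= 20000))
})

test_that("fdr argument is validated", {
  pairs <- data.frame(chrom = "chr1", bin1 = 1:10, bin2 = 11:20)
  bg <- estimate_background(pairs, rep(5, 10), min_stratum_n = 5)
  expect_error(call_loops(pairs, rep(5, 10), bg, fdr = 0), "fdr")
  expect_error(call_loops(pairs, rep(5, 10), bg, fdr = 1.5), "fdr")
})

test_that("BH q-values are monotone in p and scaling preserves ranking", {
  g <- small_genome(seed = 5)
  tr <- generate_truth(g, n_boundaries = 0, genes_per_mode = 0,
                       n_control_genes = 0, n_extra_loops = 20,
                       n_extra_enhancers = 0, n_se_clusters = 0, seed = 46)
  sim <- generate_hichip(g, tr, library_size = 3e5, seed = 47)
  pooled <- rowSums(sim$counts$ctrl)
  bg <- estimate_background(sim$pairs, pooled)
  tested <- attr(call_loops(sim$pairs, pooled, bg, fdr = 0.5), "tested")
  ord <- order(tested$p)
  expect_true(all(diff(tested$q[ord]) >= -1e-15))

  # doubling all counts (and hence expecteds) leaves the ranking intact
  bg2 <- estimate_background(sim$pairs, pooled * 2)
  tested2 <- attr(call_loops(sim$pairs, pooled * 2, bg2, fdr = 0.5), "tested")
  sub <- sample(nrow(tested), 20000)
  expect_gt(cor(tested$p[sub], tested2$p[sub], method = "spearman"), 0.99)
  top1 <- head(order(tested$p), 20)
  top2 <- head(order(tested2$p), 20)
  expect_setequal(paste(tested$bin1[top1], tested$bin2[top1]),
                  paste(tested2$bin1[top2], tested2$bin2[top2]))
})

test_that("loop QC summarizes counts and spans by condition", {
  empty <- data.frame(chrom = character(), bin1 = integer(),
                      bin2 = integer(), span = numeric())
  qc0 <- loop_qc_summary(list(ctrl = empty))
  expect_equal(qc0$counts$n_loops, 0L)
  calls <- data.frame(chrom = "chr1", bin1 = c(1L, 5L), bin2 = c(10L, 30L),
                      span = c(9e4, 2.5e5))
  qc <- loop_qc_summary(list(a = calls, b = empty))
  expect_equal(qc$counts$n_loops, c(2L, 0L))
  expect_equal(sum(qc$span_hist$n), 2L)
})
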