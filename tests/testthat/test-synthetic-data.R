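# Synthetic-data generator: placement guarantees, planted signal, and
# round-trip I/O.

test_that("generate_genome places unique, well-spaced genes deterministically", {
  g <- generate_genome(1L, 30e6, 100L, seed = 1)
  expect_equal(nrow(g$genes), 100L)
  expect_equal(anyDuplicated(g$genes$tss), 0L)
  expect_true(all(diff(sort(g$genes$tss)) >= 30000))
  expect_true(all(g$genes$tss > 0 & g$genes$tss < 30e6))
  g2 <- generate_genome(1L, 30e6, 100L, seed = 1)
  expect_identical(g, g2)
  g3 <- generate_genome(1L, 30e6, 100L, seed = 2)
  expect_false(identical(g$genes$tss, g3$genes$tss))
})

test_that("generate_genome rejects infeasible requests", {
  expect_error(generate_genome(1L, 1e6, 10000L, seed = 1))
  expect_error(generate_genome(1L, 5e6, 10000L, seed = 1), "spacing|place")
})

test_that("pure decay matrices decrease with distance and are symmetric", {
  g <- small_genome()
  m <- generate_hic(g, integer(0), noise = "none")
  row1 <- m$counts[1, 2:200]
  expect_true(all(diff(row1) < 0))
  ms <- generate_hic(g, c(200L, 500L), seed = 3)
  expect_identical(ms$counts, t(ms$counts))
  expect_true(all(ms$counts >= 0))
  expect_true(all(ms$counts == round(ms$counts)))
  expect_error(generate_hic(g, 5000L), "out of range")
})

test_that("TAD enrichment is recovered from sampled block means", {
  g <- small_genome()
  m <- generate_hic(g, 500L, tad_enrichment = 3, seed = 4)
  x <- m$counts
  d <- abs(outer(seq_len(nrow(x)), seq_len(nrow(x)), "-"))
  sel <- d >= 5 & d <= 60
  within <- (row(x) <= 500 & col(x) <= 500) | (row(x) > 500 & col(x) > 500)
  # compare within- and between-block means at matched distances
  ratios <- vapply(5:60, function(dd) {
    w <- x[d == dd & within]; b <- x[d == dd & !within]
    if (length(b) < 20) return(NA_real_)
    mean(w) / mean(b)
  }, numeric(1))
  expect_equal(mean(ratios, na.rm = TRUE), 3, tolerance = 0.1)
})

test_that("hichip counts honor planted multipliers and determinism", {
  g <- small_genome()
  tr <- generate_truth(g, n_boundaries = 2, genes_per_mode = 0,
                       n_control_genes = 0, n_extra_loops = 50,
                       n_extra_enhancers = 0, n_se_clusters = 0,
                       loop_base_strength = 4, seed = 5)
  sim <- generate_hichip(g, tr, library_size = 4e5, seed = 6)
  # constant multiplier 1 in both conditions: per-loop means agree
  mc <- rowMeans(sim$counts$ctrl[sim$truth_idx, ])
  ms <- rowMeans(sim$counts$stim[sim$truth_idx, ])
  expect_equal(mean(mc), mean(ms), tolerance = 0.1)
  # planted enrichment ~4x the matched-distance background
  d_all <- sim$pairs$bin2 - sim$pairs$bin1
  enr <- vapply(seq_along(sim$truth_idx), function(i) {
    ti <- sim$truth_idx[i]
    bgsel <- which(d_all == d_all[ti])
    bgsel <- setdiff(bgsel, sim$truth_idx)
    mean(sim$counts$ctrl[ti, ]) / mean(sim$counts$ctrl[bgsel, ])
  }, numeric(1))
  expect_equal(mean(enr), 4, tolerance = 0.5)
  sim2 <- generate_hichip(g, tr, library_size = 4e5, seed = 6)
  expect_identical(sim$counts, sim2$counts)
  # spans outside the legal range are rejected at construction
  tr_bad <- tr
  tr_bad$loops$bin2[1] <- tr_bad$loops$bin1[1] + 1L
  tr_bad$loops$span[1] <- 10000
  expect_error(generate_hichip(g, tr_bad, seed = 1), "span")
})

test_that("peak signal encodes enhancer classes and stays in bounds", {
  g <- small_genome()
  tr <- generate_truth(g, n_boundaries = 2, genes_per_mode = 3,
                       n_control_genes = 4, inducible_ratio = 2,
                       span_range = c(40000, 150000), seed = 8)
  const <- tr$enhancers[tr$enhancers$class == "constitutive", ]
  expect_true(all(abs(log2(const$signal_stim / const$signal_ctrl)) <
                    0.378512))
  ind <- tr$enhancers[tr$enhancers$class == "inducible", ]
  expect_equal(log2(ind$signal_stim / ind$signal_ctrl),
               rep(1, nrow(ind)))
  pk <- generate_peaks(g, tr, "stim", seed = 9)
  for (set in pk) {
    expect_true(all(set$start >= 0))
    expect_true(all(set$end <= 10e6))
    expect_true(all(set$signal >= 0))
    expect_true(all(diff(set$start) >= 0))
  }
  # empirical replicate-averaged signal ratio tracks the planted class
  reps <- lapply(1:6, function(r) generate_peaks(g, tr, "stim", seed = r))
  stim_mean <- rowMeans(sapply(reps, function(p) p$h3k27ac$signal))
  reps0 <- lapply(1:6, function(r) generate_peaks(g, tr, "ctrl", seed = 100 + r))
  ctrl_mean <- rowMeans(sapply(reps0, function(p) p$h3k27ac$signal))
  nm <- reps[[1]]$h3k27ac$name
  ind_idx <- nm %in% ind$enh_id
  expect_equal(mean(log2(stim_mean[ind_idx] / ctrl_mean[ind_idx])), 1,
               tolerance = 0.25)
})

test_that("rna counts carry the planted fold-changes", {
  g <- small_genome()
  tr <- generate_truth(g, n_boundaries = 2, genes_per_mode = 5,
                       n_control_genes = 5,
                       mode_log2fc = c(i = 1, ii = 1, iii = 1,
                                       iv = -1, v = -1, vi = -1),
                       span_range = c(40000, 150000), seed = 10)
  cnt <- generate_rna_counts(g, tr, n_replicates = 8, seed = 11)
  grp <- attr(cnt, "conditions")
  lfc <- log2((rowMeans(cnt[, grp == "stim"]) + 0.5) /
                (rowMeans(cnt[, grp == "ctrl"]) + 0.5))
  gm <- tr$gene_modes[match(rownames(cnt), tr$gene_modes$gene_id), ]
  null_genes <- gm$mode %in% c("control", "none")
  expect_equal(mean(lfc[null_genes]), 0, tolerance = 0.25)
  up <- gm$mode %in% c("i", "ii", "iii")
  expect_equal(mean(lfc[up]), 1, tolerance = 0.2)
  cnt2 <- generate_rna_counts(g, tr, n_replicates = 8, seed = 11)
  expect_identical(cnt, cnt2)
})

test_that("truth tables and matrices round-trip through text files", {
  g <- small_genome()
  tr <- generate_truth(g, n_boundaries = 2, genes_per_mode = 2,
                       n_control_genes = 2, span_range = c(40000, 150000),
                       seed = 12)
  dir <- tempfile("truth_")
  write_truth(tr, dir)
  tr2 <- read_truth(dir)
  expect_equal(tr$boundaries, tr2$boundaries)
  expect_equal(tr$loops, tr2$loops, tolerance = 1e-12)
  expect_equal(tr$enhancers$signal_stim, tr2$enhancers$signal_stim)
  expect_equal(tr$gene_modes, tr2$gene_modes)

  m <- generate_hic(g, c(300L), seed = 13)
  f1 <- tempfile(fileext = ".tsv")
  write_contact_matrix(m, f1, format = "coo")
  expect_equal(read_contact_matrix(f1)$counts, m$counts)
  f2 <- tempfile(fileext = ".tsv")
  write_contact_matrix(rebin_matrix(m, 100000L), f2, format = "dense")
  expect_equal(read_contact_matrix(f2)$counts,
               rebin_matrix(m, 100000L)$counts)

  sim <- generate_hichip(g, tr, library_size = 2e5, seed = 14)
  dir2 <- tempfile("hichip_")
  paths <- write_hichip_bedpe(sim, dir2)
  back <- read_hichip_bedpe(paths[["ctrl"]])
  expect_equal(back$pairs$bin1, sim$pairs$bin1)
  expect_equal(unname(back$counts), unname(sim$counts$ctrl))

  pk <- generate_peaks(g, tr, "ctrl", seed = 15)
  f3 <- tempfile(fileext = ".bed")
  write_peaks_bed(pk$h3k27ac, f3)
  back_pk <- read_peaks_bed(f3)
  expect_equal(back_pk$start, pk$h3k27ac$start)
  expect_equal(back_pk$signal, pk$h3k27ac$signal)
})
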