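# Regulatory-mode assignment, cross-boundary analysis, TF targets, and
# region-set enrichment.

toy_mode_setup <- function() {
  ann <- data.frame(
    chrom = "chr1", bin = 1:8,
    anchor_id = paste0("chr1:", 1:8),
    label = c("promoter", "enhancer", "promoter", "enhancer",
              "promoter", "enhancer", "promoter", "enhancer"),
    gene_ids = c("g1", "", "g2", "", "g3", "", "g4", ""),
    se_flag = FALSE)
  enh_cls <- data.frame(anchor_id = paste0("chr1:", c(2, 4, 6, 8)),
                        class = c("inducible", "constitutive",
                                  "repressed", "constitutive"))
  list(ann = ann, enh_cls = enh_cls)
}

test_that("mode assignment follows the loop-by-enhancer wiring table", {
  s <- toy_mode_setup()
  loops <- data.frame(
    chrom = "chr1",
    bin1 = c(1L, 3L, 5L, 7L),
    bin2 = c(2L, 4L, 6L, 8L),
    class = c("gained", "lost", "constant", "constant"),
    loop_id = paste0("L", 1:4))
  asg <- assign_modes(loops, s$enh_cls, s$ann)
  expect_equal(asg$mode[match(c("g1", "g2", "g3", "g4"), asg$gene_id)],
               c("i", "iv", "v", "control"))
  # reversed anchor order and shuffled input leave assignments unchanged
  loops_r <- loops[4:1, ]
  tmp <- loops_r$bin1; loops_r$bin1 <- loops_r$bin2; loops_r$bin2 <- tmp
  asg2 <- assign_modes(loops_r, s$enh_cls, s$ann)
  expect_equal(asg2[order(asg2$gene_id), c("gene_id", "mode")],
               asg[order(asg$gene_id), c("gene_id", "mode")],
               ignore_attr = TRUE)
  # remaining combinations: gained+constitutive -> iii, a combination
  # outside the wiring table (gained + repressed) stays unassigned
  loops$class <- c("constant", "gained", "gained", "lost")
  asg3 <- assign_modes(loops, s$enh_cls, s$ann)
  expect_equal(asg3$mode[match(c("g1", "g2", "g3", "g4"), asg3$gene_id)],
               c("ii", "iii", "unassigned", "iv"))
  # loops without a promoter anchor are skipped
  loops_np <- data.frame(chrom = "chr1", bin1 = 2L, bin2 = 4L,
                         class = "gained", loop_id = "LX")
  asg4 <- assign_modes(loops_np, s$enh_cls, s$ann)
  expect_equal(nrow(asg4), 0L)
  expect_equal(attr(asg4, "n_skipped"), 1L)
})

test_that("mode-vs-control expression testing uses Welch t-tests", {
  set.seed(61)
  asg <- data.frame(
    gene_id = c(sprintf("up%02d", 1:30), sprintf("ct%02d", 1:30)),
    loop_id = "L", distal_anchor_id = "a",
    loop_class = "x", enh_class = "y",
    mode = rep(c("i", "control"), each = 30))
  de <- data.frame(feature_id = asg$gene_id,
                   log2fc = c(rnorm(30, 1, 0.3), rnorm(30, 0, 0.3)))
  tab <- mode_expression_test(asg, de)
  row_i <- tab[tab$mode == "i", ]
  expect_gt(row_i$t, 0)
  expect_lt(row_i$p, 0.01)
  # a mode with the same members as control is indistinguishable
  asg2 <- asg; asg2$mode[asg2$mode == "i"] <- "ii"
  asg2 <- rbind(asg2, transform(asg2[asg2$mode == "control", ], mode = "v"))
  de2 <- de
  tab2 <- mode_expression_test(asg2, de2)
  expect_gt(tab2$p[tab2$mode == "v"], 0.99)
})

test_that("boundary crossing matches the exhaustive containment oracle", {
  set.seed(62)
  n <- 2000
  loops <- data.frame(chrom = sample(c("chr1", "chr2"), n, TRUE),
                      bin1 = sample(1:500, n, TRUE))
  loops$bin2 <- loops$bin1 + sample(2:60, n, TRUE)
  bnd <- data.frame(chrom = rep(c("chr1", "chr2"), each = 10),
                    bin = sample(1:560, 20))
  got <- crosses_boundary(loops, bnd)
  ref <- vapply(seq_len(n), function(i) {
    b <- bnd$bin[bnd$chrom == loops$chrom[i]]
    oracle_crosses(loops$bin1[i], loops$bin2[i], b)
  }, logical(1))
  expect_identical(got, ref)
  # a boundary exactly at an anchor bin does not separate the anchors
  edge <- data.frame(chrom = "chr1", bin1 = 10L, bin2 = 20L)
  expect_false(crosses_boundary(edge, data.frame(chrom = "chr1", bin = 10L)))
  expect_false(crosses_boundary(edge, data.frame(chrom = "chr1", bin = 20L)))
  expect_true(crosses_boundary(edge, data.frame(chrom = "chr1", bin = 11L)))
})

test_that("the crossing report partitions loops and tabulates genes", {
  ann <- data.frame(chrom = "chr1", bin = c(1L, 30L, 100L),
                    anchor_id = paste0("chr1:", c(1, 30, 100)),
                    label = c("promoter", "enhancer", "promoter"),
                    gene_ids = c("gU", "", "gD"), se_flag = FALSE)
  loops <- data.frame(chrom = "chr1", bin1 = c(1L, 30L), bin2 = c(30L, 100L))
  bnd <- data.frame(chrom = "chr1", bin = 50L)
  de <- data.frame(feature_id = c("gU", "gD"),
                   direction = c("up", "down"))
  rep_ <- boundary_crossing_report(loops, bnd, de, ann)
  expect_equal(rep_$n_across, 1L)
  expect_equal(rep_$n_within, 1L)
  expect_equal(rep_$fraction_across, 0.5)
  expect_equal(unname(rep_$gene_table["across", "down"]), 1L)
  expect_equal(unname(rep_$gene_table["within", "up"]), 1L)
  # no boundaries: nothing crosses
  rep0 <- boundary_crossing_report(loops, bnd[0, ], de, ann)
  expect_equal(rep0$fraction_across, 0)
})

test_that("TF target classes reflect promoter and looped-enhancer binding", {
  genes <- data.frame(gene_id = c("gP", "gB", "gD"), chrom = "chr1",
                      strand = "+", tss = c(105000, 1005000, 2005000))
  enh_peaks <- data.frame(chrom = "chr1",
                          start = c(200000, 1100000, 2100000),
                          end = c(201000, 1101000, 2101000),
                          name = c("e1", "e2", "e3"), signal = 1)
  el <- build_elements(genes, enh_peaks)
  anchors <- data.frame(chrom = "chr1",
                        bin = pos_to_bin(c(105000, 200500, 1005000, 1100500,
                                           2005000, 2100500), 1e4))
  ann <- annotate_anchors(anchors, el)
  loops <- data.frame(chrom = "chr1",
                      bin1 = ann$bin[c(3, 5)], bin2 = ann$bin[c(4, 6)])
  # TF binds gP's promoter, gB's promoter AND its looped enhancer, and only
  # the enhancer looped to gD
  tf <- data.frame(chrom = "chr1",
                   start = c(104000, 1004000, 1100200, 2100200),
                   end = c(104500, 1004500, 1100800, 2100800))
  tt <- assign_tf_targets(tf, el, loops, ann)
  expect_equal(tt$class[tt$gene_id == "gP"], "promoter_only")
  expect_equal(tt$class[tt$gene_id == "gB"], "promoter_and_distal")
  expect_equal(tt$class[tt$gene_id == "gD"], "distal_only")
})

test_that("region enrichment reproduces the hypergeometric tail", {
  # worked table (a, b, c, d) = (20, 10, 5, 65)
  p <- fisher_tail_p(20, 10, 5, 65)
  expect_equal(p, oracle_hyper_tail(20, 10, 5, 65), tolerance = 1e-14)
  ft <- fisher.test(matrix(c(20, 10, 5, 65), 2, byrow = TRUE),
                    alternative = "greater")
  expect_equal(p, ft$p.value, tolerance = 1e-12)

  mk <- function(n, w = 100) {
    data.frame(chrom = "chr1", start = (n - 1) * 1000,
               end = (n - 1) * 1000 + w)
  }
  universe <- do.call(rbind, lapply(1:100, mk))
  query <- do.call(rbind, lapply(1:30, mk))
  refset <- do.call(rbind, lapply(c(1:25), mk))
  enr <- region_set_enrichment(query, refset, universe)
  expect_equal(unname(enr$table["query", "ref"]), 25)
  expect_equal(enr$p, oracle_hyper_tail(25, 5, 0, 70), tolerance = 1e-12)
  expect_gt(enr$odds_ratio, 1)
  # query == universe: no contrast, odds ratio 1, p 1
  enr_all <- region_set_enrichment(universe, refset, universe)
  expect_equal(enr_all$odds_ratio, 1)
  expect_equal(enr_all$p, 1)
  # disjoint query vs abundant reference: depletion
  enr_dep <- region_set_enrichment(do.call(rbind, lapply(90:99, mk)),
                                   do.call(rbind, lapply(1:80, mk)),
                                   universe)
  expect_lt(enr_dep$odds_ratio, 1)
})
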