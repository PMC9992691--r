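# End-to-end orchestration: config, staged execution, output manifest, and
# recovery metrics against planted truth.

#' Build and validate a pipeline configuration
#'
#' Defaults mirror the analysis parameters used throughout the package:
#' 10 kb bins, loop spans 20 kb - 2 Mb, loop FDR 1e-5 for the acetylation
#' assay and 1e-2 for the TF assay, the [threshold_set()] classification
#' cutoffs, promoter +/- 2.5 kb, 12.5 kb super-enhancer stitching, and
#' insulation 500 kb window / 200 kb delta span / noise threshold 0.1 /
#' boundary margin 3 bins.
#'
#' @param seed Pipeline-level seed; per-stage seeds are derived by fixed
#'   offsets.
#' @param chrom_length,n_genes,n_boundaries Genome/truth dimensions.
#' @param n_hichip_replicates,n_rna_replicates Replicates per condition.
#' @param hichip_library_size Expected background contacts per replicate.
#' @param loop_fdr_h3k27ac,loop_fdr_tf Loop-calling FDR per assay.
#' @param min_span,max_span Loop span range (bp).
#' @param bin_size Bin width (bp).
#' @param thresholds A [threshold_set()].
#' @param conditions Two condition labels, reference first.
#' @param tad_enrichment,hic_depth Hi-C simulation parameters.
#' @param truth_args Extra arguments forwarded to [generate_truth()].
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, chrom_length = 30e6, n_genes = 100L,
                            n_boundaries = 5L, n_hichip_replicates = 2L,
                            n_rna_replicates = 3L,
                            hichip_library_size = 1e6,
                            loop_fdr_h3k27ac = 1e-5, loop_fdr_tf = 1e-2,
                            min_span = 20000L, max_span = 2000000L,
                            bin_size = 10000L,
                            thresholds = threshold_set(),
                            conditions = c("ctrl", "stim"),
                            tad_enrichment = 3, hic_depth = 100,
                            truth_args = list()) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' Fails fast, before any computation, on out-of-range values.
#'
#' @param cfg A [pipeline_config()] list.
#' @return `cfg`, invisibly.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) stop("invalid config: ", msg, call. = FALSE)
  chk(cfg$loop_fdr_h3k27ac > 0 && cfg$loop_fdr_h3k27ac < 1,
      "loop_fdr_h3k27ac must lie in (0, 1)")
  chk(cfg$loop_fdr_tf > 0 && cfg$loop_fdr_tf < 1,
      "loop_fdr_tf must lie in (0, 1)")
  chk(cfg$min_span > 0 && cfg$max_span > cfg$min_span,
      "span range must satisfy 0 < min_span < max_span")
  chk(cfg$bin_size > 0, "bin_size must be positive")
  chk(cfg$chrom_length >= 5e6, "chrom_length must be at least 5 Mb")
  chk(cfg$n_hichip_replicates >= 2, "need >= 2 HiChIP replicates")
  chk(cfg$tad_enrichment > 1, "tad_enrichment must exceed 1")
  chk(length(cfg$conditions) == 2, "exactly two conditions are required")
  invisible(cfg)
}

# fixed per-stage seed offsets (single pipeline-level seed -> stage seeds)
stage_offsets <- c(genome = 1L, truth = 2L, hic = 3L, hichip = 4L,
                   peaks = 5L, rna = 6L, louvain = 7L)

#' Run one pipeline stage
#'
#' Stages operate on an in-memory `state` list (as produced by earlier
#' stages) and write their text outputs under `outdir`. A stage whose
#' upstream results are missing fails with an error naming the stage to run
#' first.
#'
#' @param stage One of "simulate", "insulation", "compartments",
#'   "call-loops", "annotate", "diff-loops", "diff-anchors",
#'   "diff-expression", "modes", "boundaries", "tf-targets", "enrich",
#'   "v4c", "cliques", "report".
#' @param config A [pipeline_config()].
#' @param state State list from previous stages (`NULL` to start).
#' @param outdir Output directory.
#' @return The updated state list, invisibly for side-effect-only stages.
#' @export
run_stage <- function(stage, config, state = NULL, outdir = tempfile("loopscape_")) {
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  need <- function(what, from) {
    if (is.null(state[[what]])) {
      stop(sprintf("stage '%s' requires '%s'; run stage '%s' first",
                   stage, what, from), call. = FALSE)
    }
  }
  seed_of <- function(nm) derive_seed(config$seed, stage_offsets[[nm]])
  cond <- config$conditions
  bs <- config$bin_size

  state <- switch(stage,
    "simulate" = {
      genome <- generate_genome(1L, config$chrom_length, config$n_genes,
                                bin_size = bs, seed = seed_of("genome"))
      truth <- do.call(generate_truth, c(
        list(genome = genome, n_boundaries = config$n_boundaries,
             conditions = cond, seed = seed_of("truth")),
        config$truth_args))
      nb <- n_bins(config$chrom_length, bs)
      # A/B blocks alternate across TADs so compartment transitions sit on
      # planted boundaries, as they do in real genomes
      block <- findInterval(seq_len(nb), sort(truth$boundaries$bin) + 0.5)
      comp <- ifelse(block %% 2 == 0, 1, -1)
      hic <- lapply(seq_along(cond), function(ci) {
        generate_hic(genome, truth$boundaries$bin,
                     tad_enrichment = config$tad_enrichment,
                     depth = config$hic_depth,
                     compartment_profile = comp,
                     seed = derive_seed(seed_of("hic"), ci))
      })
      names(hic) <- cond
      hichip <- generate_hichip(genome, truth,
                                n_replicates = config$n_hichip_replicates,
                                library_size = config$hichip_library_size,
                                min_span = config$min_span,
                                max_span = config$max_span,
                                seed = seed_of("hichip"))
      peaks <- lapply(seq_along(cond), function(ci) {
        lapply(seq_len(2), function(r) {
          generate_peaks(genome, truth, cond[ci],
                         seed = derive_seed(seed_of("peaks"), 10 * ci + r))
        })
      })
      names(peaks) <- cond
      rna <- generate_rna_counts(genome, truth,
                                 n_replicates = config$n_rna_replicates,
                                 seed = seed_of("rna"))
      write_truth(truth, file.path(outdir, "truth"))
      write_hichip_bedpe(hichip, file.path(outdir, "hichip"))
      for (ci in cond) {
        write_contact_matrix(hic[[ci]],
                             file.path(outdir, sprintf("hic_%s.coo.tsv", ci)))
        write_peaks_bed(peaks[[ci]][[1]]$h3k27ac,
                        file.path(outdir, sprintf("h3k27ac_%s_rep1.bed", ci)))
      }
      write_tsv(genome$genes, file.path(outdir, "genes.tsv"))
      write.table(rna, file.path(outdir, "rna_counts.tsv"), sep = "\t",
                  quote = FALSE)
      c(state, list(genome = genome, truth = truth, hic = hic,
                    hichip = hichip, peaks = peaks, rna = rna,
                    compartment_truth = comp))
    },
    "insulation" = {
      need("hic", "simulate")
      ins <- lapply(state$hic, insulation_score)
      bnd <- lapply(ins, call_boundaries)
      for (ci in names(bnd)) {
        write_bedgraph(as.numeric(ins[[ci]]), state$hic[[ci]]$chrom, bs,
                       file.path(outdir, sprintf("insulation_%s.bedgraph", ci)))
        write_boundaries_bed(bnd[[ci]], bs,
                             file.path(outdir, sprintf("boundaries_%s.bed", ci)))
      }
      c(state, list(insulation = ins, boundary_calls = bnd))
    },
    "compartments" = {
      need("hic", "simulate")
      compart <- lapply(state$hic, function(m) {
        prof <- compartment_eigenvector(m, bin_size = 100000L)
        write_bedgraph(prof$eigenvector, m$chrom, 100000L,
                       file.path(outdir, sprintf("eigenvector_%s.bedgraph",
                                                 m$chrom)))
        prof
      })
      c(state, list(compartments = compart))
    },
    "call-loops" = {
      need("hichip", "simulate")
      sim <- state$hichip
      calls <- lapply(cond, function(ci) {
        pooled <- rowSums(sim$counts[[ci]])
        bg <- estimate_background(sim$pairs, pooled, bin_size = bs)
        call_loops(sim$pairs, pooled, bg, fdr = config$loop_fdr_h3k27ac,
                   min_span = config$min_span, max_span = config$max_span,
                   bin_size = bs)
      })
      names(calls) <- cond
      for (ci in cond) {
        write_tsv(calls[[ci]], file.path(outdir, sprintf("loops_%s.tsv", ci)))
      }
      write_tsv(loop_qc_summary(calls)$counts,
                file.path(outdir, "loop_counts.tsv"))
      c(state, list(loop_calls = calls))
    },
    "annotate" = {
      need("loop_calls", "call-loops")
      k27 <- mean_peak_signal(state$peaks, cond)
      elements <- build_elements(state$genome$genes, k27,
                                 ctcf_peaks = peak_union(state$peaks, cond, "ctcf"))
      universe <- loop_universe(state$loop_calls)
      anchors <- unique(rbind(
        data.frame(chrom = universe$chrom, bin = universe$bin1),
        data.frame(chrom = universe$chrom, bin = universe$bin2)))
      ann <- annotate_anchors(anchors, elements, bin_size = bs)
      write_tsv(ann, file.path(outdir, "anchor_annotations.tsv"))
      write_tsv(elements$super_enhancers, file.path(outdir, "super_enhancers.tsv"))
      c(state, list(elements = elements, annotations = ann,
                    loop_universe = universe))
    },
    "diff-loops" = {
      need("loop_universe", "annotate")
      uni <- state$loop_universe
      sim <- state$hichip
      idx <- match(paste(uni$chrom, uni$bin1, uni$bin2),
                   paste(sim$pairs$chrom, sim$pairs$bin1, sim$pairs$bin2))
      ca <- sim$counts[[cond[1]]][idx, , drop = FALSE]
      cb <- sim$counts[[cond[2]]][idx, , drop = FALSE]
      rownames(ca) <- rownames(cb) <- uni$loop_id
      res <- nb_wald(ca, cb)
      res <- classify_loop_records(res, config$thresholds)
      res <- cbind(uni[, c("loop_id", "chrom", "bin1", "bin2")],
                   res[, setdiff(names(res), "feature_id")])
      write_tsv(res, file.path(outdir, "differential_loops.tsv"))
      c(state, list(diff_loops = res))
    },
    "diff-anchors" = {
      need("annotations", "annotate")
      ann <- state$annotations
      sig <- lapply(cond, function(ci) {
        vapply(state$peaks[[ci]], function(pk) {
          anchor_signal(ann, pk$h3k27ac, bin_size = bs)
        }, numeric(nrow(ann)))
      })
      names(sig) <- cond
      rownames(sig[[1]]) <- rownames(sig[[2]]) <- ann$anchor_id
      res <- nb_wald(round(sig[[1]]), round(sig[[2]]), size_factors = 1)
      res <- classify_enhancer_records(res, config$thresholds)
      res$anchor_id <- ann$anchor_id
      write_tsv(res, file.path(outdir, "differential_anchors.tsv"))
      c(state, list(diff_anchors = res))
    },
    "diff-expression" = {
      need("rna", "simulate")
      res <- differential_expression(state$rna, attr(state$rna, "conditions"),
                                     contrast = cond,
                                     thresholds = config$thresholds)
      write_tsv(res, file.path(outdir, "differential_expression.tsv"))
      c(state, list(diff_rna = res))
    },
    "modes" = {
      need("diff_loops", "diff-loops"); need("diff_anchors", "diff-anchors")
      need("diff_rna", "diff-expression")
      enh_cls <- state$diff_anchors[, c("anchor_id", "class")]
      asg <- assign_modes(state$diff_loops, enh_cls, state$annotations)
      mode_tab <- mode_expression_test(asg, state$diff_rna)
      write_tsv(asg, file.path(outdir, "mode_assignments.tsv"))
      write_tsv(mode_tab, file.path(outdir, "mode_summary.tsv"))
      jsonlite::write_json(mode_tab, file.path(outdir, "mode_summary.json"),
                           dataframe = "rows", auto_unbox = TRUE, digits = NA)
      c(state, list(mode_assignments = asg, mode_summary = mode_tab))
    },
    "boundaries" = {
      need("diff_loops", "diff-loops"); need("boundary_calls", "insulation")
      need("diff_rna", "diff-expression")
      gained <- state$diff_loops[state$diff_loops$class == "gained", ,
                                 drop = FALSE]
      rep_ <- boundary_crossing_report(gained,
                                       state$boundary_calls[[cond[1]]],
                                       state$diff_rna, state$annotations)
      jsonlite::write_json(
        list(fraction_across = rep_$fraction_across,
             n_across = rep_$n_across, n_within = rep_$n_within),
        file.path(outdir, "boundary_crossing.json"), auto_unbox = TRUE,
        digits = NA)
      c(state, list(crossing_report = rep_))
    },
    "tf-targets" = {
      need("elements", "annotate")
      tf <- state$peaks[[cond[2]]][[1]]$tf
      tt <- assign_tf_targets(tf, state$elements,
                              state$loop_universe, state$annotations,
                              bin_size = bs)
      write_tsv(tt, file.path(outdir, "tf_targets.tsv"))
      c(state, list(tf_targets = tt))
    },
    "enrich" = {
      need("diff_loops", "diff-loops")
      gained <- state$diff_loops[state$diff_loops$class == "gained", ,
                                 drop = FALSE]
      uni <- state$loop_universe
      universe <- anchor_regions(uni, bs)
      query <- anchor_regions(gained, bs)
      tf <- state$peaks[[cond[2]]][[1]]$tf
      enr <- region_set_enrichment(query, tf, universe)
      jsonlite::write_json(list(odds_ratio = enr$odds_ratio, p = enr$p),
                           file.path(outdir, "tf_enrichment.json"),
                           auto_unbox = TRUE, digits = NA)
      c(state, list(tf_enrichment = enr))
    },
    "v4c" = {
      need("loop_calls", "call-loops")
      genes_i <- state$truth$gene_modes$gene_id[
        state$truth$gene_modes$mode == "i"]
      genes_i <- head(genes_i, 3)
      tracks <- lapply(genes_i, function(g) {
        gr <- state$genome$genes[state$genome$genes$gene_id == g, ]
        tr <- virtual_4c(state$loop_calls[[cond[2]]],
                         list(chrom = gr$chrom, pos = gr$tss),
                         chrom_length = config$chrom_length,
                         bin_size = bs)
        f <- file.path(outdir, sprintf("v4c_%s_%s.bedgraph", g, cond[2]))
        write_bedgraph(replace(rep(NA_real_, max(tr$bin)), tr$bin, tr$value),
                       gr$chrom, bs, f)
        tr
      })
      names(tracks) <- genes_i
      c(state, list(v4c_tracks = tracks))
    },
    "cliques" = {
      need("loop_calls", "call-loops")
      cliques <- lapply(cond, function(ci) {
        g <- build_clique_graph(state$loop_calls[[ci]])
        if (igraph::vcount(g) == 0) {
          return(list(graph = g, membership = integer(0),
                      modularity = NA_real_, connectivity = NULL))
        }
        lv <- louvain_communities(g, seed = seed_of("louvain"))
        conn <- clique_connectivity(g, lv$membership)
        write_tsv(conn, file.path(outdir, sprintf("cliques_%s.tsv", ci)))
        list(graph = g, membership = lv$membership,
             modularity = lv$modularity, connectivity = conn)
      })
      names(cliques) <- cond
      c(state, list(cliques = cliques))
    },
    "report" = {
      need("mode_assignments", "modes"); need("crossing_report", "boundaries")
      rec <- recovery_report(state, config)
      jsonlite::write_json(rec, file.path(outdir, "recovery_report.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      write_manifest(config, outdir)
      c(state, list(recovery = rec))
    },
    stop(sprintf("unknown stage '%s'", stage))
  )
  invisible(state)
}

# mean H3K27ac peak signal across conditions/replicates (intervals are
# condition-invariant in the generator)
mean_peak_signal <- function(peaks, cond) {
  base <- peaks[[cond[1]]][[1]]$h3k27ac
  sigs <- lapply(cond, function(ci) {
    vapply(peaks[[ci]], function(pk) pk$h3k27ac$signal,
           numeric(nrow(base)))
  })
  base$signal <- rowMeans(do.call(cbind, sigs))
  base
}

peak_union <- function(peaks, cond, what) peaks[[cond[1]]][[1]][[what]]

# union of per-condition loop calls (significant in at least one condition)
loop_universe <- function(calls) {
  uni <- unique(do.call(rbind, lapply(calls, function(x) {
    x[, c("chrom", "bin1", "bin2")]
  })))
  uni <- uni[order(uni$chrom, uni$bin1, uni$bin2), ]
  uni$loop_id <- sprintf("loop_%05d", seq_len(nrow(uni)))
  rownames(uni) <- NULL
  uni
}

anchor_regions <- function(loops, bin_size) {
  bins <- unique(rbind(data.frame(chrom = loops$chrom, bin = loops$bin1),
                       data.frame(chrom = loops$chrom, bin = loops$bin2)))
  data.frame(chrom = bins$chrom, start = bin_start(bins$bin, bin_size),
             end = bin_start(bins$bin, bin_size) + bin_size)
}

#' Run the full pipeline
#'
#' Executes every stage in order on a fresh state and writes all outputs,
#' a recovery report against the planted truth, and a manifest under
#' `outdir`.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory.
#' @return The final state list (invisibly), with the recovery report in
#'   `$recovery`.
#' @export
run_all <- function(config = pipeline_config(), outdir = tempfile("loopscape_")) {
  stages <- c("simulate", "insulation", "compartments", "call-loops",
              "annotate", "diff-loops", "diff-anchors", "diff-expression",
              "modes", "boundaries", "tf-targets", "enrich", "v4c",
              "cliques", "report")
  state <- NULL
  for (s in stages) {
    message(sprintf("[loopscape] stage %s", s))
    state <- run_stage(s, config, state, outdir)
  }
  invisible(state)
}

# recovery metrics against planted truth
recovery_report <- function(state, config) {
  truth <- state$truth
  cond <- config$conditions
  bs <- config$bin_size

  # boundaries (reference condition)
  bnd <- state$boundary_calls[[cond[1]]]
  planted <- truth$boundaries$bin
  matched <- vapply(planted, function(b) any(abs(bnd$bin - b) <= 3),
                    logical(1))
  spurious <- sum(vapply(bnd$bin, function(b) all(abs(planted - b) > 3),
                         logical(1)))

  # loop recovery per condition (planted enrichment >= 5x in the condition)
  loop_rec <- lapply(cond, function(ci) {
    mult <- truth$loops[[paste0("mult_", ci)]] * truth$loops$base_strength
    strong <- truth$loops[mult >= 5, , drop = FALSE]
    calls <- state$loop_calls[[ci]]
    key <- paste(calls$chrom, calls$bin1, calls$bin2)
    found <- paste(strong$chrom, strong$bin1, strong$bin2) %in% key
    tk <- paste(truth$loops$chrom, truth$loops$bin1, truth$loops$bin2)
    false_calls <- sum(!key %in% tk)
    list(recall = mean(found), n_true = nrow(strong),
         n_called = nrow(calls), false_calls = false_calls)
  })
  names(loop_rec) <- cond

  # mode recovery (gene-level)
  asg <- state$mode_assignments
  tm <- truth$gene_modes
  modes <- c("i", "ii", "iii", "iv", "v", "vi")
  mode_stats <- do.call(rbind, lapply(modes, function(m) {
    assigned <- unique(asg$gene_id[asg$mode == m])
    true_g <- tm$gene_id[tm$mode == m]
    tp <- length(intersect(assigned, true_g))
    data.frame(mode = m,
               precision = if (length(assigned)) tp / length(assigned) else NA,
               recall = if (length(true_g)) tp / length(true_g) else NA,
               n_assigned = length(assigned), n_true = length(true_g))
  }))

  # differential expression recovery for strongly planted genes
  de <- state$diff_rna
  strong_up <- tm$gene_id[tm$planted_log2fc >= 1]
  strong_dn <- tm$gene_id[tm$planted_log2fc <= -1]
  de_up <- mean(de$direction[match(strong_up, de$feature_id)] == "up")
  de_dn <- mean(de$direction[match(strong_dn, de$feature_id)] == "down")

  comp_cor <- vapply(state$compartments, function(pr) {
    tr <- state$compartment_truth
    tr100 <- tapply(tr, ((seq_along(tr) - 1) %/% 10) + 1, mean)
    ev <- pr$eigenvector
    n <- min(length(ev), length(tr100))
    abs(cor(ev[seq_len(n)], tr100[seq_len(n)], use = "complete.obs"))
  }, numeric(1))

  list(
    boundary = list(recall = mean(matched), n_planted = length(planted),
                    n_called = nrow(bnd), spurious = spurious),
    loops = loop_rec,
    modes = mode_stats,
    mode_summary = state$mode_summary,
    crossing_fraction = state$crossing_report$fraction_across,
    de_recovery = list(up = de_up, down = de_dn),
    compartment_abs_cor = comp_cor,
    n_super_enhancers = sum(state$elements$super_enhancers$se),
    tf_target_classes = as.list(table(state$tf_targets$class))
  )
}

# manifest of outputs: md5, size, plus the full parameter echo
write_manifest <- function(config, outdir) {
  files <- list.files(outdir, recursive = TRUE)
  files <- setdiff(files, "manifest.json")
  info <- lapply(files, function(f) {
    path <- file.path(outdir, f)
    list(file = f, md5 = unname(tools::md5sum(path)),
         bytes = file.info(path)$size)
  })
  cfg <- config
  cfg$thresholds <- unclass(cfg$thresholds)
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("loopscape")),
         seed = config$seed, parameters = unclass(cfg), outputs = info),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(file.path(outdir, "manifest.json"))
}
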