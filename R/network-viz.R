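# Virtual 4C viewpoint tracks and 3D-clique (anchor-loop) graph analysis.

#' Extract a virtual 4C track
#'
#' For a viewpoint position, the track value at every bin in the window is
#' the `-log10(q)` of the loop joining the viewpoint bin to that bin (0 when
#' no loop), or the loop's count in `counts` mode. Loops contribute
#' regardless of anchor order; loops not touching the viewpoint bin are
#' ignored.
#'
#' @param calls Loop calls with chrom, bin1, bin2, q (and count for
#'   `counts` mode).
#' @param viewpoint List or data.frame row with `chrom` and `pos` (bp; e.g.
#'   a gene TSS).
#' @param chrom_length Length of the viewpoint chromosome (bp), for bounds
#'   checking.
#' @param window Half-window around the viewpoint (bp).
#' @param mode `"neglog10q"` or `"counts"`.
#' @param bin_size Bin width in bp.
#' @param norm_factor Division factor applied in `counts` mode (e.g. mean
#'   library size in millions); default 1.
#' @return data.frame of class `v4c_track`: chrom, bin, start, end, value;
#'   attributes `viewpoint_bin`, `mode`.
#' @export
virtual_4c <- function(calls, viewpoint, chrom_length, window = 1e6,
                       mode = c("neglog10q", "counts"), bin_size = 10000L,
                       norm_factor = 1) {
  mode <- match.arg(mode)
  if (viewpoint$pos < 0 || viewpoint$pos >= chrom_length) {
    stop("viewpoint outside the chromosome")
  }
  vb <- pos_to_bin(viewpoint$pos, bin_size)
  nb <- n_bins(chrom_length, bin_size)
  lo <- max(1L, vb - as.integer(window / bin_size))
  hi <- min(nb, vb + as.integer(window / bin_size))
  bins <- seq.int(lo, hi)
  values <- numeric(length(bins))
  sel <- calls$chrom == viewpoint$chrom &
    (calls$bin1 == vb | calls$bin2 == vb)
  hits <- calls[sel, , drop = FALSE]
  if (nrow(hits)) {
    other <- ifelse(hits$bin1 == vb, hits$bin2, hits$bin1)
    val <- if (mode == "neglog10q") {
      -log10(pmax(hits$q, .Machine$double.xmin))
    } else {
      hits$count / norm_factor
    }
    for (j in seq_along(other)) {
      k <- match(other[j], bins)
      if (!is.na(k)) values[k] <- max(values[k], val[j])
    }
  }
  out <- data.frame(chrom = viewpoint$chrom, bin = bins,
                    start = bin_start(bins, bin_size),
                    end = bin_start(bins, bin_size) + bin_size,
                    value = values)
  class(out) <- c("v4c_track", "data.frame")
  attr(out, "viewpoint_bin") <- vb
  attr(out, "mode") <- mode
  out
}

#' Build the anchor-loop (3D clique) graph
#'
#' An undirected graph whose vertices are loop anchors and whose edges are
#' loops with `-log10(q)` at or above the threshold; edge weight is the
#' `-log10(q)`. Isolated anchors are excluded. An optional per-anchor
#' H3K27ac signal is attached as a vertex attribute.
#'
#' @param calls Loop calls with chrom, bin1, bin2, neglog10q.
#' @param neglog10q_min Edge inclusion threshold (default 5).
#' @param anchor_signal Optional data.frame with anchor_id, signal.
#' @return An `igraph` graph with vertex attribute `signal` and edge
#'   attribute `weight`.
#' @export
build_clique_graph <- function(calls, neglog10q_min = 5,
                               anchor_signal = NULL) {
  keep <- calls[calls$neglog10q >= neglog10q_min, , drop = FALSE]
  if (nrow(keep) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges <- data.frame(
    from = anchor_key(keep$chrom, keep$bin1),
    to = anchor_key(keep$chrom, keep$bin2),
    weight = keep$neglog10q)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (!is.null(anchor_signal)) {
    sig <- setNames(anchor_signal$signal, anchor_signal$anchor_id)
    v <- igraph::V(g)$name
    igraph::V(g)$signal <- unname(sig[v])
  }
  g
}

#' Louvain communities of an anchor-loop graph
#'
#' Runs multilevel (Louvain) modularity optimization with default
#' parameters. The heuristic depends on a randomized vertex order, so it is
#' restarted `restarts` times under seeds derived from `seed` and the
#' highest-modularity partition is kept; the result is deterministic for a
#' fixed seed.
#'
#' @param graph An `igraph` graph (edge weights used when present).
#' @param seed Integer seed.
#' @param restarts Number of seeded restarts (default 10).
#' @return List: `membership` (named integer vector), `modularity`
#'   (numeric), `communities` (the igraph communities object).
#' @export
louvain_communities <- function(graph, seed = 1L, restarts = 10L) {
  if (igraph::vcount(graph) == 0) {
    return(list(membership = integer(0), modularity = NA_real_,
                communities = NULL))
  }
  best <- NULL; best_mod <- -Inf
  for (r in seq_len(restarts)) {
    cl <- withr::with_seed(derive_seed(seed, r), igraph::cluster_louvain(graph))
    m <- max(cl$modularity)
    if (m > best_mod) { best_mod <- m; best <- cl }
  }
  list(membership = igraph::membership(best),
       modularity = best_mod,
       communities = best)
}

#' Intra-community edge counts (clique connectivity)
#'
#' The connectivity of a community is the number of edges with both
#' endpoints inside it; edges between communities are excluded.
#'
#' @param graph An `igraph` graph.
#' @param membership Named or positional community membership vector.
#' @return data.frame: community, n_nodes, connectivity.
#' @export
clique_connectivity <- function(graph, membership) {
  el <- igraph::as_edgelist(graph, names = TRUE)
  m <- membership
  if (is.null(names(m))) names(m) <- igraph::V(graph)$name
  comm <- sort(unique(as.integer(m)))
  conn <- vapply(comm, function(cm) {
    sum(m[el[, 1]] == cm & m[el[, 2]] == cm)
  }, numeric(1))
  sizes <- vapply(comm, function(cm) sum(m == cm), numeric(1))
  data.frame(community = comm, n_nodes = as.integer(sizes),
             connectivity = as.integer(conn))
}
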