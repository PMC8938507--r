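#' Shared-nearest-neighbor graph in PC space
#'
#' Exact Euclidean k-nearest neighbors (ties at the k-th distance broken by
#' lowest cell index, so the graph is a deterministic function of the
#' coordinates), followed by shared-nearest-neighbor edge weights: the
#' Jaccard overlap of the two cells' neighbor sets (each set includes the
#' cell itself). Edges with weight below `prune` are dropped.
#'
#' @param pca a [scale_and_pca()] result (or a cells x dims matrix).
#' @param k neighbors per cell (default 20).
#' @param prune SNN weight threshold (default 1/15).
#' @param n_dims number of leading components to use (default all).
#' @return object of class `snn_graph`: `knn` (cells x k index matrix),
#'   `snn` (sparse symmetric weight matrix), `k`, `prune`.
#' @export
build_snn_graph <- function(pca, k = 20, prune = 1 / 15, n_dims = NULL) {
  coords <- if (inherits(pca, "pca_space")) pca$coords else as.matrix(pca)
  if (!is.null(n_dims)) coords <- coords[, seq_len(n_dims), drop = FALSE]
  n <- nrow(coords)
  if (k >= n) abort("k must be smaller than the number of cells")
  d <- as.matrix(stats::dist(coords))
  # self is always the first neighbor (distance 0, lowest index tie-break)
  knn <- t(apply(d, 1, function(row) order(row)[seq_len(k)]))
  rownames(knn) <- rownames(coords)

  member <- Matrix::sparseMatrix(
    i = rep(seq_len(n), each = k), j = as.vector(t(knn)), x = 1,
    dims = c(n, n)
  )
  shared <- Matrix::tcrossprod(member) # |N_i intersect N_j|
  jac <- shared
  jac@x <- jac@x / (2 * k - jac@x) # |union| = 2k - |intersection|
  jac <- jac * (jac >= prune)
  Matrix::diag(jac) <- 0
  jac <- Matrix::drop0(jac)
  dimnames(jac) <- list(rownames(coords), rownames(coords))
  structure(
    list(knn = knn, snn = jac, k = k, prune = prune,
         cell_ids = rownames(coords)),
    class = "snn_graph"
  )
}

#' @export
print.snn_graph <- function(x, ...) {
  cat("<snn_graph> ", nrow(x$knn), " cells, k = ", x$k, ", ",
    length(x$snn@x), " SNN edges (prune ", signif(x$prune, 3), ")\n",
    sep = ""
  )
  invisible(x)
}

#' Louvain clustering of the SNN graph
#'
#' Modularity optimization (Louvain, with a resolution parameter) on the
#' weighted SNN graph; deterministic given the seed.
#'
#' @param graph a [build_snn_graph()] result.
#' @param resolution modularity resolution (default 0.8).
#' @param seed integer seed.
#' @return tibble of class `cluster_assignment` (`cell_id`, `cluster`
#'   0-based contiguous integer); resolution, achieved modularity and seed
#'   kept as attributes.
#' @export
cluster_louvain <- function(graph, resolution = 0.8, seed = 1L) {
  stopifnot(inherits(graph, "snn_graph"))
  if (length(graph$snn@x) == 0) abort("empty graph: no SNN edges")
  g <- igraph::graph_from_adjacency_matrix(
    graph$snn, mode = "undirected", weighted = TRUE
  )
  res <- withr::with_seed(seed, {
    igraph::cluster_louvain(g, resolution = resolution)
  })
  cl <- as.integer(igraph::membership(res)) - 1L
  out <- tibble(cell_id = graph$cell_ids, cluster = cl)
  structure(
    out,
    class = c("cluster_assignment", class(out)),
    resolution = resolution,
    modularity = max(igraph::modularity(res)),
    seed = seed
  )
}

#' Seeded 2-D t-SNE embedding
#'
#' Visualization-only stochastic neighbor embedding of the (batch-adjusted)
#' PC coordinates; identical seed gives identical output.
#'
#' @param pca a [scale_and_pca()] result (or matrix).
#' @param seed integer seed.
#' @param perplexity t-SNE perplexity (default 30; requires
#'   `n_cells > 3 * perplexity`).
#' @param n_dims leading components to use (default all).
#' @return tibble of class `embedding_2d` (`cell_id`, `tsne1`, `tsne2`).
#' @export
embed_tsne <- function(pca, seed = 1L, perplexity = 30, n_dims = NULL) {
  coords <- if (inherits(pca, "pca_space")) pca$coords else as.matrix(pca)
  if (!is.null(n_dims)) coords <- coords[, seq_len(n_dims), drop = FALSE]
  if (nrow(coords) <= 3 * perplexity) {
    abort("need n_cells > 3 * perplexity")
  }
  if (all(apply(coords, 2, sd) == 0)) abort("degenerate input: all cells identical")
  emb <- withr::with_seed(seed, {
    Rtsne::Rtsne(coords,
      dims = 2, perplexity = perplexity, pca = FALSE,
      check_duplicates = FALSE
    )$Y
  })
  out <- tibble(
    cell_id = rownames(coords), tsne1 = emb[, 1], tsne2 = emb[, 2]
  )
  structure(out,
    class = c("embedding_2d", class(out)),
    seed = seed, perplexity = perplexity, method = "tsne"
  )
}

#' Annotate clusters by mean signature score
#'
#' Labels each cluster with the signature whose mean per-cell score is
#' highest in that cluster; when the margin between the top two signatures
#' falls below `min_margin` the cluster is labelled `"unresolved"`.
#'
#' @param assign a [cluster_louvain()] result.
#' @param scores data frame with columns `cell_id`, `signature`, `score`
#'   (e.g. the `score` column of [signature_score()] results bound together).
#' @param min_margin minimum top-2 margin for a confident label (default 0).
#' @return tibble of class `cluster_annotation`: `cluster`, `label`,
#'   `margin`, plus one mean-score column per signature.
#' @export
annotate_clusters <- function(assign, scores, min_margin = 0) {
  stopifnot(
    inherits(assign, "cluster_assignment"),
    all(c("cell_id", "signature", "score") %in% names(scores)),
    length(unique(scores$signature)) >= 1
  )
  means <- scores |>
    dplyr::inner_join(as_tibble(assign), by = "cell_id") |>
    dplyr::group_by(.data$cluster, .data$signature) |>
    dplyr::summarise(mean_score = mean(.data$score), .groups = "drop")
  lab <- means |>
    dplyr::group_by(.data$cluster) |>
    dplyr::arrange(dplyr::desc(.data$mean_score), .by_group = TRUE) |>
    dplyr::summarise(
      label = .data$signature[1],
      margin = if (dplyr::n() > 1) {
        .data$mean_score[1] - .data$mean_score[2]
      } else {
        Inf
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(
      # an exact tie is never resolvable, whatever the margin setting
      label = ifelse(.data$margin < min_margin | .data$margin == 0,
        "unresolved", .data$label
      )
    )
  wide <- means |>
    tidyr::pivot_wider(
      names_from = "signature", values_from = "mean_score",
      names_prefix = "mean_"
    )
  out <- dplyr::left_join(lab, wide, by = "cluster")
  structure(out,
    class = c("cluster_annotation", class(out)),
    min_margin = min_margin
  )
}
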