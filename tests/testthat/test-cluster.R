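blob_coords <- function(centers, n_each, sd = 0.2, seed = 1) {
  withr::with_seed(seed, {
    pts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
      matrix(rnorm(n_each * ncol(centers), sd = sd), n_each) +
        matrix(centers[i, ], n_each, ncol(centers), byrow = TRUE)
    }))
    rownames(pts) <- sprintf("c%03d", seq_len(nrow(pts)))
    pts
  })
}

test_that("kNN sets match a brute-force all-pairs computation", {
  set.seed(11)
  x <- matrix(rnorm(200 * 5), 200, 5)
  rownames(x) <- sprintf("c%03d", 1:200)
  g <- build_snn_graph(x, k = 10)
  d <- as.matrix(dist(x))
  for (i in sample(200, 25)) {
    expect_setequal(g$knn[i, ], order(d[i, ])[1:10])
  }
})

test_that("SNN weights are valid Jaccard overlaps", {
  set.seed(12)
  x <- matrix(rnorm(80 * 4), 80, 4)
  rownames(x) <- sprintf("c%02d", 1:80)
  # duplicate a cell: the pair must be mutual NNs with maximal overlap
  x[2, ] <- x[1, ]
  g <- build_snn_graph(x, k = 8)
  expect_true(2 %in% g$knn[1, ] && 1 %in% g$knn[2, ])
  expect_identical(max(g$snn@x), max(g$snn[1, 2], 0))
  expect_true(all(g$snn@x >= 0 & g$snn@x <= 1))
  expect_identical(sum(Matrix::diag(g$snn)), 0) # no self edges
  expect_lt(max(abs(g$snn - Matrix::t(g$snn))), 1e-15) # symmetric
  # graph construction is invariant to cell order (same sets recovered)
  perm <- sample(80)
  g2 <- build_snn_graph(x[perm, ], k = 8)
  ord <- match(rownames(x), rownames(x[perm, ]))
  expect_identical(
    as.matrix(g2$snn[ord, ord]) > 0, as.matrix(g$snn) > 0
  )
})

test_that("two fully connected components produce exactly two clusters", {
  centers <- rbind(c(0, 0), c(100, 100))
  x <- blob_coords(centers, 20, seed = 3)
  # k = blob size: every cell's neighbor set is exactly its own component,
  # giving two complete components with SNN weight 1 and no cross edges
  g <- build_snn_graph(x, k = 20)
  expect_true(all(g$snn@x == 1))
  cl <- cluster_louvain(g, seed = 5)
  expect_identical(length(unique(cl$cluster)), 2L)
  expect_identical(length(unique(cl$cluster[1:20])), 1L)
  expect_identical(length(unique(cl$cluster[21:40])), 1L)
})

test_that("achieved modularity beats random same-sized partitions", {
  centers <- rbind(c(0, 0), c(6, 0), c(0, 6))
  x <- blob_coords(centers, 30, sd = 1, seed = 4)
  g <- build_snn_graph(x, k = 10)
  cl <- cluster_louvain(g, seed = 6)
  ig <- igraph::graph_from_adjacency_matrix(g$snn,
    mode = "undirected", weighted = TRUE
  )
  sizes <- table(cl$cluster)
  rand_mod <- withr::with_seed(7, {
    vapply(1:100, function(i) {
      igraph::modularity(ig, sample(rep(seq_along(sizes), sizes)))
    }, 0)
  })
  expect_gte(attr(cl, "modularity"), max(rand_mod))
})

test_that("clustering and cluster ids are deterministic given the seed", {
  centers <- rbind(c(0, 0), c(5, 0), c(0, 5))
  x <- blob_coords(centers, 20, sd = 0.8, seed = 8)
  g <- build_snn_graph(x, k = 8)
  c1 <- cluster_louvain(g, seed = 9)
  c2 <- cluster_louvain(g, seed = 9)
  expect_identical(c1$cluster, c2$cluster)
  expect_identical(sort(unique(c1$cluster)), seq_along(unique(c1$cluster)) - 1L)
})

test_that("planted well-separated blobs are recovered by clustering", {
  centers <- 8 * diag(5)
  x <- blob_coords(centers, 30, sd = 0.5, seed = 10)
  g <- build_snn_graph(x, k = 12)
  cl <- cluster_louvain(g, seed = 11)
  truth <- rep(1:5, each = 30)
  expect_gte(ari(cl$cluster, truth), 0.9)
})

test_that("the t-SNE embedding is seeded, finite and separates planted blobs", {
  centers <- rbind(c(0, 0, 0), c(40, 0, 0))
  x <- blob_coords(centers, 60, sd = 0.5, seed = 12)
  e1 <- embed_tsne(x, seed = 13, perplexity = 12)
  e2 <- embed_tsne(x, seed = 13, perplexity = 12)
  expect_identical(e1, e2)
  expect_true(all(is.finite(c(e1$tsne1, e1$tsne2))))
  emb <- cbind(e1$tsne1, e1$tsne2)
  blob <- rep(1:2, each = 60)
  d <- as.matrix(dist(emb))
  intra <- mean(d[blob == 1, blob == 1])
  inter <- mean(d[blob == 1, blob == 2])
  expect_gt(inter, intra)
  # degenerate input is rejected
  same <- matrix(0, 100, 3, dimnames = list(sprintf("c%03d", 1:100), NULL))
  expect_error(embed_tsne(same, seed = 1, perplexity = 10), "degenerate")
})

test_that("cluster annotation picks dominant programs and flags ties", {
  assign <- structure(
    tibble::tibble(
      cell_id = sprintf("c%02d", 1:40),
      cluster = rep(0:1, each = 20)
    ),
    class = c("cluster_assignment", class(tibble::tibble())),
    resolution = 0.8, modularity = NA, seed = 1
  )
  scores <- dplyr::bind_rows(
    tibble::tibble(
      cell_id = sprintf("c%02d", 1:40), signature = "stem",
      score = rep(c(2, 0.1), each = 20)
    ),
    tibble::tibble(
      cell_id = sprintf("c%02d", 1:40), signature = "secretory",
      score = rep(c(0.3, 1.4), each = 20)
    )
  )
  ann <- annotate_clusters(assign, scores)
  expect_identical(ann$label[ann$cluster == 0], "stem")
  expect_identical(ann$label[ann$cluster == 1], "secretory")

  # exact tie -> unresolved
  tied <- scores
  tied$score[tied$signature == "secretory"] <- rep(c(2, 0.1), each = 20)
  ann_tie <- annotate_clusters(assign, tied)
  expect_true(all(ann_tie$label == "unresolved"))

  # single cluster, single signature -> that label
  one <- assign
  one$cluster <- 0L
  ann_one <- annotate_clusters(one, scores[scores$signature == "stem", ])
  expect_identical(ann_one$label, "stem")

  # margin below the configured minimum -> unresolved
  ann_margin <- annotate_clusters(assign, scores, min_margin = 10)
  expect_true(all(ann_margin$label == "unresolved"))
})

test_that("annotation recovers planted cell types on simulated data", {
  cfg <- default_sim_config(seed = 3)
  sim <- simulate_counts(cfg)
  norm <- normalize_log(sim$counts)
  hvg <- find_variable_genes(norm)
  pca <- scale_and_pca(norm, hvg, n_components = 15)
  pca <- batch_adjust(pca, norm$cell_meta$replicate)
  g <- build_snn_graph(pca, k = 20)
  cl <- cluster_louvain(g, seed = 4)
  # marker-block signatures, one per planted type
  types <- c("stem", "progenitor", "enterocyte", "secretory", "revival")
  sigs <- lapply(seq_along(types), function(i) {
    gene_signature(types[i], sprintf("g%04d", ((i - 1) * 40 + 1):(i * 40)))
  })
  scores <- score_signatures(norm, sigs)
  ann <- annotate_clusters(cl, scores)
  truth <- sim$truth$cells
  labelled <- dplyr::left_join(tidy(cl), ann[, c("cluster", "label")],
    by = "cluster"
  ) |>
    dplyr::left_join(truth[, c("cell_id", "cell_type")], by = "cell_id")
  expect_gte(mean(labelled$label == labelled$cell_type), 0.9)
})
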