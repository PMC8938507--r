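test_that("gene-count QC bounds are inclusive at 200 and 5000", {
  n_genes <- 5001
  detected <- c(199, 200, 5000, 5001)
  m <- Matrix::sparseMatrix(
    i = unlist(lapply(detected, seq_len)),
    j = rep(seq_along(detected), detected),
    x = 1,
    dims = c(n_genes, 4),
    dimnames = list(sprintf("g%04d", 1:n_genes), sprintf("c%d", 1:4))
  )
  res <- qc_filter(umi_counts(m))
  expect_identical(colnames(res$counts$counts), c("c2", "c3"))
  expect_identical(res$report$kept, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("cells above 10% mitochondrial UMIs are discarded", {
  m <- matrix(0, 300, 3)
  m[1:250, ] <- 1 # 250 detected genes everywhere
  m[251:300, 1] <- 0 # cell 1: 0 mito of 250
  m[251:281, 2] <- 1 # cell 2: 31 mito / 281 total = 11.0%
  m[251:277, 3] <- 1 # cell 3: 27 mito / 277 total = 9.7%
  rn <- c(sprintf("g%03d", 1:250), sprintf("mt-g%03d", 1:50))
  dimnames(m) <- list(rn, c("c1", "c2", "c3"))
  res <- qc_filter(umi_counts(m), min_genes = 10, max_mito_fraction = 0.10)
  expect_identical(colnames(res$counts$counts), c("c1", "c3"))
  # exactly 10% is kept (only > 10% discarded)
  m2 <- m[, 1, drop = FALSE]
  m2[251:275, 1] <- 1 # 25 mito / 250 non-mito + 25 = 9.09%... recompute below
  frac <- sum(m2[251:300, 1]) / sum(m2[, 1])
  res2 <- qc_filter(umi_counts(m2), min_genes = 10, max_mito_fraction = frac)
  expect_true(res2$report$kept[1])
})

test_that("planted QC failures are removed and genes are never dropped", {
  cfg <- two_type_config(n_genes = 400, n_per = 50, seed = 17)
  sim <- simulate_counts(cfg)
  m <- as.matrix(sim$counts$counts)
  # plant exactly 7 failing cells: wipe all but 5 genes
  fail <- c(3, 19, 33, 47, 61, 77, 94)
  m[6:400, fail] <- 0
  x <- counts_from_matrix(m)
  res <- qc_filter(x, min_genes = 50, max_genes = 5000)
  expect_identical(ncol(res$counts$counts), 93L)
  expect_identical(nrow(res$counts$counts), 400L)
  expect_setequal(which(!res$report$kept), fail)

  # idempotent, and invariant to cell order
  res_again <- qc_filter(res$counts, min_genes = 50, max_genes = 5000)
  expect_identical(
    as.matrix(res_again$counts$counts), as.matrix(res$counts$counts)
  )
  perm <- sample(ncol(m))
  res_perm <- qc_filter(counts_from_matrix(m[, perm]),
    min_genes = 50, max_genes = 5000
  )
  expect_setequal(
    colnames(res_perm$counts$counts), colnames(res$counts$counts)
  )
})

test_that("normalization matches the log1p formula and preserves structure", {
  set.seed(1)
  m <- matrix(rpois(50 * 20, 5), 50, 20)
  m[1, ] <- 0
  x <- counts_from_matrix(m)
  norm <- normalize_log(x)
  # direct one-line recomputation
  expected <- log1p(1e4 * sweep(m, 2, colSums(m), "/"))
  expect_lt(max(abs(norm$values - expected)), 1e-12)
  # zeros preserved
  expect_true(all(norm$values[m == 0] == 0))
  # within-cell rank order preserved
  for (j in c(1, 10)) {
    expect_identical(unname(rank(norm$values[, j])), rank(m[, j]))
  }
  # unit case: cell total = scale factor, count 1 -> log(2)
  m2 <- matrix(c(1, 9999), 2, 1)
  norm2 <- normalize_log(counts_from_matrix(m2))
  expect_equal(norm2$values[1, 1], log(2), tolerance = 1e-12)
})

test_that("identically distributed genes are never called variable", {
  set.seed(2)
  base <- rpois(30, 8)
  y <- log1p(matrix(rep(base, each = 40), nrow = 40) * 0.5)
  norm <- norm_from_values(y)
  hvg <- find_variable_genes(norm)
  expect_identical(sum(hvg$selected), 0L)
})

test_that("variable-gene selection matches brute-force binned dispersion", {
  set.seed(3)
  n_cells <- 200
  y <- log1p(matrix(rpois(100 * n_cells, 3), 100, n_cells))
  # plant an overdispersed gene at the same mean as its bin peers
  y[7, ] <- log1p(rpois(n_cells, rep(c(0.5, 5.5), length.out = n_cells)))
  # and one high-dispersion gene below the expression cutoff
  y[13, ] <- log1p(rpois(n_cells, 0.08) * 5)
  norm <- norm_from_values(y)
  hvg <- find_variable_genes(norm)
  expect_true("g007" %in% hvg$gene_id[hvg$selected])
  expect_false("g013" %in% hvg$gene_id[hvg$selected])
  expect_lt(hvg$mean[hvg$gene_id == "g013"], 0.5)
  expect_identical(
    sort(hvg$gene_id[hvg$selected]),
    sort(brute_hvg(norm$values))
  )
})

test_that("PCA is exact on low-rank input and reconstructs the scaled matrix", {
  set.seed(4)
  u <- matrix(rnorm(60 * 2), 60, 2)
  v <- matrix(rnorm(2 * 30), 2, 30)
  y <- u %*% v + 5
  norm <- norm_from_values(y)
  pca <- scale_and_pca(norm, rownames(norm$values), n_components = 20, clip = 1e9)
  expect_lt(sum(pca$explained_var[3:20]), 1e-10)
  expect_true(all(diff(pca$explained_var) < 1e-12))
  # loadings orthonormal
  gram <- crossprod(pca$loadings)
  expect_lt(max(abs(gram - diag(20))), 1e-8)
  # full-rank reconstruction returns the scaled matrix
  pca_full <- scale_and_pca(norm, rownames(norm$values), n_components = 30, clip = 1e9)
  recon <- t(pca_full$coords %*% t(pca_full$loadings))
  expect_lt(max(abs(recon - pca_full$scaled)), 1e-8)
  # deterministic sign convention: recomputation is identical
  pca2 <- scale_and_pca(norm, rownames(norm$values), n_components = 20, clip = 1e9)
  expect_identical(pca$coords, pca2$coords)
})

test_that("zero-variance genes are dropped from scaling with a warning", {
  set.seed(5)
  y <- matrix(rnorm(40 * 25), 40, 25)
  y[3, ] <- 7
  norm <- norm_from_values(y)
  expect_warning(
    pca <- scale_and_pca(norm, rownames(norm$values), n_components = 10),
    "zero-variance"
  )
  expect_false("g003" %in% pca$genes)
})

test_that("batch adjustment aligns centroids and preserves geometry", {
  set.seed(6)
  y <- matrix(rnorm(50 * 60), 50, 60)
  norm <- norm_from_values(y)
  pca <- scale_and_pca(norm, rownames(norm$values), n_components = 10)
  batch <- rep(c("r1", "r2"), each = 30)

  # planted constant offset: centroids coincide afterwards
  shifted <- pca
  offset <- rnorm(10)
  shifted$coords[batch == "r2", ] <-
    sweep(shifted$coords[batch == "r2", ], 2, offset, "+")
  adj <- batch_adjust(shifted, batch)
  c1 <- colMeans(adj$coords[batch == "r1", ])
  c2 <- colMeans(adj$coords[batch == "r2", ])
  expect_lt(sqrt(sum((c1 - c2)^2)), 1e-8)

  # within-batch pairwise distances exactly preserved
  d_before <- dist(shifted$coords[batch == "r1", ])
  d_after <- dist(adj$coords[batch == "r1", ])
  expect_lt(max(abs(d_before - d_after)), 1e-10)

  # identical batches (batch b an exact copy of batch a): identity map
  dup <- pca
  dup$coords <- rbind(pca$coords[1:30, ], pca$coords[1:30, ])
  rownames(dup$coords) <- sprintf("c%03d", 1:60)
  adj_same <- batch_adjust(dup, rep(c("a", "b"), each = 30))
  expect_lt(max(abs(adj_same$coords - dup$coords)), 1e-12)

  # single batch: identity
  one <- batch_adjust(pca, rep("a", 60))
  expect_identical(one$coords, pca$coords)
})
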