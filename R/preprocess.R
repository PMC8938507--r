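#' Quality-control filtering of cells
#'
#' Keeps a cell when its number of detected genes (genes with count > 0) lies
#' in `[min_genes, max_genes]` — cells with fewer than `min_genes` or more
#' than `max_genes` detected genes are discarded — and, when
#' `max_mito_fraction` is given, when its fraction of mitochondrial UMIs does
#' not exceed the cutoff (cells above it are discarded). Genes are never
#' removed.
#'
#' @param x a [umi_counts()].
#' @param min_genes,max_genes detected-gene bounds (defaults 200 and 5000).
#' @param max_mito_fraction mitochondrial UMI fraction cutoff in `[0, 1]`, or
#'   `NULL` to disable; requires an `is_mito` flag in `gene_meta`.
#' @return list with `counts` (filtered `umi_counts`) and `report` (tibble,
#'   one row per input cell: detected genes, mito fraction, kept flag).
#' @export
qc_filter <- function(x, min_genes = 200, max_genes = 5000,
                      max_mito_fraction = NULL) {
  stopifnot(inherits(x, "umi_counts"), min_genes < max_genes)
  detected <- Matrix::colSums(x$counts > 0)
  total <- Matrix::colSums(x$counts)
  if (!is.null(max_mito_fraction)) {
    stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1)
    if (!"is_mito" %in% names(x$gene_meta)) {
      abort("mito filter needs an is_mito flag in gene_meta")
    }
    mito <- Matrix::colSums(x$counts[x$gene_meta$is_mito, , drop = FALSE])
    mito_frac <- ifelse(total > 0, mito / total, 0)
  } else {
    mito_frac <- rep(NA_real_, ncol(x$counts))
  }
  keep <- detected >= min_genes & detected <= max_genes
  if (!is.null(max_mito_fraction)) keep <- keep & mito_frac <= max_mito_fraction
  report <- tibble(
    cell_id = colnames(x$counts),
    n_genes_detected = as.integer(unname(detected)),
    total_umis = as.numeric(unname(total)),
    mito_fraction = unname(mito_frac),
    kept = unname(keep)
  )
  if (!any(keep)) abort("QC removed all cells")
  out <- umi_counts(
    x$counts[, keep, drop = FALSE],
    cell_meta = x$cell_meta[keep, , drop = FALSE],
    gene_meta = x$gene_meta
  )
  list(counts = out, report = report)
}

#' Size-normalize and log-transform counts
#'
#' `y_gc = log(1 + scale_factor * counts_gc / total_c)` with natural log;
#' zeros map to zeros and within-cell gene ranks are preserved.
#'
#' @param x a [umi_counts()] with no all-zero cells (guaranteed post-QC).
#' @param scale_factor library-size target (default 10,000).
#' @return object of class `norm_matrix`: `values` (dense genes x cells
#'   matrix), metadata carried over, and `provenance`.
#' @export
normalize_log <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "umi_counts"))
  total <- Matrix::colSums(x$counts)
  if (any(total == 0)) abort("all-zero cell: run qc_filter first")
  y <- log1p(as.matrix(x$counts) %*% Matrix::Diagonal(x = scale_factor / total))
  y <- as.matrix(y)
  dimnames(y) <- dimnames(x$counts)
  structure(
    list(
      values = y,
      cell_meta = x$cell_meta,
      gene_meta = x$gene_meta,
      provenance = list(scale_factor = scale_factor, transform = "log1p")
    ),
    class = "norm_matrix"
  )
}

#' @export
print.norm_matrix <- function(x, ...) {
  cat("<norm_matrix> ", nrow(x$values), " genes x ", ncol(x$values),
    " cells (log1p, scale factor ", x$provenance$scale_factor, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.norm_matrix <- function(x) dim(x$values)

#' Select highly variable genes by binned dispersion
#'
#' Per gene, the mean `m_g` and variance of the back-transformed expression
#' (`expm1(y)`) give a dispersion `d_g = log(var/mean)`. Genes are cut into
#' `n_bins` equal-width bins of `m_g` and `d_g` is z-scored within each bin;
#' a gene is selected when `m_g > expression_cutoff` and its dispersion
#' z-score exceeds `dispersion_cutoff`.
#'
#' @param norm a [normalize_log()] result.
#' @param expression_cutoff,dispersion_cutoff selection cutoffs (defaults
#'   0.5 and 0.5).
#' @param n_bins number of mean bins (default 20).
#' @return tibble of class `hvg_set`, one row per gene: `gene_id`, `mean`,
#'   `dispersion`, `dispersion_z`, `selected`; cutoffs kept as attributes.
#' @export
find_variable_genes <- function(norm, expression_cutoff = 0.5,
                                dispersion_cutoff = 0.5, n_bins = 20) {
  stopifnot(inherits(norm, "norm_matrix"), ncol(norm$values) >= 2)
  ex <- expm1(norm$values)
  m <- rowMeans(ex)
  v <- apply(ex, 1, var)
  d <- ifelse(m > 0 & v > 0, log(v / m), NA_real_)
  bin <- cut(m, breaks = n_bins, include.lowest = TRUE)
  z <- rep(0, length(m))
  for (b in levels(bin)) {
    sel <- which(bin == b & !is.na(d))
    if (length(sel) >= 2 && sd(d[sel]) > 0) {
      z[sel] <- (d[sel] - mean(d[sel])) / sd(d[sel])
    } # single-gene or constant bins keep z = 0
  }
  out <- tibble(
    gene_id = rownames(norm$values),
    mean = m,
    dispersion = d,
    dispersion_z = z,
    selected = m > expression_cutoff & z > dispersion_cutoff
  )
  structure(
    out,
    class = c("hvg_set", class(out)),
    expression_cutoff = expression_cutoff,
    dispersion_cutoff = dispersion_cutoff,
    n_bins = n_bins
  )
}

# z-score genes across cells and clip, dropping zero-variance genes
scale_clipped <- function(values, clip = 10) {
  sds <- apply(values, 1, sd)
  drop <- sds == 0
  if (any(drop)) {
    warn(sprintf("dropping %d zero-variance gene(s) before scaling",
                 sum(drop)))
    values <- values[!drop, , drop = FALSE]
    sds <- sds[!drop]
  }
  z <- (values - rowMeans(values)) / sds
  z[z > clip] <- clip
  z[z < -clip] <- -clip
  z
}

#' Scale selected genes and compute PCA
#'
#' Genes are z-scored across cells (zero mean, unit variance), values clipped
#' to `±clip`, and the cells are projected onto the leading principal
#' components of the scaled HVG submatrix. Component signs are fixed by
#' making each component's largest-magnitude gene loading positive, so the
#' result is deterministic.
#'
#' @param norm a [normalize_log()] result.
#' @param hvg a [find_variable_genes()] result (or a character vector of gene
#'   ids to use directly).
#' @param n_components number of components (default 20).
#' @param clip clip bound for scaled values (default 10).
#' @return object of class `pca_space`: `coords` (cells x components),
#'   `loadings` (genes x components, orthonormal), `explained_var`,
#'   `scaled` (the scaled genes x cells submatrix), metadata carried over.
#' @export
scale_and_pca <- function(norm, hvg, n_components = 20, clip = 10) {
  stopifnot(inherits(norm, "norm_matrix"))
  genes <- if (is.character(hvg)) hvg else hvg$gene_id[hvg$selected]
  stopifnot(length(genes) >= n_components)
  z <- scale_clipped(norm$values[genes, , drop = FALSE], clip)
  # rows of z are centered by construction (clipping can perturb negligibly),
  # so the SVD of t(z) is the PCA of the scaled matrix and reconstruction
  # from all components returns z exactly
  sv <- svd(t(z), nu = n_components, nv = n_components)
  signs <- vapply(seq_len(n_components), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, 0)
  coords <- sweep(sv$u[, seq_len(n_components), drop = FALSE] %*%
    diag(sv$d[seq_len(n_components)], n_components), 2, signs, "*")
  loadings <- sweep(sv$v, 2, signs, "*")
  rownames(coords) <- colnames(norm$values)
  colnames(coords) <- paste0("PC", seq_len(n_components))
  dimnames(loadings) <- list(rownames(z), colnames(coords))
  ev <- sv$d[seq_len(n_components)]^2 / (ncol(z) - 1)
  structure(
    list(
      coords = coords, loadings = loadings, explained_var = ev,
      scaled = z, genes = rownames(z), n_components = n_components,
      cell_meta = norm$cell_meta
    ),
    class = "pca_space"
  )
}

#' @export
print.pca_space <- function(x, ...) {
  cat("<pca_space> ", nrow(x$coords), " cells x ", x$n_components,
    " components over ", length(x$genes), " genes\n",
    sep = ""
  )
  invisible(x)
}

#' Centroid batch adjustment in PC space
#'
#' Subtracts each batch's centroid and restores the global centroid, per
#' component: after adjustment all batch centroids coincide while pairwise
#' distances within a batch are untouched. A deliberately simple,
#' fully testable stand-in for iterative batch-integration methods, adequate
#' when batches share cell-type composition.
#'
#' @param pca a [scale_and_pca()] result.
#' @param batch vector of batch labels, one per cell (e.g. replicate).
#' @return a `pca_space` with adjusted `coords`.
#' @export
batch_adjust <- function(pca, batch) {
  stopifnot(inherits(pca, "pca_space"), length(batch) == nrow(pca$coords))
  batches <- unique(batch)
  if (length(batches) == 1) return(pca)
  if (any(table(batch) < 2)) abort("each batch needs >= 2 cells")
  global <- colMeans(pca$coords)
  out <- pca$coords
  for (b in batches) {
    sel <- batch == b
    out[sel, ] <- sweep(out[sel, , drop = FALSE], 2,
      colMeans(pca$coords[sel, , drop = FALSE]) - global)
  }
  pca$coords <- out
  pca$batch_adjusted <- TRUE
  pca
}
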