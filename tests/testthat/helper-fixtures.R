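# Fixture builders and independent oracles shared across test files.

# two-cell-type, single-plate configuration (fits one 96-well plate)
two_type_config <- function(n_genes = 200, n_per = 48, seed = 7,
                            libsize_meanlog = log(1000), theta = 10,
                            batch_sdlog = 0, sig_fold = 1,
                            sig_genes = 1:20, target = list()) {
  bm <- withr::with_seed(seed, {
    matrix(stats::rgamma(2 * n_genes, 2, 2) + 0.05, n_genes, 2,
      dimnames = list(NULL, c("a", "b"))
    )
  })
  grp <- data.frame(
    cell_type = c("a", "b"),
    condition = c("normal", "injured"),
    gate = "venus_neg", replicate = 1L, n_cells = n_per
  )
  sigs <- if (sig_fold > 1 || length(target) > 0) {
    list(list(
      name = "sig", genes = sig_genes, effect_fold = sig_fold,
      target = target
    ))
  } else {
    list()
  }
  sim_config(n_genes, grp, bm,
    dispersion = theta, libsize_meanlog = libsize_meanlog,
    signature_defs = sigs, batch_sdlog = batch_sdlog, seed = seed
  )
}

# norm_matrix wrapper around a given value matrix (for direct-formula tests)
norm_from_values <- function(y) {
  if (is.null(rownames(y))) rownames(y) <- sprintf("g%03d", seq_len(nrow(y)))
  if (is.null(colnames(y))) colnames(y) <- sprintf("c%03d", seq_len(ncol(y)))
  structure(
    list(
      values = y,
      cell_meta = tibble::tibble(cell_id = colnames(y)),
      gene_meta = tibble::tibble(gene_id = rownames(y)),
      provenance = list(scale_factor = NA, transform = "direct")
    ),
    class = "norm_matrix"
  )
}

# umi_counts wrapper around a given count matrix
counts_from_matrix <- function(m, ...) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("c%03d", seq_len(ncol(m)))
  umi_counts(Matrix::Matrix(m, sparse = TRUE), ...)
}

# brute-force signature score: literal recomputation of the formula
brute_signature_score <- function(y, genes) {
  genes <- intersect(unique(genes), rownames(y))
  scaled <- matrix(0, length(genes), ncol(y))
  maxs <- numeric(length(genes))
  for (i in seq_along(genes)) {
    v <- y[genes[i], ]
    lo <- min(v)
    hi <- max(v)
    scaled[i, ] <- if (hi > lo) (v - lo) / (hi - lo) else 0
    maxs[i] <- hi
  }
  s <- colMeans(scaled)
  list(s = s, avg_max = mean(maxs), h = s * mean(maxs))
}

# brute-force binned-dispersion HVG selection
brute_hvg <- function(y, expression_cutoff = 0.5, dispersion_cutoff = 0.5,
                      n_bins = 20) {
  ex <- expm1(y)
  m <- rowMeans(ex)
  v <- apply(ex, 1, stats::var)
  d <- ifelse(m > 0 & v > 0, log(v / m), NA)
  bin <- cut(m, breaks = n_bins, include.lowest = TRUE)
  z <- rep(0, length(m))
  for (b in levels(bin)) {
    idx <- which(bin == b & !is.na(d))
    if (length(idx) >= 2 && stats::sd(d[idx]) > 0) {
      z[idx] <- (d[idx] - mean(d[idx])) / stats::sd(d[idx])
    }
  }
  rownames(y)[m > expression_cutoff & z > dispersion_cutoff]
}

# adjusted Rand index between two labelings (independent of the package)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# quadrature of the studentized-range CDF with infinite df:
# F(q) = k * integral phi(z) * (Phi(z) - Phi(z - q))^(k-1) dz
prange_inf <- function(q, k) {
  f <- function(z) stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q))^(k - 1)
  k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
}

# studentized-range CDF with df nu by integrating over the chi scale factor
prange_df <- function(q, k, nu) {
  g <- function(u) {
    vapply(u, function(ui) prange_inf(q * ui, k), 0) *
      stats::dchisq(u^2 * nu, df = nu) * 2 * u * nu
  }
  stats::integrate(g, 0, Inf, rel.tol = 1e-8)$value
}

# standardized pairwise rank statistic used by the Steel-Dwass construction
pairwise_rank_stat <- function(x, y) {
  n1 <- length(x)
  n <- n1 + length(y)
  r <- rank(c(x, y))
  v <- n1 * (n - n1) / (n * (n - 1)) * (sum(r^2) - n * (n + 1)^2 / 4)
  if (v == 0) return(0)
  (sum(r[seq_len(n1)]) - n1 * (n + 1) / 2) / sqrt(v)
}
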