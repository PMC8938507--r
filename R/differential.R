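#' Two-sided Wilcoxon rank-sum p-value
#'
#' Normal approximation with midranks, tie-corrected variance and continuity
#' correction; exact enumeration when both groups together hold at most 12
#' tie-free values (override with `exact`). Two identical multisets give
#' p = 1.
#'
#' @param a,b numeric vectors (each non-empty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact path; `NULL`
#'   (default) applies the size-and-ties rule above.
#' @param correct apply the continuity correction on the normal-approximation
#'   path (default `TRUE`).
#' @return the two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(a, b, exact = NULL, correct = TRUE) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1) return(1)
  if (is.null(exact)) {
    exact <- length(a) + length(b) <= 12 && !any(duplicated(c(a, b)))
  }
  res <- suppressWarnings(
    wilcox.test(a, b, exact = exact, correct = correct)
  )
  min(1, res$p.value)
}

#' Log2 fold change on the expm1-mean scale
#'
#' `log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))`: values on the
#' log-normalized scale are back-transformed, averaged per group, and the
#' ratio of pseudocounted means is taken.
#'
#' @param a,b numeric vectors of log-normalized expression.
#' @return the log2 fold change (a over b).
#' @export
log2_fold_change <- function(a, b) {
  log2((mean(expm1(a)) + 1) / (mean(expm1(b)) + 1))
}

# one gene-wise A-vs-B comparison table
de_table <- function(y, in_a, min_pct, min_log2fc) {
  a <- y[, in_a, drop = FALSE]
  b <- y[, !in_a, drop = FALSE]
  pct_in <- rowMeans(a > 0)
  pct_out <- rowMeans(b > 0)
  lfc <- vapply(
    seq_len(nrow(y)), function(g) log2_fold_change(a[g, ], b[g, ]), 0
  )
  tested <- pmax(pct_in, pct_out) >= min_pct & abs(lfc) >= min_log2fc
  p <- rep(NA_real_, nrow(y))
  p[tested] <- vapply(which(tested), function(g) {
    wilcoxon_rank_sum(a[g, ], b[g, ], exact = FALSE)
  }, 0)
  tibble(
    gene_id = rownames(y),
    log2_fc = lfc, p_value = p,
    pct_in = pct_in, pct_out = pct_out,
    tested = tested
  )
}

rank_de <- function(df) {
  df |>
    dplyr::arrange(
      .data$p_value, dplyr::desc(abs(.data$log2_fc)), .data$gene_id
    )
}

#' Per-cluster marker genes (each cluster vs all other cells)
#'
#' For every cluster, each gene is compared between the cluster's cells and
#' all remaining cells with the Wilcoxon rank-sum test (normal approximation,
#' the convention of single-cell marker finding). Genes are pre-filtered by
#' detection fraction (`max(pct_in, pct_out) >= min_pct`) and absolute fold
#' change; p-values are Bonferroni-adjusted over the genes actually tested in
#' that cluster. Records are ranked by p-value, then |log2 FC|, then gene id.
#'
#' @param norm a [normalize_log()] result.
#' @param assign a [cluster_louvain()] result (or data frame `cell_id`,
#'   `cluster`).
#' @param min_pct minimum detection fraction in either group (default 0.1).
#' @param min_log2fc minimum |log2 fold change| (default 0.25).
#' @return tibble of class `marker_table`: `cluster`, `gene_id`, `log2_fc`,
#'   `p_value`, `adj_p`, `pct_in`, `pct_out`; filters kept as attributes.
#'   Only genes passing the filters appear. Size-1 clusters are skipped with
#'   a warning.
#' @export
find_markers <- function(norm, assign, min_pct = 0.1, min_log2fc = 0.25) {
  stopifnot(inherits(norm, "norm_matrix"))
  assign <- as_tibble(assign)
  stopifnot(all(c("cell_id", "cluster") %in% names(assign)))
  cl <- assign$cluster[match(colnames(norm$values), assign$cell_id)]
  stopifnot(!anyNA(cl))
  clusters <- sort(unique(cl))
  if (length(clusters) < 2) abort("need >= 2 clusters")
  out <- lapply(clusters, function(k) {
    in_a <- cl == k
    if (sum(in_a) < 2) {
      warn(sprintf("cluster %s has a single cell; skipped", k))
      return(NULL)
    }
    df <- de_table(norm$values, in_a, min_pct, min_log2fc)
    df <- df[df$tested, , drop = FALSE]
    df$adj_p <- pmin(1, df$p_value * nrow(df)) # Bonferroni over tested genes
    df$cluster <- k
    rank_de(df)
  })
  out <- dplyr::bind_rows(out) |>
    dplyr::select(
      "cluster", "gene_id", "log2_fc", "p_value", "adj_p",
      "pct_in", "pct_out"
    )
  structure(out,
    class = c("marker_table", class(out)),
    min_pct = min_pct, min_log2fc = min_log2fc, mt = "bonferroni",
    test = "wilcoxon (normal approximation)"
  )
}

#' Grouped differential expression: a cluster group versus all other cells
#'
#' Pools the clusters in `group_a` into one group and tests every gene
#' against all remaining cells (the construction behind volcano plots of a
#' "regenerating" cluster group versus the rest). Same filters and test as
#' [find_markers()]; all passing records are returned, ranked by p-value,
#' with the `top_n` by p-value flagged.
#'
#' @param norm a [normalize_log()] result.
#' @param assign cluster assignment (`cell_id`, `cluster`).
#' @param group_a cluster ids forming the group of interest (non-empty,
#'   proper subset of all clusters).
#' @param top_n size of the flagged top set (default 100).
#' @inheritParams find_markers
#' @return tibble of class `deg_table`: `gene_id`, `log2_fc`, `p_value`,
#'   `adj_p`, `pct_in`, `pct_out`, `in_top`.
#' @export
find_degs_grouped <- function(norm, assign, group_a, top_n = 100,
                              min_pct = 0.1, min_log2fc = 0.25) {
  stopifnot(inherits(norm, "norm_matrix"), length(group_a) >= 1)
  assign <- as_tibble(assign)
  cl <- assign$cluster[match(colnames(norm$values), assign$cell_id)]
  stopifnot(!anyNA(cl))
  if (!all(group_a %in% cl)) abort("unknown cluster id in group_a")
  if (all(unique(cl) %in% group_a)) {
    abort("group_a must be a proper subset of the clusters")
  }
  df <- de_table(norm$values, cl %in% group_a, min_pct, min_log2fc)
  df <- df[df$tested, , drop = FALSE]
  df$adj_p <- pmin(1, df$p_value * nrow(df))
  df <- rank_de(df)
  df$in_top <- seq_len(nrow(df)) <= top_n
  out <- dplyr::select(
    df, "gene_id", "log2_fc", "p_value", "adj_p",
    "pct_in", "pct_out", "in_top"
  )
  structure(out,
    class = c("deg_table", class(out)),
    group_a = group_a, top_n = top_n,
    min_pct = min_pct, min_log2fc = min_log2fc, mt = "bonferroni"
  )
}
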