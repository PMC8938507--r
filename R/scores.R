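#' Gene signature
#'
#' A named gene set used for per-cell scoring (e.g. fetal intestine, adult
#' stomach, revival stem cell, quiescence up/down, cell-cycle S or G2M).
#' Duplicate gene ids are removed.
#'
#' @param name signature name.
#' @param genes character vector of gene ids.
#' @param direction `"up"` (default) or `"down"`, for directional sets.
#' @return object of class `gene_signature`.
#' @export
gene_signature <- function(name, genes, direction = c("up", "down")) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  if (length(genes) == 0) abort("empty signature")
  structure(
    list(name = name, genes = genes, direction = direction),
    class = "gene_signature"
  )
}

#' @export
print.gene_signature <- function(x, ...) {
  cat("<gene_signature> ", x$name, ": ", length(x$genes), " genes (",
    x$direction, ")\n",
    sep = ""
  )
  invisible(x)
}

#' Min-max scale one gene across cells
#'
#' `z_c = (y_c - min) / (max - min)` so every gene spans the same dynamic
#' range (min 0, max 1). A constant gene maps to all zeros by convention.
#'
#' @param y numeric vector of one gene's log-normalized values across cells.
#' @return numeric vector in `[0, 1]`.
#' @export
minmax_scale_gene <- function(y) {
  stopifnot(length(y) >= 1)
  rng <- range(y)
  if (rng[1] == rng[2]) return(rep(0, length(y)))
  (y - rng[1]) / (rng[2] - rng[1])
}

#' Per-cell signature score (min-max scaled, rescaled to average abundance)
#'
#' The log-normalized expression of each signature gene is min-max scaled
#' across cells so every gene contributes on an equal dynamic range; the raw
#' score `S_c` is the mean of these scaled values over the signature genes.
#' Because the log-normalized values track absolute transcript abundance,
#' the displayed score rescales `S_c` by the average of the per-gene maxima:
#' `H_c = S_c * avg_max`, so the dynamic range of `H` corresponds to the
#' average absolute amount of the signature transcripts.
#'
#' Signature genes absent from the matrix are dropped (not zero-filled) and
#' the retained fraction is recorded.
#'
#' @param norm a [normalize_log()] result.
#' @param sig a [gene_signature()] (or character vector of gene ids).
#' @return tibble of class `signature_scores`: `cell_id`, `signature`,
#'   `score_raw` (`S_c` in `[0, 1]`), `score` (`H_c`); attributes `avg_max`
#'   and `intersect_ratio`.
#' @export
signature_score <- function(norm, sig) {
  stopifnot(inherits(norm, "norm_matrix"))
  if (is.character(sig)) sig <- gene_signature("signature", sig)
  present <- intersect(sig$genes, rownames(norm$values))
  ratio <- length(present) / length(sig$genes)
  if (length(present) == 0) {
    abort(sprintf(
      "no gene of signature '%s' present in the matrix (0/%d)",
      sig$name, length(sig$genes)
    ))
  }
  y <- norm$values[present, , drop = FALSE]
  scaled <- t(apply(y, 1, minmax_scale_gene))
  if (ncol(y) == 1) scaled <- matrix(scaled, ncol = 1) # apply() drops dims
  s <- colMeans(scaled)
  avg_max <- mean(apply(y, 1, max))
  out <- tibble(
    cell_id = colnames(norm$values),
    signature = sig$name,
    score_raw = unname(s),
    score = unname(s * avg_max)
  )
  structure(out,
    class = c("signature_scores", class(out)),
    avg_max = avg_max, intersect_ratio = ratio,
    n_genes_used = length(present)
  )
}

#' Score several signatures at once
#'
#' @param norm a [normalize_log()] result.
#' @param sigs a list of [gene_signature()] objects (e.g. from
#'   [read_signatures()]).
#' @return a single long tibble of [signature_score()] results.
#' @export
score_signatures <- function(norm, sigs) {
  dplyr::bind_rows(lapply(sigs, function(s) signature_score(norm, s)))
}

#' Cell-cycle phase calls from S and G2M signatures
#'
#' Scores the S-phase and G2M-phase gene sets with [signature_score()],
#' centers each score across cells, and calls the phase with the larger
#' centered score; a cell is called `G1/G0` when both centered scores are at
#' or below `threshold`. A deliberately simple phase caller: no control gene
#' bins.
#'
#' @param norm a [normalize_log()] result.
#' @param s_genes,g2m_genes [gene_signature()] objects (or gene id vectors).
#' @param threshold call threshold on the centered scores (default 0).
#' @return tibble of class `cell_cycle_phase`: `cell_id`, `s_score`,
#'   `g2m_score` (centered), `phase` in `{"G1/G0", "S", "G2M"}`.
#' @export
cell_cycle_phase <- function(norm, s_genes, g2m_genes, threshold = 0) {
  if (is.character(s_genes)) s_genes <- gene_signature("S", s_genes)
  if (is.character(g2m_genes)) g2m_genes <- gene_signature("G2M", g2m_genes)
  s <- signature_score(norm, s_genes)$score
  g <- signature_score(norm, g2m_genes)$score
  s <- s - mean(s)
  g <- g - mean(g)
  phase <- dplyr::case_when(
    s <= threshold & g <= threshold ~ "G1/G0",
    s >= g ~ "S",
    TRUE ~ "G2M"
  )
  out <- tibble(
    cell_id = colnames(norm$values), s_score = s, g2m_score = g,
    phase = phase
  )
  structure(out,
    class = c("cell_cycle_phase", class(out)),
    threshold = threshold
  )
}

#' Transcriptional-diversity stemness score
#'
#' Infers relative differentiation status from transcriptional diversity:
#' the number of detectably expressed genes per cell `D_c` is correlated with
#' each gene's expression; the gene-count signature `GCS_c` is the mean
#' log-normalized expression of the `top_m` genes most correlated with `D`;
#' `GCS` is then smoothed over the SNN graph by the diffusion
#' `s <- (1 - alpha) * GCS + alpha * W s` (`W` = row-normalized SNN weights,
#' `iterations` steps), and the final score is the rank-normalization of the
#' smoothed value to `[0, 1]` (higher = more stem-like). With `alpha = 0`
#' the score is exactly the rank-normalized raw `GCS`.
#'
#' @param norm a [normalize_log()] result.
#' @param graph a [build_snn_graph()] over the same cells (only needed when
#'   `alpha > 0`).
#' @param top_m genes used for the gene-count signature (default 200, capped
#'   at the number of genes).
#' @param alpha diffusion weight in `[0, 1)` (default 0.5).
#' @param iterations diffusion steps (default 30).
#' @return tibble of class `stemness_scores`: `cell_id`, `n_detected`,
#'   `gcs`, `stemness` in `[0, 1]`.
#' @export
stemness_score <- function(norm, graph = NULL, top_m = 200, alpha = 0.5,
                           iterations = 30) {
  stopifnot(inherits(norm, "norm_matrix"), alpha >= 0, alpha < 1)
  y <- norm$values
  n <- ncol(y)
  d_c <- colSums(y > 0)
  if (sd(d_c) == 0) {
    warn("all cells have identical transcriptional diversity; scores set to 0.5")
    out <- tibble(
      cell_id = colnames(y), n_detected = as.integer(d_c),
      gcs = rowMeans(t(y)), stemness = rep(0.5, n)
    )
    return(structure(out, class = c("stemness_scores", class(out)),
      alpha = alpha, iterations = iterations, top_m = top_m))
  }
  r_g <- suppressWarnings(apply(y, 1, function(g) cor(g, d_c)))
  r_g[is.na(r_g)] <- -Inf # constant genes never enter the top set
  top_m <- min(top_m, sum(is.finite(r_g)))
  top <- order(r_g, decreasing = TRUE)[seq_len(top_m)]
  gcs <- colMeans(y[top, , drop = FALSE])
  s <- gcs
  if (alpha > 0) {
    if (is.null(graph)) abort("alpha > 0 needs an SNN graph for smoothing")
    stopifnot(inherits(graph, "snn_graph"), nrow(graph$knn) == n)
    w <- graph$snn
    rs <- Matrix::rowSums(w)
    keep <- rs > 0
    for (i in seq_len(iterations)) {
      sm <- as.vector(w %*% s)
      sm[keep] <- sm[keep] / rs[keep]
      sm[!keep] <- s[!keep] # isolated cells keep their own value
      s <- (1 - alpha) * gcs + alpha * sm
    }
  }
  out <- tibble(
    cell_id = colnames(y),
    n_detected = as.integer(d_c),
    gcs = unname(gcs),
    stemness = unname((rank(s) - 1) / (n - 1))
  )
  structure(out,
    class = c("stemness_scores", class(out)),
    alpha = alpha, iterations = iterations, top_m = top_m,
    top_genes = rownames(y)[top]
  )
}
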