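#' Tidiers for pipeline result objects
#'
#' `tidy()` returns the per-observation table of a result as a plain tibble;
#' `glance()` returns a one-row summary of the object and the settings it
#' was produced with.
#'
#' @param x a result object.
#' @param ... unused.
#' @name regensc-tidiers
NULL

#' @rdname regensc-tidiers
#' @method tidy pairwise_test
#' @export
tidy.pairwise_test <- function(x, ...) {
  as_tibble(unclass2(x))
}

#' @rdname regensc-tidiers
#' @method glance pairwise_test
#' @export
glance.pairwise_test <- function(x, ...) {
  tibble(
    method = attr(x, "method"), k = attr(x, "k"), n_pairs = nrow(x),
    min_p = min(x$p_value), n_significant = sum(x$p_value < 0.05)
  )
}

#' @rdname regensc-tidiers
#' @method tidy hvg_set
#' @export
tidy.hvg_set <- function(x, ...) as_tibble(unclass2(x))

#' @rdname regensc-tidiers
#' @method glance hvg_set
#' @export
glance.hvg_set <- function(x, ...) {
  tibble(
    n_genes = nrow(x), n_selected = sum(x$selected),
    expression_cutoff = attr(x, "expression_cutoff"),
    dispersion_cutoff = attr(x, "dispersion_cutoff"),
    n_bins = attr(x, "n_bins")
  )
}

#' @rdname regensc-tidiers
#' @method tidy pca_space
#' @export
tidy.pca_space <- function(x, ...) {
  dplyr::bind_cols(
    tibble(cell_id = rownames(x$coords)),
    as_tibble(x$coords)
  )
}

#' @rdname regensc-tidiers
#' @method glance pca_space
#' @export
glance.pca_space <- function(x, ...) {
  tibble(
    n_cells = nrow(x$coords), n_components = x$n_components,
    n_genes = length(x$genes),
    var_pc1 = x$explained_var[1],
    batch_adjusted = isTRUE(x$batch_adjusted)
  )
}

#' @rdname regensc-tidiers
#' @method tidy cluster_assignment
#' @export
tidy.cluster_assignment <- function(x, ...) as_tibble(unclass2(x))

#' @rdname regensc-tidiers
#' @method glance cluster_assignment
#' @export
glance.cluster_assignment <- function(x, ...) {
  tibble(
    n_cells = nrow(x), n_clusters = length(unique(x$cluster)),
    resolution = attr(x, "resolution"),
    modularity = attr(x, "modularity"), seed = attr(x, "seed")
  )
}

#' @rdname regensc-tidiers
#' @method tidy signature_scores
#' @export
tidy.signature_scores <- function(x, ...) as_tibble(unclass2(x))

#' @rdname regensc-tidiers
#' @method glance signature_scores
#' @export
glance.signature_scores <- function(x, ...) {
  tibble(
    signature = x$signature[1], n_cells = nrow(x),
    avg_max = attr(x, "avg_max"),
    intersect_ratio = attr(x, "intersect_ratio"),
    n_genes_used = attr(x, "n_genes_used")
  )
}

#' @rdname regensc-tidiers
#' @method tidy stemness_scores
#' @export
tidy.stemness_scores <- function(x, ...) as_tibble(unclass2(x))

#' @rdname regensc-tidiers
#' @method glance stemness_scores
#' @export
glance.stemness_scores <- function(x, ...) {
  tibble(
    n_cells = nrow(x), top_m = attr(x, "top_m"),
    alpha = attr(x, "alpha"), iterations = attr(x, "iterations")
  )
}

#' @rdname regensc-tidiers
#' @method tidy marker_table
#' @export
tidy.marker_table <- function(x, ...) as_tibble(unclass2(x))

#' @rdname regensc-tidiers
#' @method tidy deg_table
#' @export
tidy.deg_table <- function(x, ...) as_tibble(unclass2(x))

#' @rdname regensc-tidiers
#' @method glance deg_table
#' @export
glance.deg_table <- function(x, ...) {
  tibble(
    n_tested = nrow(x), top_n = attr(x, "top_n"),
    n_adj_significant = sum(x$adj_p < 0.05),
    min_pct = attr(x, "min_pct"), min_log2fc = attr(x, "min_log2fc")
  )
}

# strip the result class but keep the tibble classes
unclass2 <- function(x) {
  class(x) <- setdiff(class(x), class(x)[1])
  attr(x, "min_pct") <- NULL
  x
}
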