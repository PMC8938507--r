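#' UMI count matrix with cell and gene annotations
#'
#' The central container of the pipeline: a genes x cells matrix of
#' non-negative integer UMI counts, a per-cell metadata tibble and a per-gene
#' metadata tibble (carrying at least an `is_mito` flag when the
#' mitochondrial QC filter is used).
#'
#' @param counts genes x cells matrix (base or `Matrix` sparse) of
#'   non-negative integers with row and column names.
#' @param cell_meta tibble with a `cell_id` column matching `colnames(counts)`
#'   (created from the column names when missing).
#' @param gene_meta tibble with a `gene_id` column matching `rownames(counts)`.
#' @return object of class `umi_counts`.
#' @export
umi_counts <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("counts must have gene rownames and cell colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    abort("duplicate gene or cell ids")
  }
  vals <- if (inherits(counts, "Matrix")) counts@x else counts
  if (any(vals < 0) || any(vals != round(vals))) {
    abort("counts must be non-negative integers")
  }
  if (is.null(cell_meta)) cell_meta <- tibble(cell_id = colnames(counts))
  if (is.null(gene_meta)) {
    gene_meta <- tibble(
      gene_id = rownames(counts),
      is_mito = startsWith(rownames(counts), "mt-")
    )
  }
  cell_meta <- as_tibble(cell_meta)
  gene_meta <- as_tibble(gene_meta)
  stopifnot(
    identical(cell_meta$cell_id, colnames(counts)),
    identical(gene_meta$gene_id, rownames(counts))
  )
  structure(
    list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
    class = "umi_counts"
  )
}

#' @export
print.umi_counts <- function(x, ...) {
  cat("<umi_counts> ", nrow(x$counts), " genes x ", ncol(x$counts),
    " cells; ", format(sum(x$counts), big.mark = ","), " total UMIs\n",
    sep = ""
  )
  invisible(x)
}

#' @export
dim.umi_counts <- function(x) dim(x$counts)

#' Concatenate count matrices across experiments
#'
#' Column-binds matrices over the union of genes (absent genes filled with 0),
#' the way per-plate or per-replicate matrices are combined before joint
#' analysis.
#'
#' @param ... `umi_counts` objects with disjoint cell ids.
#' @return a single `umi_counts`.
#' @export
concat_counts <- function(...) {
  objs <- list(...)
  stopifnot(length(objs) >= 1, all(vapply(objs, inherits, TRUE, "umi_counts")))
  genes <- Reduce(union, lapply(objs, function(o) rownames(o$counts)))
  mats <- lapply(objs, function(o) {
    m <- Matrix::Matrix(0, length(genes), ncol(o$counts),
      dimnames = list(genes, colnames(o$counts)), sparse = TRUE
    )
    m[rownames(o$counts), ] <- o$counts
    m
  })
  cell_meta <- dplyr::bind_rows(lapply(objs, `[[`, "cell_meta"))
  if (anyDuplicated(cell_meta$cell_id) > 0) abort("duplicate cell ids")
  gene_meta <- dplyr::bind_rows(lapply(objs, `[[`, "gene_meta")) |>
    dplyr::distinct(.data$gene_id, .keep_all = TRUE) |>
    dplyr::arrange(match(.data$gene_id, genes))
  umi_counts(do.call(cbind, mats), cell_meta, gene_meta)
}

#' Write / read a count matrix as MatrixMarket plus TSV annotations
#'
#' `write_count_matrix()` writes `matrix.mtx`, `genes.tsv` and `cells.tsv`
#' into `dir`; `read_count_matrix()` reads them back.
#'
#' @param x a [umi_counts()].
#' @param dir directory (created if needed).
#' @return `write_count_matrix()` the directory, invisibly;
#'   `read_count_matrix()` a `umi_counts`.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "umi_counts"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(
    methods::as(methods::as(x$counts, "dMatrix"), "generalMatrix"),
    file.path(dir, "matrix.mtx")
  )
  readr::write_tsv(x$gene_meta, file.path(dir, "genes.tsv"))
  readr::write_tsv(x$cell_meta, file.path(dir, "cells.tsv"))
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  genes <- readr::read_tsv(
    file.path(dir, "genes.tsv"),
    show_col_types = FALSE
  )
  cells <- readr::read_tsv(
    file.path(dir, "cells.tsv"),
    show_col_types = FALSE
  )
  dimnames(m) <- list(genes$gene_id, cells$cell_id)
  umi_counts(methods::as(m, "CsparseMatrix"), cells, genes)
}

#' Write / read a barcode layout as TSV
#'
#' The TSV holds one row per well (`well`, `barcode`); read geometry is
#' supplied on reading.
#'
#' @param layout a [barcode_layout()].
#' @param path TSV path.
#' @inheritParams barcode_layout
#' @return `read_layout()` returns a `barcode_layout`.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "barcode_layout"))
  readr::write_tsv(layout$wells, path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path, umi_length = 6, read1_length = 25,
                        read2_length = 75, min_distance = 2) {
  wells <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("well", "barcode") %in% names(wells)))
  bl <- nchar(wells$barcode[1])
  stopifnot(all(nchar(wells$barcode) == bl))
  structure(
    list(
      wells = wells[, c("well", "barcode")],
      barcode_length = as.integer(bl),
      umi_length = as.integer(umi_length),
      read1_length = as.integer(read1_length),
      read2_length = as.integer(read2_length),
      min_distance = as.integer(min_distance)
    ),
    class = "barcode_layout"
  )
}

#' Read a gene-signature table
#'
#' Signature TSVs have columns `signature_name`, `gene_id` and optionally
#' `direction` (`up`/`down`).
#'
#' @param path TSV path.
#' @return a named list of [gene_signature()] objects.
#' @export
read_signatures <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("signature_name", "gene_id") %in% names(df)))
  split(df, df$signature_name) |>
    purrr::imap(function(d, nm) {
      gene_signature(
        name = nm, genes = d$gene_id,
        direction = if ("direction" %in% names(d)) d$direction[1] else "up"
      )
    })
}
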