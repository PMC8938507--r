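#' Demultiplex read 1 into (well, UMI)
#'
#' Read 1 carries the UMI followed by the cell barcode (CEL-seq2 layout).
#' The UMI is extracted verbatim; the barcode is matched against the plate
#' layout. With `max_mismatch = 0` only exact matches assign; mismatch
#' tolerance is opt-in and only allowed when the layout's pairwise barcode
#' distance guarantees unambiguous correction
#' (`min_distance >= 2 * max_mismatch + 1`).
#'
#' @param read1 character vector of read-1 sequences.
#' @param layout a [barcode_layout()].
#' @param max_mismatch allowed barcode mismatches (default 0).
#' @return tibble with one row per read: `well` (NA when unassigned) and
#'   `umi`.
#' @export
demultiplex <- function(read1, layout, max_mismatch = 0) {
  stopifnot(inherits(layout, "barcode_layout"))
  need <- layout$umi_length + layout$barcode_length
  if (any(nchar(read1) < need)) {
    abort("read 1 shorter than UMI + barcode")
  }
  if (max_mismatch > 0 &&
    layout$min_distance < 2 * max_mismatch + 1) {
    abort(sprintf(
      "max_mismatch = %d needs pairwise barcode distance >= %d",
      max_mismatch, 2 * max_mismatch + 1
    ))
  }
  umi <- substr(read1, 1, layout$umi_length)
  bc <- substr(read1, layout$umi_length + 1, need)
  hit <- match(bc, layout$wells$barcode)
  if (max_mismatch > 0 && anyNA(hit)) {
    todo <- which(is.na(hit))
    for (i in todo) {
      d <- hamming_dist(bc[i], layout$wells$barcode)
      ok <- which(d <= max_mismatch)
      # layout distance guarantee makes >1 hit impossible; keep the guard
      if (length(ok) == 1) hit[i] <- ok
    }
  }
  tibble(well = layout$wells$well[hit], umi = umi)
}

#' Exact-substring gene assignment index
#'
#' Enumerates every substring of length `read_length` of every transcript and
#' records which gene it belongs to; substrings shared by two or more genes
#' are marked ambiguous. Stands in for genome alignment on synthetic
#' transcriptomes, where reads are error-free.
#'
#' @param txome named `DNAStringSet` (or named character vector).
#' @param read_length read-2 length.
#' @return an index for [assign_gene()].
#' @export
build_txome_index <- function(txome, read_length) {
  km <- kmer_table(txome, read_length) |>
    dplyr::distinct(.data$gene_id, .data$kmer)
  # after per-gene dedup, a duplicated kmer means >= 2 genes share it
  dup <- unique(km$kmer[duplicated(km$kmer)])
  km <- dplyr::distinct(km, .data$kmer, .keep_all = TRUE)
  gene <- km$gene_id
  gene[km$kmer %in% dup] <- NA_character_
  structure(
    list(kmers = km$kmer, gene = gene, ambiguous = km$kmer %in% dup,
         read_length = as.integer(read_length)),
    class = "txome_index"
  )
}

#' Assign read 2 to a gene by exact substring match
#'
#' @param read2 character vector of read-2 sequences (each of the index's
#'   read length).
#' @param index from [build_txome_index()].
#' @return tibble with `gene_id` (NA when unassigned) and `reason`
#'   (`ok`, `no_gene` or `ambiguous_gene`).
#' @export
assign_gene <- function(read2, index) {
  stopifnot(inherits(index, "txome_index"))
  hit <- match(read2, index$kmers)
  gene <- index$gene[hit]
  reason <- dplyr::case_when(
    is.na(hit) ~ "no_gene",
    index$ambiguous[hit] ~ "ambiguous_gene",
    TRUE ~ "ok"
  )
  tibble(gene_id = gene, reason = reason)
}

#' UMI-collapsed counting of demultiplexed records
#'
#' Counts, for every (gene, cell), the number of distinct UMIs among records
#' assigned to both a cell and a gene. Duplicate reads of the same molecule
#' (same cell, gene and UMI) collapse to one; feeding a record twice changes
#' nothing, and the result is invariant to record order.
#'
#' @param records tibble with columns `well` (NA = unassigned), `umi`,
#'   `gene_id` (NA = unassigned) and `reason`.
#' @param layout a [barcode_layout()]; its wells define the cell universe.
#' @param gene_ids gene universe for the output matrix rows.
#' @return list with `counts` (a [umi_counts()] over all layout wells and
#'   `gene_ids`) and `report` (totals and per-reason discards).
#' @export
count_records <- function(records, layout, gene_ids) {
  stopifnot(inherits(layout, "barcode_layout"))
  ok <- records |>
    dplyr::filter(!is.na(.data$well), !is.na(.data$gene_id)) |>
    dplyr::distinct(.data$well, .data$gene_id, .data$umi)
  tab <- ok |> dplyr::count(.data$well, .data$gene_id)
  m <- Matrix::sparseMatrix(
    i = match(tab$gene_id, gene_ids),
    j = match(tab$well, layout$wells$well),
    x = tab$n,
    dims = c(length(gene_ids), nrow(layout$wells)),
    dimnames = list(gene_ids, layout$wells$well)
  )
  n_bad_bc <- sum(is.na(records$well))
  n_no_gene <- sum(!is.na(records$well) & records$reason == "no_gene")
  n_ambig <- sum(!is.na(records$well) & records$reason == "ambiguous_gene")
  n_ok <- nrow(records) - n_bad_bc - n_no_gene - n_ambig
  report <- list(
    total_reads = nrow(records),
    assigned_reads = n_ok,
    discarded = list(
      bad_barcode = n_bad_bc, no_gene = n_no_gene, ambiguous_gene = n_ambig
    ),
    umis_collapsed = n_ok - nrow(ok)
  )
  list(counts = umi_counts(m), report = report)
}

#' Count a CEL-seq2-layout FASTQ pair into a gene x cell UMI matrix
#'
#' End-to-end: reads the paired FASTQ (read 1 = UMI + barcode, read 2 =
#' transcript sequence), demultiplexes by cell barcode, assigns each read 2
#' to a gene by exact substring match against the transcriptome, collapses
#' UMIs and returns the count matrix with a processing report. Reads are
#' processed in chunks so per-read structures stay bounded.
#'
#' @param r1_path,r2_path FASTQ paths (gzipped or plain).
#' @param layout a [barcode_layout()] (or path handled by [read_layout()]).
#' @param txome named `DNAStringSet` transcriptome.
#' @param max_mismatch barcode mismatches allowed (see [demultiplex()]).
#' @param chunk_size reads per processing chunk.
#' @return list with `counts` ([umi_counts()], cells = layout wells) and
#'   `report`.
#' @export
celseq_count <- function(r1_path, r2_path, layout, txome,
                         max_mismatch = 0, chunk_size = 5e5) {
  if (is.character(layout)) layout <- read_layout(layout)
  r1 <- as.character(Biostrings::readDNAStringSet(r1_path, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(r2_path, format = "fastq"))
  if (length(r1) != length(r2)) abort("read 1 / read 2 length mismatch")
  index <- build_txome_index(txome, layout$read2_length)
  gene_ids <- names(txome)

  n <- length(r1)
  tally <- c(ok = 0L, bad_barcode = 0L, no_gene = 0L, ambiguous_gene = 0L)
  triples <- list()
  if (n > 0) {
    for (s in seq(1, n, by = chunk_size)) {
      sel <- s:min(s + chunk_size - 1, n)
      dm <- demultiplex(r1[sel], layout, max_mismatch)
      ga <- assign_gene(substr(r2[sel], 1, layout$read2_length), index)
      rec <- dplyr::bind_cols(dm, ga)
      rec$reason[is.na(rec$well)] <- "bad_barcode"
      tally <- tally + vapply(
        names(tally), function(r) sum(rec$reason == r), 0L
      )
      # only distinct ok-triples are carried across chunks (bounded memory)
      triples[[length(triples) + 1]] <- rec |>
        dplyr::filter(.data$reason == "ok") |>
        dplyr::distinct(.data$well, .data$gene_id, .data$umi)
    }
  }
  ok <- dplyr::bind_rows(triples)
  if (nrow(ok) > 0) {
    ok <- dplyr::distinct(ok, .data$well, .data$gene_id, .data$umi)
  } else {
    ok <- tibble(well = character(), gene_id = character(), umi = character())
  }
  tab <- ok |> dplyr::count(.data$well, .data$gene_id)
  m <- Matrix::sparseMatrix(
    i = match(tab$gene_id, gene_ids),
    j = match(tab$well, layout$wells$well),
    x = tab$n,
    dims = c(length(gene_ids), nrow(layout$wells)),
    dimnames = list(gene_ids, layout$wells$well)
  )
  report <- list(
    total_reads = n,
    assigned_reads = unname(tally["ok"]),
    discarded = as.list(tally[c("bad_barcode", "no_gene", "ambiguous_gene")]),
    umis_collapsed = unname(tally["ok"]) - nrow(ok)
  )
  list(counts = umi_counts(m), report = report)
}
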