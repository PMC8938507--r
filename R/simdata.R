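#' Simulation configuration for a plate-based crypt scRNA-seq experiment
#'
#' Bundles everything the count simulator needs: the gene universe, the cell
#' groups (cell type x condition x FACS gate x replicate), per-type baseline
#' expression, negative-binomial dispersion, log-normal library sizes, planted
#' gene-signature effects, and replicate-wise batch factors.
#'
#' Counts for gene g in cell c of type t are drawn as
#' `NB(mean = L_c * b_g(rep) * mu_gt * f^[g in signature & c targeted],
#' size = theta)` with `Var = m + m^2/theta`.
#'
#' @param n_genes number of genes.
#' @param cell_groups data frame with columns `cell_type`, `condition`
#'   (`"normal"` or `"injured"`), `gate` (`"venus_pos"` or `"venus_neg"`),
#'   `replicate` (integer) and `n_cells` (>= 1).
#' @param baseline_means numeric matrix, genes x cell types (column names =
#'   cell types), of non-negative relative expression levels `mu_gt`. Columns
#'   are normalized internally to sum to 1.
#' @param dispersion NB inverse-dispersion `theta` (> 0); variance is
#'   `m + m^2/theta`.
#' @param libsize_meanlog,libsize_sdlog log-normal parameters of the per-cell
#'   library size `L_c` (expected total UMIs).
#' @param signature_defs list of planted signature effects; each element a
#'   list with `name`, `genes` (gene ids or indices), `effect_fold` (>= 1) and
#'   `target` (named list over `cell_type`/`condition`/`gate`/`replicate`; a
#'   cell group is targeted when all given fields match).
#' @param batch_sdlog sdlog of the replicate-wise per-gene log-normal batch
#'   factor `b_g` (0 disables batch effects).
#' @param mito_fraction fraction of genes flagged mitochondrial (placed at the
#'   end of the gene universe, ids prefixed `mt-`).
#' @param seed integer seed; all simulator randomness derives from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_genes,
                       cell_groups,
                       baseline_means,
                       dispersion = 10,
                       libsize_meanlog = log(5000),
                       libsize_sdlog = 0.3,
                       signature_defs = list(),
                       batch_sdlog = 0.1,
                       mito_fraction = 0,
                       seed = 1L) {
  cell_groups <- as_tibble(cell_groups)
  stopifnot(
    n_genes >= 1,
    all(c("cell_type", "condition", "gate", "replicate", "n_cells") %in%
      names(cell_groups)),
    all(cell_groups$n_cells >= 1),
    dispersion > 0, libsize_sdlog >= 0, batch_sdlog >= 0,
    mito_fraction >= 0, mito_fraction <= 1,
    is.matrix(baseline_means), nrow(baseline_means) == n_genes,
    all(baseline_means >= 0)
  )
  if (is.null(colnames(baseline_means))) {
    abort("baseline_means must have cell types as column names")
  }
  missing_types <- setdiff(cell_groups$cell_type, colnames(baseline_means))
  if (length(missing_types) > 0) {
    abort(paste0("no baseline means for cell type(s): ",
                 paste(missing_types, collapse = ", ")))
  }
  if (any(colSums(baseline_means) <= 0)) {
    abort("every cell type needs positive total baseline expression")
  }
  gene_ids <- rownames(baseline_means)
  if (is.null(gene_ids)) {
    n_mito <- round(mito_fraction * n_genes)
    gene_ids <- c(
      sprintf("g%04d", seq_len(n_genes - n_mito)),
      if (n_mito > 0) sprintf("mt-g%04d", seq_len(n_mito))
    )
    rownames(baseline_means) <- gene_ids
  }
  signature_defs <- lapply(signature_defs, function(sig) {
    stopifnot(!is.null(sig$name), !is.null(sig$genes))
    if (is.numeric(sig$genes)) {
      stopifnot(all(sig$genes >= 1), all(sig$genes <= n_genes))
      sig$genes <- gene_ids[sig$genes]
    } else {
      stopifnot(all(sig$genes %in% gene_ids))
    }
    sig$effect_fold <- sig$effect_fold %||% 1
    stopifnot(sig$effect_fold >= 1)
    sig$target <- sig$target %||% list()
    sig
  })
  structure(
    list(
      n_genes = as.integer(n_genes),
      gene_ids = gene_ids,
      cell_groups = cell_groups,
      baseline_means = sweep(baseline_means, 2, colSums(baseline_means), "/"),
      dispersion = dispersion,
      libsize_meanlog = libsize_meanlog,
      libsize_sdlog = libsize_sdlog,
      signature_defs = signature_defs,
      batch_sdlog = batch_sdlog,
      mito_fraction = mito_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> ", x$n_genes, " genes, ",
    sum(x$cell_groups$n_cells), " cells in ", nrow(x$cell_groups),
    " groups, theta = ", x$dispersion,
    ", ", length(x$signature_defs), " planted signature(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Default simulated study design
#'
#' Builds a `sim_config` emulating, at reduced scale, a two-condition
#' (normal vs post-injury) x two-reporter-gate (Venus+/Venus-) x
#' two-replicate crypt cell sorting design on 96-well plates. Five cell-type
#' programs are planted (stem, progenitor, enterocyte, secretory, revival),
#' with the reporter-positive gates enriched for the secretory lineage and
#' revival cells appearing only after injury. Fetal-intestine and
#' adult-stomach signatures are planted with a fold effect in revival cells;
#' a fraction of genes is flagged mitochondrial.
#'
#' Per-condition cell-type proportions are declared defaults (see the methods
#' vignette); cell numbers per gate are 1/8 of the sorted-cell counts of the
#' emulated design (30/60 normal +/- and 36/72 injured +/- per replicate).
#'
#' @param n_genes number of genes (>= 300 to fit the default block layout).
#' @param effect_fold planted fold change of the fetal and gastric signatures
#'   in revival cells (1 = no effect).
#' @param marker_fold fold by which each type's marker block exceeds baseline.
#' @param scale multiplier on all group sizes.
#' @param dispersion,batch_sdlog,libsize_meanlog,libsize_sdlog see
#'   [sim_config()].
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
default_sim_config <- function(n_genes = 500, effect_fold = 4,
                               marker_fold = 8, scale = 1,
                               dispersion = 10, batch_sdlog = 0.1,
                               libsize_meanlog = log(5000),
                               libsize_sdlog = 0.3, seed = 1L) {
  stopifnot(n_genes >= 300)
  types <- c("stem", "progenitor", "enterocyte", "secretory", "revival")
  sizes <- function(n, props) {
    k <- floor(n * props)
    k[1] <- k[1] + n - sum(k) # absorb rounding in the first type
    k
  }
  grp <- function(condition, gate, replicate, n, props) {
    tibble(
      cell_type = names(props), condition = condition, gate = gate,
      replicate = replicate, n_cells = sizes(n, props)
    )
  }
  p_norm_neg <- c(stem = .3, progenitor = .3, enterocyte = .3, secretory = .1)
  p_norm_pos <- c(secretory = .7, stem = .1, progenitor = .1, enterocyte = .1)
  p_inj_neg <- c(
    revival = .3, stem = .15, progenitor = .25, enterocyte = .25,
    secretory = .05
  )
  p_inj_pos <- c(
    revival = .4, secretory = .45, stem = .05, progenitor = .05,
    enterocyte = .05
  )
  groups <- dplyr::bind_rows(lapply(1:2, function(r) {
    dplyr::bind_rows(
      grp("normal", "venus_pos", r, round(30 * scale), p_norm_pos),
      grp("normal", "venus_neg", r, round(60 * scale), p_norm_neg),
      grp("injured", "venus_pos", r, round(36 * scale), p_inj_pos),
      grp("injured", "venus_neg", r, round(72 * scale), p_inj_neg)
    )
  }))
  groups <- dplyr::filter(groups, .data$n_cells > 0)

  n_mito <- round(0.05 * n_genes)
  gene_ids <- c(
    sprintf("g%04d", seq_len(n_genes - n_mito)),
    if (n_mito > 0) sprintf("mt-g%04d", seq_len(n_mito))
  )
  # gene blocks: 40 markers per type, then fetal/gastric/revSC signature genes
  marker_idx <- lapply(seq_along(types), function(i) ((i - 1) * 40 + 1):(i * 40))
  names(marker_idx) <- types
  fetal_idx <- 201:225
  gastric_idx <- 226:250
  revsc_idx <- 251:265
  mito_idx <- if (n_mito > 0) (n_genes - n_mito + 1):n_genes else integer(0)

  baseline <- withr::with_seed(seed, {
    base <- stats::rgamma(n_genes, shape = 2, rate = 2) + 0.05
    m <- matrix(base, n_genes, length(types),
      dimnames = list(gene_ids, types)
    )
    for (t in types) m[marker_idx[[t]], t] <- m[marker_idx[[t]], t] * marker_fold
    # mitochondrial transcripts: abundant, shared across types
    if (n_mito > 0) m[mito_idx, ] <- mean(base) * 2
    m
  })

  sigs <- list(
    list(
      name = "fetal", genes = fetal_idx, effect_fold = effect_fold,
      target = list(cell_type = "revival")
    ),
    list(
      name = "gastric", genes = gastric_idx, effect_fold = effect_fold,
      target = list(cell_type = "revival")
    ),
    list(
      name = "revsc", genes = revsc_idx, effect_fold = effect_fold,
      target = list(cell_type = "revival")
    )
  )

  sim_config(
    n_genes = n_genes, cell_groups = groups, baseline_means = baseline,
    dispersion = dispersion, libsize_meanlog = libsize_meanlog,
    libsize_sdlog = libsize_sdlog, signature_defs = sigs,
    batch_sdlog = batch_sdlog, mito_fraction = 0.05, seed = seed
  )
}

group_is_targeted <- function(group_row, target) {
  for (field in names(target)) {
    if (!group_row[[field]] %in% target[[field]]) return(FALSE)
  }
  TRUE
}

#' Simulate a UMI count matrix with planted ground truth
#'
#' Draws gene x cell UMI counts under the negative-binomial model described in
#' [sim_config()] and records everything that was planted (cell types,
#' signature targeting, batch factors, expected means, library sizes) so that
#' downstream stages can be tested against known truth.
#'
#' @param config a [sim_config()].
#' @return a list with elements `counts` (a `umi_counts` object, see
#'   [umi_counts()]) and `truth` (class `sim_truth`): `cells` (per-cell
#'   tibble incl. planted `cell_type`, `libsize`, `well`, `plate`),
#'   `batch_factors` (genes x replicates), `signature_effects` (per planted
#'   signature gene), `cell_signature_fold` (per cell x signature planted
#'   fold) and `expected_mean` (genes x cells NB mean matrix).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    groups <- config$cell_groups
    n_cells <- sum(groups$n_cells)
    gene_ids <- config$gene_ids
    reps <- sort(unique(groups$replicate))

    b <- matrix(1, config$n_genes, length(reps),
      dimnames = list(gene_ids, paste0("rep", reps))
    )
    if (config$batch_sdlog > 0) {
      b[] <- rlnorm(
        config$n_genes * length(reps),
        meanlog = -config$batch_sdlog^2 / 2, sdlog = config$batch_sdlog
      )
    }

    wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))
    cell_no <- 0L
    cells <- vector("list", nrow(groups))
    count_cols <- vector("list", nrow(groups))
    mean_cols <- vector("list", nrow(groups))
    sig_fold <- vector("list", nrow(groups))

    for (i in seq_len(nrow(groups))) {
      g <- groups[i, ]
      mu <- config$baseline_means[, g$cell_type]
      fold_here <- setNames(
        numeric(length(config$signature_defs)),
        vapply(config$signature_defs, `[[`, "", "name")
      ) + 1
      for (sig in config$signature_defs) {
        if (group_is_targeted(g, sig$target) && sig$effect_fold != 1) {
          mu[sig$genes] <- mu[sig$genes] * sig$effect_fold
          fold_here[sig$name] <- sig$effect_fold
        }
      }
      L <- rlnorm(g$n_cells, config$libsize_meanlog, config$libsize_sdlog)
      m <- outer(mu * b[, paste0("rep", g$replicate)], L)
      cnt <- matrix(
        rnbinom(length(m), mu = m, size = config$dispersion),
        nrow = config$n_genes
      )
      idx <- cell_no + seq_len(g$n_cells)
      ids <- sprintf(
        "%s_%s_r%d_c%04d", substr(g$condition, 1, 3),
        sub("venus_", "", g$gate), g$replicate, idx
      )
      colnames(cnt) <- colnames(m) <- ids
      cells[[i]] <- tibble(
        cell_id = ids, cell_type = g$cell_type, condition = g$condition,
        gate = g$gate, replicate = g$replicate,
        well = wells[(idx - 1L) %% 96L + 1L],
        plate = (idx - 1L) %/% 96L + 1L,
        libsize = L
      )
      count_cols[[i]] <- cnt
      mean_cols[[i]] <- m
      sig_fold[[i]] <- if (length(fold_here) > 0) {
        tidyr::expand_grid(cell_id = ids, signature = names(fold_here)) |>
          dplyr::mutate(effect_fold = fold_here[.data$signature])
      } else {
        tibble(
          cell_id = character(), signature = character(),
          effect_fold = numeric()
        )
      }
      cell_no <- cell_no + g$n_cells
    }

    cell_meta <- dplyr::bind_rows(cells)
    counts <- do.call(cbind, count_cols)
    rownames(counts) <- gene_ids
    gene_meta <- tibble(
      gene_id = gene_ids, is_mito = startsWith(gene_ids, "mt-")
    )
    sig_eff <- dplyr::bind_rows(lapply(config$signature_defs, function(sig) {
      tibble(
        signature = sig$name, gene_id = sig$genes,
        effect_fold = sig$effect_fold
      )
    }))

    truth <- structure(
      list(
        cells = cell_meta,
        batch_factors = b,
        signature_effects = sig_eff,
        cell_signature_fold = dplyr::bind_rows(sig_fold),
        expected_mean = do.call(cbind, mean_cols)
      ),
      class = "sim_truth"
    )
    list(
      counts = umi_counts(
        Matrix::Matrix(counts, sparse = TRUE),
        cell_meta = dplyr::select(cell_meta, !"libsize"),
        gene_meta = gene_meta
      ),
      truth = truth
    )
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$cells), " cells, ",
    nrow(x$batch_factors), " genes, ",
    length(unique(x$signature_effects$signature)), " planted signature(s)\n",
    sep = ""
  )
  invisible(x)
}

#' Generate a synthetic transcriptome
#'
#' Random nucleotide sequences, one per gene, guaranteed pairwise
#' distinguishable at the read length: no substring of length `read_length`
#' occurs in more than one gene. This makes exact-substring gene assignment
#' unambiguous for error-free reads.
#'
#' @param gene_ids character vector of gene ids.
#' @param length transcript length (>= `read_length`).
#' @param read_length read-2 length used downstream.
#' @param seed integer seed.
#' @return a named [Biostrings::DNAStringSet].
#' @export
make_transcriptome <- function(gene_ids, length = 150, read_length = 75,
                               seed = 1L) {
  stopifnot(length >= read_length, !anyDuplicated(gene_ids))
  withr::with_seed(seed, {
    draw <- function(n) {
      vapply(seq_len(n), function(i) {
        paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
          collapse = ""
        )
      }, "")
    }
    seqs <- draw(base::length(gene_ids))
    names(seqs) <- gene_ids
    for (iter in 1:100) {
      km <- kmer_table(seqs, read_length)
      dup_genes <- unique(km$gene_id[km$kmer %in% km$kmer[duplicated(km$kmer)]])
      if (base::length(dup_genes) == 0) break
      seqs[dup_genes] <- draw(base::length(dup_genes))
    }
    km <- kmer_table(seqs, read_length)
    if (anyDuplicated(km$kmer) > 0) {
      abort("could not generate read-length-distinguishable transcripts")
    }
    Biostrings::DNAStringSet(seqs)
  })
}

kmer_table <- function(seqs, k) {
  seqs <- setNames(as.character(seqs), names(seqs)) # as.character drops names
  if (is.null(names(seqs))) abort("transcriptome sequences must be named")
  pieces <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    starts <- seq_len(nchar(s) - k + 1)
    tibble(
      gene_id = names(seqs)[i],
      kmer = substring(s, starts, starts + k - 1)
    )
  })
  dplyr::bind_rows(pieces)
}

#' Plate barcode layout
#'
#' Well-to-barcode assignment for a 96-well plate plus the read geometry:
#' read 1 carries `umi_length` UMI bases followed by the cell barcode, padded
#' with `A` to `read1_length`; read 2 is `read2_length` transcript bases.
#' Barcodes are generated with pairwise Hamming distance >= `min_distance`
#' so that mismatch-tolerant demultiplexing stays unambiguous.
#'
#' @param n_wells number of wells (<= 96 named `A1`..`H12`).
#' @param barcode_length,umi_length barcode and UMI lengths (nt).
#' @param read1_length,read2_length read lengths (nt).
#' @param min_distance minimum pairwise Hamming distance between barcodes.
#' @param seed integer seed.
#' @return object of class `barcode_layout` with a `wells` tibble
#'   (`well`, `barcode`) and the geometry fields.
#' @export
barcode_layout <- function(n_wells = 96, barcode_length = 6, umi_length = 6,
                           read1_length = 25, read2_length = 75,
                           min_distance = 2, seed = 1L) {
  stopifnot(
    n_wells >= 1, n_wells <= 96,
    read1_length >= umi_length + barcode_length
  )
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, times = 8))[1:n_wells]
  codes <- withr::with_seed(seed, {
    accepted <- character(0)
    alphabet <- c("A", "C", "G", "T")
    attempts <- 0L
    max_attempts <- 20000L * n_wells
    while (length(accepted) < n_wells) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(paste0(
          "could not place ", n_wells, " barcodes of length ",
          barcode_length, " at pairwise distance >= ", min_distance,
          "; use longer barcodes or a smaller distance"
        ))
      }
      cand <- paste(sample(alphabet, barcode_length, replace = TRUE),
        collapse = ""
      )
      if (length(accepted) == 0 ||
        all(hamming_dist(cand, accepted) >= min_distance)) {
        accepted <- c(accepted, cand)
      }
    }
    accepted
  })
  structure(
    list(
      wells = tibble(well = wells, barcode = codes),
      barcode_length = as.integer(barcode_length),
      umi_length = as.integer(umi_length),
      read1_length = as.integer(read1_length),
      read2_length = as.integer(read2_length),
      min_distance = as.integer(min_distance)
    ),
    class = "barcode_layout"
  )
}

# Hamming distances between one string and a vector of equal-length strings
hamming_dist <- function(x, ys) {
  xs <- strsplit(x, "")[[1]]
  vapply(strsplit(ys, ""), function(y) sum(xs != y), 0L)
}

#' @export
print.barcode_layout <- function(x, ...) {
  cat("<barcode_layout> ", nrow(x$wells), " wells, barcode ",
    x$barcode_length, " nt, UMI ", x$umi_length, " nt, reads ",
    x$read1_length, "/", x$read2_length, " nt\n",
    sep = ""
  )
  invisible(x)
}

int_to_umi <- function(i, len) {
  alphabet <- c("A", "C", "G", "T")
  out <- character(length(i))
  chars <- matrix("", length(i), len)
  for (p in seq_len(len)) {
    chars[, len - p + 1] <- alphabet[i %% 4 + 1]
    i <- i %/% 4
  }
  apply(chars, 1, paste, collapse = "")
}

#' Emit paired CEL-seq2-layout FASTQ for a simulated count matrix
#'
#' Every UMI (molecule) in `counts` is given a distinct random UMI sequence
#' within its (cell, gene) pair, and emitted `reads_per_molecule` times:
#' read 1 = UMI || cell barcode || `A` padding; read 2 = a random
#' `read2_length`-substring of the gene's transcript. Reads are shuffled and
#' written as a gzipped FASTQ pair. Because UMIs are distinct within each
#' (cell, gene), counting the output reproduces `counts` exactly.
#'
#' @param counts a [umi_counts()] object whose `cell_meta` carries a distinct
#'   `well` per cell (single plate: at most one cell per well).
#' @param txome transcriptome from [make_transcriptome()] (or any named
#'   `DNAStringSet` covering the counted genes).
#' @param layout a [barcode_layout()].
#' @param reads_per_molecule reads emitted per molecule.
#' @param r1_path,r2_path output FASTQ paths (gzipped when ending in `.gz`).
#' @param seed integer seed for UMI draws, substring starts and shuffling.
#' @return (invisibly) a list with `r1`, `r2` and the molecule `ledger`
#'   tibble (`cell_id`, `gene_id`, `umi`).
#' @export
simulate_fastq <- function(counts, txome, layout, reads_per_molecule = 1,
                           r1_path, r2_path, seed = 1L) {
  stopifnot(inherits(counts, "umi_counts"), inherits(layout, "barcode_layout"))
  mat <- counts$counts
  if (!all(rownames(mat) %in% names(txome))) {
    abort("all counted genes must be present in the transcriptome")
  }
  meta <- counts$cell_meta
  if (!"well" %in% names(meta)) abort("cell_meta must carry a 'well' column")
  if (anyDuplicated(meta$well) > 0) {
    abort("one plate only: each cell needs a distinct well")
  }
  if (!all(meta$well %in% layout$wells$well)) {
    abort("cell wells missing from the barcode layout")
  }
  umi_space <- 4^layout$umi_length
  if (any(mat@x > umi_space)) {
    abort(sprintf("UMI space exhausted: a (cell, gene) count exceeds 4^%d",
                  layout$umi_length))
  }
  barcode_of <- setNames(layout$wells$barcode, layout$wells$well)
  well_of <- setNames(meta$well, meta$cell_id)
  tx <- setNames(as.character(txome), names(txome))

  withr::with_seed(seed, {
    tr <- Matrix::summary(mat)
    tr <- tr[tr$x > 0, , drop = FALSE]
    if (nrow(tr) == 0) {
      ledger <- tibble(
        cell_id = character(), gene_id = character(), umi = character()
      )
    } else {
      umis <- lapply(tr$x, function(k) sample.int(umi_space, k) - 1L)
      ledger <- tibble(
        cell_id = rep(colnames(mat)[tr$j], tr$x),
        gene_id = rep(rownames(mat)[tr$i], tr$x),
        umi = int_to_umi(unlist(umis), layout$umi_length)
      )
    }

    n_mol <- nrow(ledger)
    rpm <- as.integer(reads_per_molecule)
    idx <- rep(seq_len(n_mol), each = rpm)
    n_reads <- length(idx)
    if (n_reads > 0) {
      pad <- strrep("A", layout$read1_length - layout$umi_length -
        layout$barcode_length)
      r1 <- paste0(
        ledger$umi[idx], barcode_of[well_of[ledger$cell_id[idx]]], pad
      )
      seqs <- tx[ledger$gene_id[idx]]
      starts <- floor(runif(n_reads) *
        (nchar(seqs) - layout$read2_length + 1)) + 1
      r2 <- substring(seqs, starts, starts + layout$read2_length - 1)
      ord <- sample.int(n_reads)
      r1 <- r1[ord]
      r2 <- r2[ord]
    } else {
      r1 <- r2 <- character(0)
    }
    ids <- sprintf("read%07d", seq_len(n_reads))
    write_fastq(r1, ids, r1_path)
    write_fastq(r2, ids, r2_path)
    invisible(list(r1 = r1_path, r2 = r2_path, ledger = ledger))
  })
}

write_fastq <- function(seqs, ids, path) {
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- ids
  quals <- Biostrings::BStringSet(strrep("I", nchar(seqs)))
  Biostrings::writeXStringSet(
    dss, path,
    format = "fastq", qualities = quals,
    compress = endsWith(path, ".gz")
  )
  invisible(path)
}
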