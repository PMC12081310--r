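#' ExpressionDataset: the cell x gene carrier used throughout atlasq
#'
#' A lightweight container holding a sparse cell x gene raw count matrix, an
#' optional log-normalized layer of identical shape, and cell / gene metadata
#' tables. Rows are cells, columns are genes (the orientation every atlasq
#' operation assumes).
#'
#' @param counts cell x gene matrix of non-negative integer counts (coerced
#'   to [Matrix::dgCMatrix-class]). Must carry unique row (cell) and column
#'   (gene) names.
#' @param cell_meta data.frame keyed by `cell_id`, one row per cell. Typical
#'   columns: `sample_id`, `tissue`, `stem_cell_source`, `dataset_id`,
#'   `level1`/`level2`/`level3`.
#' @param gene_meta data.frame keyed by `gene_id`, one row per gene, with
#'   optional `symbol` and `biotype` columns.
#' @param lognorm optional cell x gene matrix of log-normalized expression,
#'   same dimnames as `counts`.
#' @return An object of class `ExpressionDataset`.
#' @export
ExpressionDataset <- function(counts, cell_meta = NULL, gene_meta = NULL,
                              lognorm = NULL) {
  counts <- .as_dgc(counts)
  .stop_if(is.null(rownames(counts)) || is.null(colnames(counts)),
           "counts must have cell (row) and gene (column) names")
  .stop_if(anyDuplicated(rownames(counts)) > 0, "duplicate cell ids")
  .stop_if(anyDuplicated(colnames(counts)) > 0, "duplicate gene ids")
  x <- counts@x
  .stop_if(any(x < 0), "counts must be non-negative")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("counts must be integral; round upstream if this is intended",
         call. = FALSE)
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = rownames(counts))
  }
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene_id = colnames(counts))
  }
  .stop_if(!"cell_id" %in% names(cell_meta), "cell_meta needs a cell_id column")
  .stop_if(!"gene_id" %in% names(gene_meta), "gene_meta needs a gene_id column")
  cell_meta <- cell_meta[match(rownames(counts), cell_meta$cell_id), , drop = FALSE]
  gene_meta <- gene_meta[match(colnames(counts), gene_meta$gene_id), , drop = FALSE]
  .stop_if(anyNA(cell_meta$cell_id), "cell_meta does not cover all cells")
  .stop_if(anyNA(gene_meta$gene_id), "gene_meta does not cover all genes")
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  if (!is.null(lognorm)) {
    .stop_if(!identical(dim(lognorm), dim(counts)),
             "lognorm must match counts in shape")
    lognorm <- .as_dgc(lognorm)
    dimnames(lognorm) <- dimnames(counts)
    .stop_if(any(lognorm@x < 0), "lognorm entries must be >= 0")
  }
  structure(list(counts = counts, lognorm = lognorm,
                 cell_meta = cell_meta, gene_meta = gene_meta),
            class = "ExpressionDataset")
}

#' @export
print.ExpressionDataset <- function(x, ...) {
  cat(sprintf("ExpressionDataset: %d cells x %d genes (%s lognorm)\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$lognorm)) "no" else "with"))
  invisible(x)
}

#' @export
dim.ExpressionDataset <- function(x) dim(x$counts)

#' Number of cells / genes in a dataset
#' @param ds an [ExpressionDataset()]
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$counts)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$counts)

#' Cell and gene identifiers
#' @param ds an [ExpressionDataset()]
#' @return character vector of ids in matrix order.
#' @export
cell_ids <- function(ds) rownames(ds$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(ds) colnames(ds$counts)

#' Subset cells and/or genes of a dataset
#'
#' @param x an [ExpressionDataset()]
#' @param i cell index (integer, logical or cell_id character)
#' @param j gene index
#' @param ... ignored
#' @return the subset `ExpressionDataset`; metadata rows follow.
#' @export
`[.ExpressionDataset` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  if (is.character(i)) i <- match(i, rownames(x$counts))
  if (is.character(j)) j <- match(j, colnames(x$counts))
  if (is.logical(i)) i <- which(i)
  if (is.logical(j)) j <- which(j)
  counts <- x$counts[i, j, drop = FALSE]
  lognorm <- if (is.null(x$lognorm)) NULL else x$lognorm[i, j, drop = FALSE]
  out <- x
  out$counts <- counts
  out$lognorm <- lognorm
  out$cell_meta <- x$cell_meta[i, , drop = FALSE]
  out$gene_meta <- x$gene_meta[j, , drop = FALSE]
  rownames(out$cell_meta) <- NULL
  rownames(out$gene_meta) <- NULL
  out
}

#' Read a dataset from disk
#'
#' Two formats are supported. `mtx_dir` expects a directory holding
#' `matrix.mtx` (Matrix Market triplets, cells as rows, 1-based indices per
#' the standard), `cells.tsv` and `genes.tsv` sidecars with a header row and
#' `cell_id` / `gene_id` as first columns. `delimited` expects one dense
#' table: first column cell ids, remaining columns one gene each.
#'
#' @param path directory (`mtx_dir`) or file (`delimited`)
#' @param format one of `"mtx_dir"`, `"delimited"`
#' @param round_counts if TRUE, non-integral entries are rounded instead of
#'   raising a validation error. Off by default.
#' @return an [ExpressionDataset()]
#' @export
read_dataset <- function(path, format = c("mtx_dir", "delimited"),
                         round_counts = FALSE) {
  format <- match.arg(format)
  .stop_if(!file.exists(path), sprintf("path does not exist: %s", path))
  if (format == "mtx_dir") {
    mtx <- file.path(path, "matrix.mtx")
    cf <- file.path(path, "cells.tsv")
    gf <- file.path(path, "genes.tsv")
    for (f in c(mtx, cf, gf)) {
      .stop_if(!file.exists(f), sprintf("missing sidecar or matrix file: %s", f))
    }
    counts <- Matrix::readMM(mtx)
    cells <- utils::read.delim(cf, stringsAsFactors = FALSE)
    genes <- utils::read.delim(gf, stringsAsFactors = FALSE)
    .stop_if(nrow(cells) != nrow(counts), "cells.tsv does not match matrix rows")
    .stop_if(nrow(genes) != ncol(counts), "genes.tsv does not match matrix columns")
    dimnames(counts) <- list(cells$cell_id, genes$gene_id)
    if (round_counts) counts@x <- round(counts@x)
    ExpressionDataset(counts, cell_meta = cells, gene_meta = genes)
  } else {
    tab <- data.table::fread(path, data.table = FALSE)
    ids <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    if (round_counts) m <- round(m)
    ExpressionDataset(m)
  }
}

#' Write a dataset as Matrix Market triplets plus TSV sidecars
#'
#' Inverse of [read_dataset()] for the `mtx_dir` format.
#'
#' @param ds an [ExpressionDataset()]
#' @param path output directory (created if absent)
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(ds$counts, file.path(path, "matrix.mtx"))
  utils::write.table(ds$cell_meta, file.path(path, "cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$gene_meta, file.path(path, "genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Remove low-quality cells
#'
#' Retains exactly the cells with total count >= `min_counts` and number of
#' detected (non-zero) genes >= `min_genes`, preserving order. The default
#' thresholds are deliberately mild; tune them per dataset.
#'
#' @param ds an [ExpressionDataset()]
#' @param min_counts minimum total UMI/read count per cell
#' @param min_genes minimum number of detected genes per cell
#' @return the filtered dataset.
#' @export
filter_cells_qc <- function(ds, min_counts = 500, min_genes = 200) {
  .stop_if(min_counts < 0 || min_genes < 0, "thresholds must be >= 0")
  totals <- Matrix::rowSums(ds$counts)
  detected <- Matrix::rowSums(ds$counts > 0)
  keep <- totals >= min_counts & detected >= min_genes
  .stop_if(!any(keep), "QC filter removed every cell; lower the thresholds")
  ds[which(keep), ]
}

#' Restrict genes to selected biotypes
#'
#' @param ds an [ExpressionDataset()]; `gene_meta` must carry a `biotype`
#'   column.
#' @param keep biotypes to retain. The default keeps protein-coding genes and
#'   long non-coding RNA.
#' @return the filtered dataset.
#' @export
filter_genes_biotype <- function(ds, keep = c("protein_coding", "lncRNA")) {
  .stop_if(!"biotype" %in% names(ds$gene_meta),
           "gene_meta lacks a biotype column")
  sel <- ds$gene_meta$biotype %in% keep
  ds[, which(sel)]
}

#' Total-count normalization followed by log1p
#'
#' Each cell is scaled to a fixed total (`target_sum`, default 10,000) and
#' natural-log transformed: `lognorm[c,g] = ln(1 + counts[c,g] *
#' target_sum / total(c))`. Raw counts are kept untouched.
#'
#' @param ds an [ExpressionDataset()]
#' @param target_sum per-cell total after scaling
#' @return the dataset with the `lognorm` layer filled.
#' @export
normalize_log1p <- function(ds, target_sum = 10000) {
  totals <- Matrix::rowSums(ds$counts)
  .stop_if(any(totals <= 0),
           "cells with zero total count present; run filter_cells_qc first")
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% ds$counts
  scaled <- methods::as(scaled, "CsparseMatrix")
  scaled@x <- log1p(scaled@x)
  dimnames(scaled) <- dimnames(ds$counts)
  ds$lognorm <- scaled
  ds
}

#' Select highly variable genes
#'
#' Mean-binned normalized dispersion: per gene, mean and dispersion
#' (variance / mean) are computed on `expm1(lognorm)`; genes are split into
#' `n_bins` equal-frequency mean bins (bins are widened so that each holds
#' at least 10 genes, avoiding degenerate z-scores on small gene spaces);
#' dispersions are z-scored within each bin; genes are ranked by that
#' z-score, ties broken by gene id. This is the classic single-cell
#' dispersion criterion.
#'
#' @param ds a normalized [ExpressionDataset()]
#' @param n number of genes to select (default 3000)
#' @param n_bins number of mean bins for dispersion normalization
#' @return an object of class `HVGSet`: list with `gene_ids` (ranked), `n`
#'   and `method`.
#' @export
select_hvg <- function(ds, n = 3000, n_bins = 20) {
  .stop_if(is.null(ds$lognorm), "normalize_log1p must be run first")
  .stop_if(n < 1, "n must be >= 1")
  X <- ds$lognorm
  # moments of expm1(lognorm), computed sparsely
  E <- X
  E@x <- expm1(E@x)
  mu <- Matrix::colMeans(E)
  E2 <- E
  E2@x <- E2@x^2
  v <- (Matrix::colSums(E2) - nrow(E) * mu^2) / max(1, nrow(E) - 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  ok <- mu > 0 & disp > 0
  z <- rep(-Inf, ncol(X))
  if (any(ok)) {
    n_bins_eff <- max(1L, min(n_bins, sum(ok) %/% 10L))
    bins <- ggplot2_style_bins(mu[ok], n_bins_eff)
    zs <- disp[ok]
    for (b in unique(bins)) {
      in_b <- bins == b
      m <- mean(zs[in_b])
      s <- stats::sd(zs[in_b])
      if (!is.finite(s) || s == 0) s <- 1
      zs[in_b] <- (zs[in_b] - m) / s
    }
    z[ok] <- zs
  }
  ids <- gene_ids(ds)
  ord <- order(-z, ids)
  n_eff <- min(n, sum(is.finite(z) & z > -Inf))
  if (n > ncol(X)) {
    warning("n exceeds the number of genes; returning all genes")
    n_eff <- min(n_eff, ncol(X))
  }
  structure(list(gene_ids = ids[ord][seq_len(n_eff)], n = n_eff,
                 method = "binned_dispersion"),
            class = "HVGSet")
}

# equal-frequency binning of a vector into at most n_bins groups
ggplot2_style_bins <- function(x, n_bins) {
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(qs) < 3) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

#' @export
print.HVGSet <- function(x, ...) {
  cat(sprintf("HVGSet: %d genes (%s)\n", x$n, x$method))
  invisible(x)
}
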