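#' Sum single-cell counts into per-sample pseudo-bulk
#'
#' Gene counts are summed within each sample; the log layer is
#' `ln(1 + sum)`. Sample covariates carried over from the cell metadata are
#' the per-sample unique values of every categorical column plus total
#' counts and total detected genes.
#'
#' @param ds an [ExpressionDataset()]
#' @param sample_key cell metadata column defining samples
#' @return a `PseudobulkTable`: list with `counts` (sample x gene), `log`,
#'   and `covariates` data.frame.
#' @export
pseudobulk <- function(ds, sample_key = "sample_id") {
  .stop_if(!sample_key %in% names(ds$cell_meta),
           sprintf("cell_meta lacks column %s", sample_key))
  f <- factor(ds$cell_meta[[sample_key]])
  Mdes <- Matrix::sparseMatrix(i = seq_along(f), j = as.integer(f), x = 1,
                               dims = c(length(f), nlevels(f)))
  sums <- as.matrix(Matrix::t(Mdes) %*% ds$counts)
  rownames(sums) <- levels(f)
  covs <- data.frame(sample_id = levels(f), stringsAsFactors = FALSE)
  for (col in setdiff(names(ds$cell_meta), c("cell_id", sample_key))) {
    vals <- tapply(as.character(ds$cell_meta[[col]]), f, function(v) {
      u <- unique(v)
      if (length(u) == 1) u else NA_character_
    })
    if (!all(is.na(vals))) covs[[col]] <- as.character(vals)
  }
  covs$total_counts <- rowSums(sums)
  covs$total_genes <- rowSums(sums > 0)
  structure(list(counts = sums, log = log1p(sums), covariates = covs),
            class = "PseudobulkTable")
}

#' @export
print.PseudobulkTable <- function(x, ...) {
  cat(sprintf("PseudobulkTable: %d samples x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  invisible(x)
}

#' Pseudo-bulk PCA with top/bottom loading genes
#'
#' PCA of the log layer restricted to the most variable genes (genes
#' centered, not scaled). For each of the first `n_pcs` components, the
#' `n_top` highest- and lowest-loading genes are returned together with the
#' sample scores.
#'
#' @param pb a [pseudobulk()] table
#' @param n_hvg genes kept by log-layer variance (default 500; all genes if
#'   fewer)
#' @param n_top loading genes reported per tail (default 200)
#' @param n_pcs components to report (default 2)
#' @return list with `scores` (sample x PC), `loadings`, `top_genes`,
#'   `bottom_genes` (lists per PC), `var_explained`.
#' @export
pca_loadings <- function(pb, n_hvg = 500, n_top = 200, n_pcs = 2) {
  L <- pb$log
  .stop_if(nrow(L) < 3, "need at least 3 samples")
  v <- apply(L, 2, stats::var)
  n_hvg <- min(n_hvg, sum(v > 0))
  genes <- names(sort(v, decreasing = TRUE))[seq_len(n_hvg)]
  X <- L[, genes, drop = FALSE]
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  n_pcs <- min(n_pcs, ncol(pc$rotation))
  top <- list(); bottom <- list()
  for (j in seq_len(n_pcs)) {
    ord <- order(pc$rotation[, j], decreasing = TRUE)
    nt <- min(n_top, length(genes))
    top[[paste0("PC", j)]] <- genes[ord][seq_len(nt)]
    bottom[[paste0("PC", j)]] <- genes[rev(ord)][seq_len(nt)]
  }
  list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
       loadings = pc$rotation[, seq_len(n_pcs), drop = FALSE],
       top_genes = top, bottom_genes = bottom,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Attribute principal-component variance to sample covariates
#'
#' For each principal component and covariate, a one-way linear model
#' (one-hot for categoricals, raw for numerics) is fitted and its R-squared
#' reported — the fraction of that component's variance the covariate
#' explains. Constant covariates (or categoricals with a single level) are
#' skipped with a warning.
#'
#' @param scores sample x PC matrix (e.g. `pca_loadings()$scores`)
#' @param covariates data.frame of sample covariates, rows aligned
#' @return data.frame: PC, covariate, r_squared.
#' @export
covariate_variance <- function(scores, covariates) {
  scores <- as.matrix(scores)
  .stop_if(nrow(scores) != nrow(covariates), "row mismatch")
  rows <- list()
  for (cv in names(covariates)) {
    x <- covariates[[cv]]
    if (is.character(x)) x <- factor(x)
    nlev <- if (is.factor(x)) nlevels(droplevels(x[!is.na(x)])) else
      length(unique(x[!is.na(x)]))
    if (nlev < 2) {
      warning(sprintf("covariate %s is constant; skipped", cv))
      next
    }
    for (j in seq_len(ncol(scores))) {
      fit <- stats::lm(scores[, j] ~ x)
      r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits warn
      rows[[length(rows) + 1]] <- data.frame(
        PC = colnames(scores)[j] %||% paste0("PC", j), covariate = cv,
        r_squared = r2, stringsAsFactors = FALSE)
    }
  }
  .stop_if(length(rows) == 0, "no usable covariates")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
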