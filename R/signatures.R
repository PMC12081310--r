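#' Score drug-target signatures per cell
#'
#' The raw score of a signature in a cell is the mean log-normalized
#' expression over the signature's genes present in the dataset; the scaled
#' score is a per-signature z-score across all cells (mean 0, sd 1).
#' Signatures with no gene present are skipped with a warning; a scaled
#' column whose raw scores are constant is set to zero and flagged.
#'
#' @param ds a normalized [ExpressionDataset()]
#' @param signatures named list of gene vectors (e.g. [read_gmt()])
#' @return a `SignatureScores`: list with `raw`, `scaled` (cell x
#'   signature), `n_genes_used`, `constant` flags.
#' @export
score_signatures <- function(ds, signatures) {
  .stop_if(is.null(ds$lognorm), "dataset must be normalized")
  .stop_if(length(signatures) == 0, "no signatures supplied")
  ids <- gene_ids(ds)
  L <- ds$lognorm
  raw <- list(); used <- integer(0)
  for (nm in names(signatures)) {
    genes <- intersect(signatures[[nm]], ids)
    if (length(genes) == 0) {
      warning(sprintf("signature %s has no gene in the dataset; skipped", nm))
      next
    }
    raw[[nm]] <- Matrix::rowSums(L[, genes, drop = FALSE]) / length(genes)
    used[nm] <- length(genes)
  }
  .stop_if(length(raw) == 0, "no scorable signatures")
  raw <- do.call(cbind, raw)
  rownames(raw) <- cell_ids(ds)
  sds <- apply(raw, 2, stats::sd)
  constant <- sds == 0
  scaled <- sweep(raw, 2, colMeans(raw))
  scaled <- sweep(scaled, 2, ifelse(constant, 1, sds), "/")
  structure(list(raw = raw, scaled = scaled, n_genes_used = used,
                 constant = constant),
            class = "SignatureScores")
}

#' Assign signatures to cell types by the majority-above-median rule
#'
#' A signature is assigned to a cell type when strictly more than 50% of
#' that type's cells have a scaled score strictly above the signature's
#' median over all cells. A signature assigned to at least two cell types
#' is flagged multicellular. Cell types with fewer than `min_cells` cells
#' are skipped with a warning.
#'
#' @param scores a [score_signatures()] result
#' @param cell_type_labels per-cell type labels, aligned with the scores
#' @param min_cells minimum cells per scored type (default 5)
#' @return a `SignatureAssignment`: list with `assigned` (type x signature
#'   logical), `exceedance` (fractions above median), `multicellular`
#'   (named logical per signature).
#' @export
assign_to_celltypes <- function(scores, cell_type_labels, min_cells = 5) {
  S <- scores$scaled
  labs <- as.character(cell_type_labels)
  .stop_if(length(labs) != nrow(S), "label length mismatch")
  types <- sort(unique(labs))
  .stop_if(length(types) < 2, "need at least two cell types")
  counts <- table(labs)
  small <- names(counts)[counts < min_cells]
  if (length(small) > 0) {
    warning(sprintf("cell type(s) with < %d cells skipped: %s",
                    min_cells, paste(small, collapse = ", ")))
    types <- setdiff(types, small)
  }
  med <- apply(S, 2, stats::median)
  exceed <- matrix(NA_real_, length(types), ncol(S),
                   dimnames = list(types, colnames(S)))
  for (ty in types) {
    m <- labs == ty
    exceed[ty, ] <- colMeans(S[m, , drop = FALSE] >
                               matrix(med, sum(m), ncol(S), byrow = TRUE))
  }
  assigned <- exceed > 0.5
  multicellular <- colSums(assigned) >= 2
  structure(list(assigned = assigned, exceedance = exceed,
                 multicellular = multicellular),
            class = "SignatureAssignment")
}

#' Cosine similarity between cell types over multicellular signatures
#'
#' Each cell type is represented by its binary membership vector over the
#' multicellular signatures; pairwise cosine similarity is reported. A type
#' with an all-zero vector gets NA against every other type.
#'
#' @param assignment an [assign_to_celltypes()] result
#' @return symmetric type x type similarity matrix (possibly 0 x 0 with a
#'   warning when no signature is multicellular).
#' @export
celltype_cosine <- function(assignment) {
  mc <- assignment$multicellular
  if (!any(mc)) {
    warning("no multicellular signatures; returning empty table")
    return(matrix(numeric(0), 0, 0))
  }
  Mb <- assignment$assigned[, mc, drop = FALSE] * 1
  norms <- sqrt(rowSums(Mb^2))
  S <- Mb %*% t(Mb) / outer(norms, norms)
  S[norms == 0, ] <- NA_real_
  S[, norms == 0] <- NA_real_
  S
}
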