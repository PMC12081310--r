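#' Reconstruct a matched atlas reference per query cell
#'
#' For every query cell, the mean log-normalized expression of its k = 10
#' nearest reference cells is taken as the cell's matched reference profile
#' (its paired control for differential expression), and the mean of the k
#' neighbour distances is the cell's distance to the atlas.
#'
#' @param model a [fit_reference()] model
#' @param query_coords cells x d latent coordinates from [transform_query()]
#' @param k neighbours to average (default 10)
#' @return an object of class `MatchedReference`: list with `profile`
#'   (cells x model-genes matrix), `distance_to_atlas` (numeric vector) and
#'   `neighbors`.
#' @export
matched_reference <- function(model, query_coords, k = 10) {
  .stop_if(k > nrow(model$coords), "k exceeds the reference size")
  nn <- knn_search(model, query_coords, k = k)
  L <- .dense(model$lognorm)
  prof <- matrix(0, nrow(nn$index), ncol(L),
                 dimnames = list(rownames(query_coords), colnames(L)))
  for (i in seq_len(nrow(prof))) {
    prof[i, ] <- colMeans(L[nn$index[i, ], , drop = FALSE])
  }
  structure(list(profile = prof,
                 distance_to_atlas = rowMeans(nn$dist),
                 neighbors = nn, k = k),
            class = "MatchedReference")
}

#' @export
print.MatchedReference <- function(x, ...) {
  cat(sprintf("MatchedReference: %d cells, k = %d, median distance %.3g\n",
              nrow(x$profile), x$k, stats::median(x$distance_to_atlas)))
  invisible(x)
}

#' ROC curve and AUROC from distances
#'
#' Thresholds sweep the distances with higher values called positive; tied
#' distances step simultaneously; the area is the trapezoidal integral
#' (equivalently the tie-adjusted Mann-Whitney probability).
#'
#' @param distances numeric scores (e.g. distance to atlas)
#' @param binary_labels logical or 0/1; TRUE = positive class
#' @return list with `fpr`, `tpr`, `thresholds`, `auroc`.
#' @export
roc_from_distances <- function(distances, binary_labels) {
  y <- as.logical(binary_labels)
  .stop_if(!any(y) || all(y), "both classes must be present")
  ord <- order(distances, decreasing = TRUE)
  d <- distances[ord]
  yy <- y[ord]
  # collapse tied thresholds into single steps
  grp <- cumsum(!duplicated(d))
  tp <- cumsum(yy)
  fp <- cumsum(!yy)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(y))
  fpr <- c(0, fp[last] / sum(!y))
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr,
       thresholds = c(Inf, d[last]), auroc = auroc)
}

#' Detect disease-associated cell states by cluster enrichment
#'
#' Jointly embeds the combined normal + disease subset (PCA on highly
#' variable genes of the subset), clusters it with Leiden at the requested
#' resolution, and calls a cluster a disease state when its disease-cell
#' fraction both exceeds the global disease fraction by a factor of at least
#' `tau` and is an outright majority (> 0.5). All other clusters are
#' reference-like.
#'
#' @param ds the combined normalized [ExpressionDataset()] (normal + disease
#'   cells)
#' @param disease_mask logical: TRUE for cells from the disease sample
#' @param resolution Leiden resolution (the workflows use 1 or 2)
#' @param n_hvg HVGs for the subset embedding (default 3000, capped at the
#'   gene count)
#' @param d embedding dimensionality
#' @param tau enrichment factor over the global disease fraction
#' @param seed clustering seed
#' @return a `StateCall`: data.frame per cell with `cluster`, `state`; per
#'   cluster summary in attribute `clusters`.
#' @export
detect_states <- function(ds, disease_mask, resolution = 1, n_hvg = 3000,
                          d = 30, tau = 1.5, seed = 0) {
  .stop_if(is.null(ds$lognorm), "dataset must be normalized")
  .stop_if(!any(disease_mask) || all(disease_mask),
           "need both disease and non-disease cells")
  hvg <- suppressWarnings(select_hvg(ds, n = min(n_hvg, n_genes(ds))))
  X <- .dense(ds$lognorm[, hvg$gene_ids, drop = FALSE])
  Xc <- sweep(X, 2, colMeans(X))
  emb <- Xc %*% .pca_rotation(Xc, min(d, ncol(Xc)))
  rownames(emb) <- cell_ids(ds)
  cl <- cluster_graph(emb, k = min(30, n_cells(ds) - 1),
                      resolution = resolution, seed = seed)
  memb <- cl$cluster
  global_frac <- mean(disease_mask)
  summ <- do.call(rbind, lapply(sort(unique(memb)), function(c0) {
    m <- memb == c0
    frac <- mean(disease_mask[m])
    data.frame(cluster = c0, n = sum(m), disease_fraction = frac,
               disease_state = frac > 0.5 & frac >= tau * global_frac)
  }))
  if (nrow(summ) == 1) {
    warning("single cluster found; all cells called reference-like")
    summ$disease_state <- FALSE
  }
  state <- ifelse(summ$disease_state[match(memb, summ$cluster)],
                  "disease-state", "reference-like")
  out <- data.frame(cluster = memb, state = state,
                    row.names = cell_ids(ds))
  attr(out, "clusters") <- summ
  class(out) <- c("StateCall", "data.frame")
  out
}
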