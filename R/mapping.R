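#' Fit a linear reference model over a frozen HVG space
#'
#' Centers and scales the log-normalized expression of the reference over
#' the highly variable genes, computes a rank-`d` PCA projection, and stores
#' everything needed to place out-of-sample queries in the same latent
#' space: the frozen gene list, per-gene center/scale, rotation matrix,
#' reference coordinates and reference labels. This linear embedding is a
#' deliberately transparent stand-in for trained integration models; an
#' externally trained embedding can be substituted by building a model from
#' coordinate files with the same fields.
#'
#' @param ds a normalized, labelled reference [ExpressionDataset()]
#' @param hvg an [select_hvg()] result (or character vector of gene ids)
#' @param d latent dimensionality (default 30)
#' @param layout_dims how many leading latent dims double as the 2D layout
#' @return an object of class `ReferenceModel`.
#' @export
fit_reference <- function(ds, hvg, d = 30, layout_dims = 2) {
  .stop_if(is.null(ds$lognorm), "reference must be normalized first")
  genes <- if (inherits(hvg, "HVGSet")) hvg$gene_ids else as.character(hvg)
  .stop_if(!all(genes %in% gene_ids(ds)), "hvg genes missing from dataset")
  .stop_if(d > length(genes), "d exceeds the number of HVGs")
  X <- .dense(ds$lognorm[, genes, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl < 1e-8] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  rotation <- .pca_rotation(Xs, d)
  rownames(rotation) <- genes
  coords <- Xs %*% rotation
  rownames(coords) <- cell_ids(ds)
  label_cols <- intersect(c("tissue", "level1", "level2", "level3", "sample_id"),
                          names(ds$cell_meta))
  labels <- ds$cell_meta[, label_cols, drop = FALSE]
  rownames(labels) <- cell_ids(ds)
  layout <- coords[, seq_len(min(layout_dims, d)), drop = FALSE]
  structure(list(gene_ids = genes, center = ctr, scale = scl,
                 rotation = rotation, coords = coords, labels = labels,
                 lognorm = ds$lognorm[, genes, drop = FALSE],
                 layout = layout, d = d),
            class = "ReferenceModel")
}

#' @export
print.ReferenceModel <- function(x, ...) {
  cat(sprintf("ReferenceModel: %d cells, %d genes, %d latent dims\n",
              nrow(x$coords), length(x$gene_ids), x$d))
  invisible(x)
}

#' Project a query dataset into the reference latent space
#'
#' Query genes are aligned to the model's frozen gene list by id; model
#' genes absent from the query are zero-filled (their count is reported in
#' attribute `n_zero_filled`); the reference center/scale and rotation are
#' then applied unchanged.
#'
#' @param model a [fit_reference()] model
#' @param ds a normalized query [ExpressionDataset()]
#' @param max_missing maximum tolerated fraction of model genes absent from
#'   the query (default 0.5)
#' @return cells x d coordinate matrix.
#' @export
transform_query <- function(model, ds, max_missing = 0.5) {
  .stop_if(is.null(ds$lognorm), "query must be normalized first")
  genes <- model$gene_ids
  present <- genes %in% gene_ids(ds)
  if (mean(!present) > max_missing) {
    stop(sprintf("only %.0f%% of model genes found in query; insufficient overlap",
                 100 * mean(present)), call. = FALSE)
  }
  X <- matrix(0, n_cells(ds), length(genes),
              dimnames = list(cell_ids(ds), genes))
  X[, genes[present]] <- .dense(ds$lognorm[, genes[present], drop = FALSE])
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  coords <- Xs %*% model$rotation
  attr(coords, "n_zero_filled") <- sum(!present)
  coords
}

#' Exact k-nearest-neighbour search against the reference
#'
#' Euclidean distances in latent space; ties broken by reference cell
#' index. Matches a brute-force all-pairs scan exactly.
#'
#' @param model a [fit_reference()] model
#' @param query_coords cells x d matrix from [transform_query()]
#' @param k neighbours per query cell
#' @return list with integer `index` and numeric `dist` matrices
#'   (cells x k, distances ascending).
#' @export
knn_search <- function(model, query_coords, k) {
  .stop_if(k <= 0, "k must be positive")
  .stop_if(k > nrow(model$coords), "k exceeds the reference size")
  .knn_euclidean(model$coords, query_coords, k = k)
}

#' Transfer labels from reference neighbours
#'
#' Each query cell receives the modal label among its k nearest reference
#' neighbours; confidence is the modal fraction. Ties go to the label with
#' the larger summed inverse distance, then lexicographic order.
#'
#' @param neighbors a [knn_search()] result
#' @param ref_labels data.frame of reference labels (rows in reference
#'   order) or a vector
#' @param field label column to transfer when `ref_labels` is a data.frame
#' @param k neighbours to use (default 100; must not exceed the search k)
#' @return data.frame with `label` and `confidence` per query cell.
#' @export
transfer_labels <- function(neighbors, ref_labels, field = NULL, k = 100) {
  labs <- if (is.data.frame(ref_labels)) {
    .stop_if(is.null(field), "field required for data.frame labels")
    as.character(ref_labels[[field]])
  } else as.character(ref_labels)
  .stop_if(anyNA(labs), "reference labels contain missing values")
  .stop_if(ncol(neighbors$index) < k, "neighbor table has fewer than k columns")
  idx <- neighbors$index[, seq_len(k), drop = FALSE]
  dst <- neighbors$dist[, seq_len(k), drop = FALSE]
  n <- nrow(idx)
  label <- character(n)
  conf <- numeric(n)
  for (i in seq_len(n)) {
    li <- labs[idx[i, ]]
    tab <- table(li)
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      w <- vapply(top, function(l) sum(1 / pmax(dst[i, li == l], 1e-12)),
                  numeric(1))
      top <- top[w == max(w)]
      top <- sort(top)
    }
    label[i] <- top[1]
    conf[i] <- max(tab) / k
  }
  data.frame(label = label, confidence = conf,
             row.names = rownames(neighbors$index))
}

#' On-target fraction of a projected query
#'
#' A query cell is on-target when its predicted reference tissue matches the
#' tissue the organoid protocol intended.
#'
#' @param pred_tissue character vector of predicted tissues per cell
#' @param expected_tissue the intended tissue
#' @param confidence optional per-cell label-transfer confidence
#' @return list with `fraction`, logical `on_target` flags, and mean
#'   confidence within the on- and off-target groups (NULL when a group is
#'   empty).
#' @export
on_target_fraction <- function(pred_tissue, expected_tissue, confidence = NULL) {
  .stop_if(length(expected_tissue) != 1 || !nzchar(expected_tissue),
           "expected_tissue must be a single non-empty string")
  flags <- pred_tissue == expected_tissue
  out <- list(fraction = mean(flags), on_target = flags,
              mean_confidence_on = NULL, mean_confidence_off = NULL)
  if (!is.null(confidence)) {
    if (any(flags)) out$mean_confidence_on <- mean(confidence[flags])
    if (any(!flags)) out$mean_confidence_off <- mean(confidence[!flags])
  }
  out
}

#' Place query cells in the reference 2D layout
#'
#' Out-of-sample transform into the stored 2D layout by inverse-distance
#' weighted barycentric placement among the k nearest reference cells (a
#' query coinciding with a reference cell lands exactly on it). This is the
#' default layout transform; models built from an external embedding can
#' store any 2D layout and are transformed the same way.
#'
#' @param model a [fit_reference()] model with a fitted layout
#' @param query_coords cells x d latent coordinates
#' @param k neighbours used for the barycentric weights
#' @return cells x 2 layout matrix.
#' @export
transform_layout <- function(model, query_coords, k = 10) {
  .stop_if(is.null(model$layout), "model has no fitted 2D layout; refit")
  nn <- .knn_euclidean(model$coords, query_coords, k = min(k, nrow(model$coords)))
  out <- matrix(NA_real_, nrow(nn$index), ncol(model$layout))
  rownames(out) <- rownames(query_coords)
  for (i in seq_len(nrow(out))) {
    d <- nn$dist[i, ]
    if (d[1] == 0) {
      out[i, ] <- model$layout[nn$index[i, 1], ]
    } else {
      w <- 1 / d
      w <- w / sum(w)
      out[i, ] <- colSums(model$layout[nn$index[i, ], , drop = FALSE] * w)
    }
  }
  out
}

#' Serialize / load a reference model as plain-text files
#'
#' Writes gene list, scaling, rotation, coordinates, labels, layout and the
#' reference lognorm slice as TSVs under a directory.
#'
#' @param model a [fit_reference()] model
#' @param path output directory
#' @return `path` invisibly.
#' @export
write_reference <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(path, f), sep = "\t",
                                          quote = FALSE, col.names = NA)
  utils::write.table(data.frame(gene_id = model$gene_ids,
                                center = model$center, scale = model$scale),
                     file.path(path, "scaling.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wt(model$rotation, "rotation.tsv")
  wt(model$coords, "coords.tsv")
  wt(model$labels, "labels.tsv")
  wt(model$layout, "layout.tsv")
  Matrix::writeMM(model$lognorm, file.path(path, "lognorm.mtx"))
  writeLines(as.character(model$d), file.path(path, "dims.txt"))
  invisible(path)
}

#' @rdname write_reference
#' @param path directory written by [write_reference()]
#' @export
read_reference <- function(path) {
  sc <- utils::read.delim(file.path(path, "scaling.tsv"))
  rd <- function(f) {
    m <- utils::read.delim(file.path(path, f), row.names = 1, check.names = FALSE)
    as.matrix(m)
  }
  rotation <- rd("rotation.tsv")
  coords <- rd("coords.tsv")
  labels <- utils::read.delim(file.path(path, "labels.tsv"), row.names = 1,
                              check.names = FALSE)
  layout <- rd("layout.tsv")
  lognorm <- methods::as(Matrix::readMM(file.path(path, "lognorm.mtx")),
                         "CsparseMatrix")
  dimnames(lognorm) <- list(rownames(coords), sc$gene_id)
  structure(list(gene_ids = sc$gene_id,
                 center = stats::setNames(sc$center, sc$gene_id),
                 scale = stats::setNames(sc$scale, sc$gene_id),
                 rotation = rotation, coords = coords, labels = labels,
                 lognorm = lognorm, layout = layout,
                 d = as.integer(readLines(file.path(path, "dims.txt")))),
            class = "ReferenceModel")
}
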