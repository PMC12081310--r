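#' Build kNN neighbourhoods with mean expression profiles
#'
#' Milo-style neighbourhood construction: a fraction `prop` of cells is
#' sampled uniformly (seeded) as index cells; each neighbourhood consists of
#' its index cell plus the k - 1 nearest cells in the given representation;
#' the neighbourhood profile is the mean log-normalized expression of its
#' members over a shared HVG list. Neighbourhood annotations (cell type,
#' sample, ...) are the modal annotation of the members.
#'
#' @param coords cell x dim embedding (2D layout or latent space)
#' @param lognorm cell x gene log-normalized matrix, rows aligned to
#'   `coords`
#' @param hvg_shared gene ids shared between the datasets to be compared
#' @param k neighbourhood size, index cell included (default 30)
#' @param prop fraction of cells sampled as index cells (default 0.1)
#' @param seed sampling seed
#' @param annotations optional data.frame of per-cell annotations
#' @return a `NeighborhoodSet`: list with `index_cells`, `members`,
#'   `profiles` (neighbourhood x gene) and `annotations`.
#' @export
build_neighborhoods <- function(coords, lognorm, hvg_shared, k = 30,
                                prop = 0.1, seed = 0, annotations = NULL) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  .stop_if(k > n, "k must not exceed the number of cells")
  .stop_if(prop <= 0 || prop > 1, "prop must be in (0, 1]")
  hvg_shared <- as.character(hvg_shared)
  .stop_if(length(hvg_shared) == 0, "hvg_shared is empty")
  .stop_if(!all(hvg_shared %in% colnames(lognorm)),
           "hvg_shared contains genes absent from lognorm")
  set.seed(seed)
  idx <- sort(sample.int(n, ceiling(prop * n)))
  nn <- .knn_euclidean(coords, coords[idx, , drop = FALSE], k = k)
  # make sure the index cell itself is a member (it is its own 0-distance
  # neighbour unless duplicated coordinates push it out by the index
  # tie-break; force it in that case)
  members <- lapply(seq_along(idx), function(i) {
    m <- nn$index[i, ]
    if (!idx[i] %in% m) m[k] <- idx[i]
    m
  })
  L <- .dense(lognorm[, hvg_shared, drop = FALSE])
  profiles <- t(vapply(members, function(m) colMeans(L[m, , drop = FALSE]),
                       numeric(length(hvg_shared))))
  colnames(profiles) <- hvg_shared
  ann <- NULL
  if (!is.null(annotations)) {
    ann <- do.call(rbind, lapply(members, function(m) {
      as.data.frame(lapply(annotations[m, , drop = FALSE], function(col) {
        tab <- table(as.character(col))
        sort(names(tab)[tab == max(tab)])[1]
      }), stringsAsFactors = FALSE)
    }))
  }
  structure(list(index_cells = idx, members = members, profiles = profiles,
                 annotations = ann, k = k),
            class = "NeighborhoodSet")
}

#' @export
print.NeighborhoodSet <- function(x, ...) {
  cat(sprintf("NeighborhoodSet: %d neighbourhoods of size %d over %d genes\n",
              length(x$index_cells), x$k, ncol(x$profiles)))
  invisible(x)
}

#' Correlate every pair of neighbourhoods across two datasets
#'
#' Pearson correlation over the shared genes for each neighbourhood pair.
#' Constant profiles have undefined correlation and are recorded as NA
#' (excluded from downstream summaries).
#'
#' @param A,B [build_neighborhoods()] results with identical gene order
#' @return a `SimilarityMatrix`: list with `S` (nA x nB), `ann_a`, `ann_b`.
#' @export
cross_correlate <- function(A, B) {
  .stop_if(!identical(colnames(A$profiles), colnames(B$profiles)),
           "profiles must share an identical gene order")
  .stop_if(ncol(A$profiles) < 3, "need at least 3 shared genes")
  S <- suppressWarnings(stats::cor(t(A$profiles), t(B$profiles)))
  structure(list(S = S, ann_a = A$annotations, ann_b = B$annotations),
            class = "SimilarityMatrix")
}

#' Summarize a similarity matrix per annotation group
#'
#' For each neighbourhood of A, the maximum similarity over all
#' neighbourhoods of B is taken (NAs dropped); the per-neighbourhood maxima
#' are then aggregated within annotation groups by `stat`.
#'
#' @param sim a [cross_correlate()] result
#' @param by annotation column of the A-side neighbourhoods
#' @param stat `"max"` or `"median"` aggregation within groups
#' @return data.frame: group, value, n_neighborhoods.
#' @export
summarize_similarity <- function(sim, by = "celltype",
                                 stat = c("max", "median")) {
  stat <- match.arg(stat)
  .stop_if(is.null(sim$ann_a) || !by %in% names(sim$ann_a),
           sprintf("A-side annotations lack column %s", by))
  best <- apply(sim$S, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) == 0) NA_real_ else max(r)
  })
  groups <- as.character(sim$ann_a[[by]])
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    v <- best[groups == g & is.finite(best)]
    if (length(v) == 0) {
      warning(sprintf("group %s has no finite similarities; skipped", g))
      return(NULL)
    }
    data.frame(group = g,
               value = if (stat == "max") max(v) else stats::median(v),
               n_neighborhoods = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Contrast similarity matrices between derivation protocols
#'
#' Given one similarity matrix per protocol, all aligned on the same primary
#' tissue neighbourhoods, returns elementwise difference matrices for every
#' protocol pair.
#'
#' @param sims named list of matrices (or [cross_correlate()] results) with
#'   identical dimensions
#' @return named list of difference matrices, one per ordered protocol pair
#'   (`"A-B"` = A minus B).
#' @export
contrast_protocols <- function(sims) {
  mats <- lapply(sims, function(s) if (inherits(s, "SimilarityMatrix")) s$S else s)
  .stop_if(length(mats) < 2, "need at least two protocols")
  dims <- vapply(mats, function(m) paste(dim(m), collapse = "x"), character(1))
  .stop_if(length(unique(dims)) != 1, "similarity matrices are misaligned")
  out <- list()
  nms <- names(mats)
  for (i in seq_along(mats)) for (j in seq_along(mats)) {
    if (i != j) out[[paste(nms[i], nms[j], sep = "-")]] <- mats[[i]] - mats[[j]]
  }
  out
}
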