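#' Leiden clustering on a kNN graph
#'
#' Builds an exact Euclidean kNN graph (undirected union of neighbour sets)
#' on the given embedding and partitions it with the Leiden algorithm at the
#' requested resolution. The random seed is fixed so results are
#' reproducible; cluster ids are contiguous integers starting at 0, numbered
#' by first occurrence.
#'
#' @param embedding cell x dim numeric matrix (rows named by cell id)
#' @param k number of nearest neighbours for the graph (default 30)
#' @param resolution Leiden resolution parameter (the atlas workflows use 2
#'   for annotation and 10 for reannotation)
#' @param seed RNG seed for the Leiden optimiser
#' @return an object of class `ClusterAssignment`: list with `cluster`
#'   (named integer vector), `resolution`, `k`, `method`.
#' @export
cluster_graph <- function(embedding, k = 30, resolution = 1, seed = 0) {
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  .stop_if(n < 2, "need at least two cells")
  .stop_if(k >= n, "k must be smaller than the number of cells")
  nn <- .knn_euclidean(embedding, embedding, k = k, exclude_self = TRUE)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn$index)))
  edges <- t(apply(edges, 1, sort))
  edges <- unique(edges)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 10)
  memb <- igraph::membership(cl)
  relab <- match(memb, unique(memb)) - 1L
  names(relab) <- rownames(embedding)
  structure(list(cluster = relab, resolution = resolution, k = k,
                 method = "leiden", seed = seed),
            class = "ClusterAssignment")
}

#' @export
print.ClusterAssignment <- function(x, ...) {
  cat(sprintf("ClusterAssignment: %d cells, %d clusters (resolution %.2g)\n",
              length(x$cluster), length(unique(x$cluster)), x$resolution))
  invisible(x)
}

#' Marker AUC: in-cluster vs out-of-cluster ROC area for one gene
#'
#' The probability that a random in-cluster cell expresses the gene higher
#' than a random out-of-cluster cell, counting ties as one half. Equal to
#' the Mann-Whitney U statistic divided by `n_in * n_out`.
#'
#' @param expr numeric expression values, one per cell
#' @param in_cluster logical mask of the same length
#' @return the AUC in \[0, 1\].
#' @export
marker_auc <- function(expr, in_cluster) {
  n1 <- sum(in_cluster)
  n2 <- sum(!in_cluster)
  .stop_if(n1 == 0 || n2 == 0, "both classes must be non-empty")
  r <- rank(expr)
  (sum(r[in_cluster]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Marker fold change on the log scale
#'
#' Difference of mean log-normalized expression between in-cluster and
#' out-of-cluster cells (natural-log fold change given a log1p layer).
#'
#' @inheritParams marker_auc
#' @return the log fold change (can be negative).
#' @export
marker_fc <- function(expr, in_cluster) {
  .stop_if(sum(in_cluster) == 0 || sum(!in_cluster) == 0,
           "both classes must be non-empty")
  mean(expr[in_cluster]) - mean(expr[!in_cluster])
}

#' Score candidate labels against clusters at one taxonomy level
#'
#' For each cluster and candidate label, every marker gene of the label is
#' scored with [marker_auc()] and [marker_fc()] against the cluster; the
#' maximum AUC and maximum fold change over the label's markers are
#' averaged into a single score, and the label with the highest score is
#' assigned. At levels 2 and 3 candidates are restricted to children of the
#' cluster's assigned parent label.
#'
#' @param ds a normalized [ExpressionDataset()]
#' @param clusters a [cluster_graph()] result (or named integer vector)
#' @param taxonomy a [LabelTaxonomy()]
#' @param level taxonomy level to annotate (1, 2 or 3)
#' @param parent_assignment named character vector mapping cluster id to the
#'   label assigned at `level - 1`; required for level > 1
#' @return a `TypeScoreTable`: data.frame with columns cluster, label,
#'   auc_max, fc_max, score, assigned, tie; attribute `assignment` maps
#'   cluster to label.
#' @export
score_types <- function(ds, clusters, taxonomy, level = 1,
                        parent_assignment = NULL) {
  .stop_if(is.null(ds$lognorm), "dataset must be normalized")
  memb <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster else clusters
  .stop_if(level > 1 && is.null(parent_assignment),
           "parent_assignment is required for level > 1")
  X <- .dense(ds$lognorm)
  ids <- gene_ids(ds)
  cluster_ids <- sort(unique(memb))
  rows <- list()
  assignment <- character(0)
  for (cl in cluster_ids) {
    mask <- memb == cl
    cands <- if (level == 1) taxonomy_labels(taxonomy, 1) else
      taxonomy_labels(taxonomy, level, parent = parent_assignment[[as.character(cl)]])
    .stop_if(length(cands) == 0,
             sprintf("no candidate labels at level %d for cluster %s", level, cl))
    for (lab in cands) {
      mk <- taxonomy_markers(taxonomy, lab)
      present <- mk[mk %in% ids]
      if (length(present) < length(mk)) {
        warning(sprintf("label %s: %d marker gene(s) missing, dropped",
                        lab, length(mk) - length(present)))
      }
      if (length(present) == 0) {
        warning(sprintf("label %s excluded: no markers present", lab))
        next
      }
      aucs <- vapply(present, function(g) marker_auc(X[, g], mask), numeric(1))
      fcs <- vapply(present, function(g) marker_fc(X[, g], mask), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        cluster = cl, label = lab,
        auc_max = max(aucs), fc_max = max(fcs),
        score = (max(aucs) + max(fcs)) / 2,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$assigned <- FALSE
  tab$tie <- FALSE
  for (cl in cluster_ids) {
    sub <- tab[tab$cluster == cl, , drop = FALSE]
    best <- max(sub$score)
    winners <- sort(sub$label[sub$score == best])
    pick <- winners[1]
    sel <- tab$cluster == cl & tab$label == pick
    tab$assigned[sel] <- TRUE
    if (length(winners) > 1) tab$tie[tab$cluster == cl] <- TRUE
    assignment[as.character(cl)] <- pick
  }
  attr(tab, "assignment") <- assignment
  attr(tab, "level") <- level
  class(tab) <- c("TypeScoreTable", "data.frame")
  tab
}

#' Annotate a full label hierarchy, top-down
#'
#' Runs [score_types()] at level 1, then levels 2 and 3 with candidates
#' restricted to children of each cluster's assigned parent.
#'
#' @inheritParams score_types
#' @param max_level deepest level to annotate
#' @return named list of per-level assignment vectors (`level1`, ...), plus
#'   the score tables in attribute `tables`.
#' @export
annotate_hierarchy <- function(ds, clusters, taxonomy, max_level = 2) {
  assignments <- list()
  tables <- list()
  parent <- NULL
  for (lv in seq_len(max_level)) {
    if (length(taxonomy_labels(taxonomy, lv)) == 0) break
    tab <- score_types(ds, clusters, taxonomy, level = lv,
                       parent_assignment = parent)
    parent <- attr(tab, "assignment")
    assignments[[paste0("level", lv)]] <- parent
    tables[[paste0("level", lv)]] <- tab
  }
  attr(assignments, "tables") <- tables
  assignments
}

#' Majority-vote cluster reannotation
#'
#' Assigns every cluster the modal label of its member cells. Ties go first
#' to the label most abundant in the whole dataset, then lexicographically.
#'
#' @param clusters a [cluster_graph()] result or named integer vector
#' @param cell_labels character vector of provisional per-cell labels,
#'   aligned with the clustering
#' @return named character vector: cluster id -> label.
#' @export
majority_reannotate <- function(clusters, cell_labels) {
  memb <- if (inherits(clusters, "ClusterAssignment")) clusters$cluster else clusters
  .stop_if(length(memb) != length(cell_labels), "length mismatch")
  .stop_if(anyNA(cell_labels), "every cell needs a provisional label")
  global <- table(cell_labels)
  out <- character(0)
  for (cl in sort(unique(memb))) {
    tab <- table(cell_labels[memb == cl])
    top <- names(tab)[tab == max(tab)]
    if (length(top) > 1) {
      g <- global[top]
      top <- top[g == max(g)]
      top <- sort(top)
    }
    out[as.character(cl)] <- top[1]
  }
  out
}

#' Refine marker genes by one-vs-rest Wilcoxon tests
#'
#' For each label, a tie-corrected Wilcoxon rank-sum test compares its cells
#' with all other cells per gene; the `top_n` genes by z statistic (ties by
#' p, then gene id) become the refined markers. The union of all refined
#' markers is hierarchically clustered (average linkage on correlation
#' distance across cells). Cells are subsampled uniformly when the dataset
#' exceeds `subsample`.
#'
#' @param ds a normalized [ExpressionDataset()]
#' @param labels per-cell label vector
#' @param subsample maximum cells used (default 100,000)
#' @param top_n markers kept per label
#' @param seed subsampling seed
#' @return list with `markers` (label -> gene vector), `dendrogram`
#'   (an `hclust` over the marker union, NULL when fewer than 3 genes) and
#'   `stats` (long data.frame of per-gene statistics).
#' @export
refine_markers <- function(ds, labels, subsample = 100000, top_n = 10,
                           seed = 0) {
  .stop_if(is.null(ds$lognorm), "dataset must be normalized")
  labs <- as.character(labels)
  .stop_if(length(unique(labs)) < 2, "need at least two labels")
  n <- n_cells(ds)
  idx <- seq_len(n)
  if (n > subsample) {
    set.seed(seed)
    idx <- sort(sample.int(n, subsample))
  }
  X <- .dense(ds$lognorm[idx, , drop = FALSE])
  labs <- labs[idx]
  ids <- gene_ids(ds)
  markers <- list()
  stats_rows <- list()
  for (lab in sort(unique(labs))) {
    mask <- labs == lab
    if (sum(mask) < 3) {
      warning(sprintf("label %s has < 3 cells; skipped", lab))
      next
    }
    st <- .rank_sum_stats(X, mask)
    ord <- order(-st$z, st$p, ids)
    markers[[lab]] <- ids[ord][seq_len(min(top_n, length(ids)))]
    stats_rows[[lab]] <- data.frame(label = lab, gene_id = ids,
                                    z = st$z, p = st$p,
                                    stringsAsFactors = FALSE)
  }
  union_genes <- sort(unique(unlist(markers)))
  dend <- NULL
  if (length(union_genes) >= 3) {
    cm <- stats::cor(X[, union_genes, drop = FALSE])
    cm[!is.finite(cm)] <- 0
    dend <- stats::hclust(stats::as.dist(1 - cm), method = "average")
  }
  list(markers = markers, dendrogram = dend,
       stats = do.call(rbind, stats_rows))
}
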