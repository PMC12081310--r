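#' Hierarchical marker-gene label taxonomy
#'
#' A three-level tree of cell labels (class, type, subtype). Each node has a
#' level in 1..3, a parent (NULL at level 1) and a non-empty marker gene
#' list. Level-2 nodes must have a level-1 parent, level-3 nodes a level-2
#' parent.
#'
#' @param nodes named list; each element a list with `level`, `markers` and
#'   optional `parent`.
#' @return an object of class `LabelTaxonomy`.
#' @export
LabelTaxonomy <- function(nodes) {
  .stop_if(length(nodes) == 0, "taxonomy has no nodes")
  .stop_if(is.null(names(nodes)) || anyDuplicated(names(nodes)) > 0,
           "nodes must be uniquely named")
  for (nm in names(nodes)) {
    nd <- nodes[[nm]]
    .stop_if(!nd$level %in% 1:3, sprintf("node %s: level must be 1..3", nm))
    .stop_if(length(nd$markers) == 0,
             sprintf("node %s: marker list must be non-empty", nm))
    if (nd$level == 1) {
      .stop_if(!is.null(nd$parent), sprintf("node %s: level-1 nodes have no parent", nm))
    } else {
      .stop_if(is.null(nd$parent) || !nd$parent %in% names(nodes),
               sprintf("node %s: parent missing from taxonomy", nm))
      .stop_if(nodes[[nd$parent]]$level != nd$level - 1,
               sprintf("node %s: parent must sit one level up", nm))
    }
  }
  structure(list(nodes = nodes), class = "LabelTaxonomy")
}

#' Read a taxonomy from nested JSON
#'
#' Expected shape: `{"Epithelial": {"markers": [...], "children": {"Goblet":
#' {"markers": [...], "children": {...}}}}`. Levels are implied by nesting
#' depth (1 at the top).
#'
#' @param path JSON file
#' @return a [LabelTaxonomy()]
#' @export
read_taxonomy_json <- function(path) {
  raw <- jsonlite::read_json(path)
  nodes <- list()
  walk <- function(tree, level, parent) {
    for (nm in names(tree)) {
      nd <- tree[[nm]]
      nodes[[nm]] <<- list(level = level,
                           parent = parent,
                           markers = unlist(nd$markers, use.names = FALSE))
      if (!is.null(nd$children)) walk(nd$children, level + 1, nm)
    }
  }
  walk(raw, 1, NULL)
  LabelTaxonomy(nodes)
}

#' Labels at a taxonomy level, optionally restricted to a parent
#' @param tax a [LabelTaxonomy()]
#' @param level 1, 2 or 3
#' @param parent if given, only children of this label are returned
#' @return character vector of labels.
#' @export
taxonomy_labels <- function(tax, level, parent = NULL) {
  keep <- vapply(tax$nodes, function(nd) {
    nd$level == level && (is.null(parent) || identical(nd$parent, parent))
  }, logical(1))
  names(tax$nodes)[keep]
}

#' Marker genes of one taxonomy node
#' @param tax a [LabelTaxonomy()]
#' @param label node name
#' @return character vector of marker gene ids.
#' @export
taxonomy_markers <- function(tax, label) {
  .stop_if(!label %in% names(tax$nodes), sprintf("unknown label: %s", label))
  tax$nodes[[label]]$markers
}

#' @export
print.LabelTaxonomy <- function(x, ...) {
  lv <- vapply(x$nodes, `[[`, numeric(1), "level")
  cat(sprintf("LabelTaxonomy: %d nodes (%d/%d/%d at levels 1/2/3)\n",
              length(lv), sum(lv == 1), sum(lv == 2), sum(lv == 3)))
  invisible(x)
}
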