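#' Assemble a run configuration
#'
#' Central bundle of the workflow parameters: k = 100 for label transfer,
#' k = 10 for the matched reference, per-cell total 10,000, 3,000 HVGs and
#' BH alpha 0.05 by default. The configuration is serialized next to every
#' run's outputs for provenance.
#'
#' @param k_label neighbours for label / tissue transfer
#' @param k_match neighbours for the matched reference
#' @param target_sum normalization total
#' @param n_hvg highly variable genes
#' @param alpha BH significance level
#' @param seed workflow seed
#' @param out_dir output directory (NULL = no files written)
#' @return a `RunConfig` list.
#' @export
run_config <- function(k_label = 100, k_match = 10, target_sum = 10000,
                       n_hvg = 3000, alpha = 0.05, seed = 0, out_dir = NULL) {
  .stop_if(k_label < 1 || k_match < 1, "all k must be >= 1")
  structure(list(k_label = k_label, k_match = k_match,
                 target_sum = target_sum, n_hvg = n_hvg, alpha = alpha,
                 seed = seed, out_dir = out_dir),
            class = "RunConfig")
}

.write_run_outputs <- function(out_dir, config, per_cell, report) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, null = "null")
  utils::write.table(per_cell, file.path(out_dir, "per_cell.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(NULL)
}

#' Incorporate a query dataset into a reference atlas
#'
#' End-to-end recipe: normalize the query, project it into the reference
#' latent space, transfer tissue and level-1/2 labels from the k = 100
#' nearest neighbours, reconstruct the k = 10 matched reference and distance
#' to atlas, and tabulate per-sample predicted-tissue proportions. Writes
#' `per_cell.tsv`, `report.json` and `config.json` when `config$out_dir` is
#' set.
#'
#' @param model a [fit_reference()] model
#' @param query an [ExpressionDataset()] (raw counts; normalized internally)
#' @param config a [run_config()]
#' @param expected_tissue optional intended tissue for on-target accounting
#' @return a report list with `per_cell` (data.frame), `proportions`,
#'   `on_target`, `matched` (a [matched_reference()] object) and `coords`.
#' @export
run_incorporate <- function(model, query, config = run_config(),
                            expected_tissue = NULL) {
  step <- function(tag, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", tag, conditionMessage(e)), call. = FALSE))
  }
  q <- step("normalize", {
    if (is.null(query$lognorm)) normalize_log1p(query, config$target_sum)
    else query
  })
  coords <- step("transform", transform_query(model, q))
  k_use <- min(config$k_label, nrow(model$coords))
  nn <- step("knn", knn_search(model, coords, k = k_use))
  preds <- list()
  for (field in intersect(c("tissue", "level1", "level2"),
                          names(model$labels))) {
    preds[[field]] <- step("transfer",
                           transfer_labels(nn, model$labels, field, k = k_use))
  }
  matched <- step("matched_reference",
                  matched_reference(model, coords, k = config$k_match))
  per_cell <- data.frame(cell_id = cell_ids(q), stringsAsFactors = FALSE)
  for (field in names(preds)) {
    per_cell[[paste0("pred_", field)]] <- preds[[field]]$label
    per_cell[[paste0("conf_", field)]] <- preds[[field]]$confidence
  }
  per_cell$distance_to_atlas <- matched$distance_to_atlas
  per_cell$sample_id <- q$cell_meta$sample_id
  proportions <- NULL
  if ("tissue" %in% names(preds)) {
    proportions <- as.data.frame(prop.table(
      table(sample_id = per_cell$sample_id, tissue = per_cell$pred_tissue),
      margin = 1), stringsAsFactors = FALSE)
  }
  on_target <- NULL
  if (!is.null(expected_tissue) && "tissue" %in% names(preds)) {
    on_target <- on_target_fraction(per_cell$pred_tissue, expected_tissue,
                                    per_cell$conf_tissue)
  }
  report <- list(n_cells = nrow(per_cell),
                 median_distance = stats::median(matched$distance_to_atlas),
                 on_target_fraction =
                   if (is.null(on_target)) NULL else on_target$fraction,
                 k_label = k_use, k_match = config$k_match)
  .write_run_outputs(config$out_dir, config, per_cell, report)
  list(per_cell = per_cell, proportions = proportions, on_target = on_target,
       matched = matched, coords = coords, report = report)
}

#' Assess two perturbation conditions against the atlas cohort
#'
#' Incorporates a control and a treated dataset, runs the paired F test of
#' each against its matched atlas reference, categorizes the DEGs across the
#' two conditions, optionally scores gene-set enrichment of each category,
#' and compares distance-to-atlas between conditions per predicted cell type
#' (two-sided Mann-Whitney).
#'
#' @param model a [fit_reference()] model
#' @param control,treated raw [ExpressionDataset()]s
#' @param config a [run_config()]
#' @param gene_sets optional named list for [fisher_enrichment()]
#' @return list with `incorporation` (per condition), `de` (per condition),
#'   `categories`, `enrichment`, `distance_tests`.
#' @export
run_perturbation_assessment <- function(model, control, treated,
                                        config = run_config(),
                                        gene_sets = NULL) {
  inc_c <- run_incorporate(model, control, config)
  inc_t <- run_incorporate(model, treated, config)
  q_c <- normalize_log1p(control, config$target_sum)
  q_t <- normalize_log1p(treated, config$target_sum)
  de_c <- paired_f_test(q_c$lognorm[, model$gene_ids, drop = FALSE],
                        inc_c$matched$profile, alpha = config$alpha)
  de_t <- paired_f_test(q_t$lognorm[, model$gene_ids, drop = FALSE],
                        inc_t$matched$profile, alpha = config$alpha)
  cats <- categorize_degs(de_t, de_c, alpha = config$alpha)
  enrich <- NULL
  if (!is.null(gene_sets)) {
    enrich <- lapply(cats, function(gs) {
      if (length(gs) == 0) return(NULL)
      fisher_enrichment(gs, gene_sets, universe = de_c$gene)
    })
  }
  # distance comparison per predicted level-2 type
  dist_tests <- NULL
  if ("pred_level2" %in% names(inc_c$per_cell)) {
    types <- intersect(unique(inc_c$per_cell$pred_level2),
                       unique(inc_t$per_cell$pred_level2))
    rows <- lapply(types, function(ty) {
      a <- inc_c$per_cell$distance_to_atlas[inc_c$per_cell$pred_level2 == ty]
      b <- inc_t$per_cell$distance_to_atlas[inc_t$per_cell$pred_level2 == ty]
      if (length(a) < 3 || length(b) < 3) return(NULL)
      data.frame(cell_type = ty, median_control = stats::median(a),
                 median_treated = stats::median(b),
                 p = stats::wilcox.test(a, b, exact = FALSE)$p.value,
                 stringsAsFactors = FALSE)
    })
    dist_tests <- do.call(rbind, rows)
  }
  list(incorporation = list(control = inc_c, treated = inc_t),
       de = list(control = de_c, treated = de_t),
       categories = cats, enrichment = enrich, distance_tests = dist_tests)
}
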