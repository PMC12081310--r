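#' Specification of a synthetic multi-tissue atlas
#'
#' Describes the generative world used by all tests: several tissues, each
#' with a handful of cell types carrying exclusive marker programs; one
#' shared type per tissue (a goblet-like lineage present in every tissue)
#' whose base program is identical across tissues apart from small
#' tissue-specific offsets, making tissue prediction for those cells
#' non-trivial; a fetal-to-adult maturation gradient acting on epithelial
#' types; negative-binomial counts with log-normal library sizes.
#'
#' @param n_tissues number of tissues (default 3)
#' @param types_per_tissue cell types per tissue; the last one is the shared
#'   lineage when `shared_type` is TRUE (default 4)
#' @param n_genes total genes (default 3000, mirroring the usual
#'   highly-variable-gene working space)
#' @param markers_per_type exclusive marker genes per type program
#' @param marker_log_fold natural-log fold elevation of marker genes
#' @param shared_type if TRUE the last type of every tissue shares one base
#'   program (same level-2 label across tissues)
#' @param shared_offset_sd sd of the per-tissue gene offsets added to the
#'   shared program (default 0.1)
#' @param n_maturation_genes genes loading on the maturation axis
#' @param maturation_log_fold log-fold change across the full 0 -> 1
#'   maturation range
#' @param libsize_meanlog,libsize_sdlog log-normal library size parameters
#' @param dispersion negative-binomial dispersion (variance = mu + disp *
#'   mu^2); 0 gives Poisson counts
#' @param seed seed fixing the gene programs (and default data seed)
#' @return an object of class `SimSpec`.
#' @export
sim_spec <- function(n_tissues = 3, types_per_tissue = 4, n_genes = 3000,
                     markers_per_type = 20, marker_log_fold = 2.0,
                     shared_type = TRUE, shared_offset_sd = 0.1,
                     n_maturation_genes = 100, maturation_log_fold = 1.0,
                     libsize_meanlog = log(2000), libsize_sdlog = 0.3,
                     dispersion = 0.5, seed = 0) {
  .stop_if(n_tissues < 1 || types_per_tissue < 1, "degenerate spec")
  .stop_if(marker_log_fold < 0, "marker_log_fold must be >= 0")
  structure(list(n_tissues = n_tissues, types_per_tissue = types_per_tissue,
                 n_genes = n_genes, markers_per_type = markers_per_type,
                 marker_log_fold = marker_log_fold, shared_type = shared_type,
                 shared_offset_sd = shared_offset_sd,
                 n_maturation_genes = n_maturation_genes,
                 maturation_log_fold = maturation_log_fold,
                 libsize_meanlog = libsize_meanlog,
                 libsize_sdlog = libsize_sdlog,
                 dispersion = dispersion, seed = seed),
            class = "SimSpec")
}

# Deterministic gene programs implied by a spec (keyed only by spec$seed so
# reference and query draws share the exact same world).
.build_programs <- function(spec) {
  set.seed(spec$seed)
  genes <- sprintf("gene%04d", seq_len(spec$n_genes))
  baseline <- stats::rnorm(spec$n_genes, 0, 0.5)
  tissues <- sprintf("tissue%d", seq_len(spec$n_tissues))
  combos <- expand.grid(type_idx = seq_len(spec$types_per_tissue),
                        tissue = tissues, stringsAsFactors = FALSE)
  is_shared <- spec$shared_type & combos$type_idx == spec$types_per_tissue
  combos$level2 <- ifelse(is_shared, "shared_goblet",
                          paste0(sub("tissue", "t", combos$tissue), "_type",
                                 combos$type_idx))
  combos$level1 <- ifelse(combos$type_idx == 3, "mesenchymal", "epithelial")
  # one marker block per distinct level-2 label
  labels <- unique(combos$level2)
  n_blocks <- length(labels)
  .stop_if(n_blocks * spec$markers_per_type + spec$n_maturation_genes >
             spec$n_genes, "not enough genes for the requested programs")
  marker_idx <- split(seq_len(n_blocks * spec$markers_per_type),
                      rep(seq_len(n_blocks), each = spec$markers_per_type))
  names(marker_idx) <- labels
  mat_idx <- seq(n_blocks * spec$markers_per_type + 1,
                 length.out = spec$n_maturation_genes)
  programs <- matrix(rep(baseline, each = nrow(combos)), nrow(combos),
                     spec$n_genes, dimnames = list(NULL, genes))
  for (i in seq_len(nrow(combos))) {
    programs[i, marker_idx[[combos$level2[i]]]] <-
      programs[i, marker_idx[[combos$level2[i]]]] + spec$marker_log_fold
  }
  # tissue offsets for the shared lineage
  offsets <- matrix(0, spec$n_tissues, spec$n_genes,
                    dimnames = list(tissues, genes))
  if (spec$shared_type) {
    for (t in tissues) offsets[t, ] <- stats::rnorm(spec$n_genes, 0,
                                                    spec$shared_offset_sd)
    for (i in which(is_shared)) {
      programs[i, ] <- programs[i, ] + offsets[combos$tissue[i], ]
    }
  }
  mat_w <- numeric(spec$n_genes)
  mat_w[mat_idx] <- spec$maturation_log_fold
  list(genes = genes, combos = combos, programs = programs,
       marker_idx = marker_idx, maturation_weights = mat_w)
}

# negative-binomial draw tolerating dispersion 0 (Poisson limit)
.rcounts <- function(n, mu, dispersion) {
  if (dispersion <= 0) stats::rpois(n, mu) else
    stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

# expected counts for given cells (rows of internals) over all genes
.cell_mu <- function(world, cells) {
  logm <- world$programs[world$combo_of_cell[cells], , drop = FALSE]
  mat <- world$maturation[cells]
  logm <- logm + outer(mat, world$maturation_weights)
  p <- exp(logm)
  p <- p / rowSums(p)
  p * world$libsize[cells]
}

.generate_cells <- function(spec, pg, combo_rows, maturation, prefix, seed,
                            sample_of_tissue = 2) {
  set.seed(seed)
  n <- length(combo_rows)
  libsize <- stats::rlnorm(n, spec$libsize_meanlog, spec$libsize_sdlog)
  world <- list(programs = pg$programs, combo_of_cell = combo_rows,
                maturation = maturation,
                maturation_weights = pg$maturation_weights,
                libsize = libsize)
  mu <- .cell_mu(world, seq_len(n))
  counts <- matrix(.rcounts(length(mu), as.vector(mu), spec$dispersion),
                   n, spec$n_genes)
  dimnames(counts) <- list(sprintf("%s_c%05d", prefix, seq_len(n)), pg$genes)
  tissue <- pg$combos$tissue[combo_rows]
  sample_id <- sprintf("%s_%s_s%d", prefix, tissue,
                       1 + (sample(seq_len(n)) %% sample_of_tissue))
  cell_meta <- data.frame(cell_id = rownames(counts),
                          sample_id = sample_id, tissue = tissue,
                          stem_cell_source = "unknown",
                          dataset_id = prefix,
                          level1 = pg$combos$level1[combo_rows],
                          level2 = pg$combos$level2[combo_rows],
                          stringsAsFactors = FALSE)
  gene_meta <- data.frame(gene_id = pg$genes, symbol = pg$genes,
                          biotype = "protein_coding",
                          stringsAsFactors = FALSE)
  ds <- ExpressionDataset(counts, cell_meta, gene_meta)
  list(ds = ds, world = world)
}

#' Simulate a labelled multi-tissue reference atlas
#'
#' Cells are allocated evenly across all tissue x type combinations; counts
#' follow a negative binomial around softmax-normalized programs scaled by
#' log-normal library sizes; a uniform maturation value drives the
#' fetal-to-adult gradient on epithelial types. Fully determined by
#' `spec$seed` and `seed`.
#'
#' @param spec a [sim_spec()]
#' @param n_cells total reference cells (default 6000)
#' @param seed data-generation seed (defaults to `spec$seed`)
#' @return an `AtlasSimulation`: list with `ds` (an [ExpressionDataset()]),
#'   `truth` (per-cell ground-truth data.frame), `spec` and generator
#'   internals.
#' @export
simulate_reference <- function(spec, n_cells = 6000, seed = spec$seed) {
  pg <- .build_programs(spec)
  n_combo <- nrow(pg$combos)
  combo_rows <- rep(seq_len(n_combo), length.out = n_cells)
  set.seed(seed + 1L)
  maturation <- stats::runif(n_cells)
  maturation[pg$combos$level1[combo_rows] != "epithelial"] <- 0
  sim <- .generate_cells(spec, pg, combo_rows, maturation, "ref", seed)
  truth <- data.frame(cell_id = cell_ids(sim$ds),
                      tissue = pg$combos$tissue[combo_rows],
                      level1 = pg$combos$level1[combo_rows],
                      level2 = pg$combos$level2[combo_rows],
                      maturation = maturation,
                      off_target = FALSE, perturbed = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(ds = sim$ds, truth = truth, spec = spec, programs = pg,
                 world = sim$world),
            class = "AtlasSimulation")
}

#' Simulate a query dataset with planted off-target cells
#'
#' On-target cells are drawn from the target tissue's type programs; a
#' planted fraction comes from the exclusive types of the other tissues
#' (`off_target` in the ground truth). `maturation_shift` displaces the
#' query's maturation values, emulating fetal- versus adult-like states.
#'
#' @param spec the [sim_spec()] used for the reference (the gene programs
#'   are shared through `spec$seed`)
#' @param target_tissue tissue the query emulates (default `"tissue1"`)
#' @param n_cells query size (default 1000)
#' @param off_target_fraction planted off-target fraction in \[0, 1)
#' @param maturation_shift added to every epithelial cell's maturation value
#' @param type_weights sampling weights over the target tissue's types, by
#'   type index. The default (two dominant epithelial types, a smaller
#'   mesenchymal pool, a minority shared secretory lineage) emulates typical
#'   organoid composition; used only when `types_per_tissue` is 4, otherwise
#'   uniform.
#' @param seed data-generation seed
#' @return an `AtlasSimulation` (query flavour).
#' @export
simulate_query <- function(spec, target_tissue = "tissue1", n_cells = 1000,
                           off_target_fraction = 0, maturation_shift = 0,
                           type_weights = NULL,
                           seed = spec$seed + 1000) {
  .stop_if(off_target_fraction < 0 || off_target_fraction >= 1,
           "off_target_fraction must be in [0, 1)")
  pg <- .build_programs(spec)
  on_rows <- which(pg$combos$tissue == target_tissue)
  off_rows <- which(pg$combos$tissue != target_tissue &
                      pg$combos$level2 != "shared_goblet")
  .stop_if(length(on_rows) == 0, "unknown target tissue")
  if (is.null(type_weights)) {
    type_weights <- if (spec$types_per_tissue == 4) c(0.35, 0.35, 0.2, 0.1)
      else rep(1, length(on_rows))
  }
  .stop_if(length(type_weights) != length(on_rows),
           "type_weights must have one entry per target-tissue type")
  n_off <- round(off_target_fraction * n_cells)
  set.seed(seed)
  combo_rows <- c(sample(on_rows, n_cells - n_off, replace = TRUE,
                         prob = type_weights),
                  if (n_off > 0) sample(off_rows, n_off, replace = TRUE))
  maturation <- stats::runif(n_cells)
  is_epi <- pg$combos$level1[combo_rows] == "epithelial"
  maturation[!is_epi] <- 0
  maturation[is_epi] <- maturation[is_epi] + maturation_shift
  sim <- .generate_cells(spec, pg, combo_rows, maturation, "query", seed + 1L)
  truth <- data.frame(cell_id = cell_ids(sim$ds),
                      tissue = pg$combos$tissue[combo_rows],
                      level1 = pg$combos$level1[combo_rows],
                      level2 = pg$combos$level2[combo_rows],
                      maturation = maturation,
                      off_target = seq_len(n_cells) > n_cells - n_off,
                      perturbed = FALSE,
                      stringsAsFactors = FALSE)
  structure(list(ds = sim$ds, truth = truth, spec = spec, programs = pg,
                 world = sim$world, target_tissue = target_tissue),
            class = "AtlasSimulation")
}

#' Inject a known expression perturbation into simulated cells
#'
#' The expected counts of the selected cells are multiplied by
#' `exp(log_fold)` for the selected genes and those entries are redrawn from
#' the count model; everything else is untouched. Ground truth records the
#' perturbed cells and genes.
#'
#' @param sim an `AtlasSimulation`
#' @param genes gene ids to perturb
#' @param log_fold natural-log fold change applied to their means
#' @param cell_mask logical mask of cells to perturb
#' @param seed redraw seed
#' @return the updated `AtlasSimulation` (lognorm layer dropped; re-run
#'   [normalize_log1p()]).
#' @export
inject_perturbation <- function(sim, genes, log_fold, cell_mask,
                                seed = sim$spec$seed + 2000) {
  .stop_if(!inherits(sim, "AtlasSimulation"), "sim must be an AtlasSimulation")
  .stop_if(!all(genes %in% gene_ids(sim$ds)), "unknown genes in perturbation")
  if (!any(cell_mask)) {
    warning("empty cell mask; returning the simulation unchanged")
    return(sim)
  }
  cells <- which(cell_mask)
  mu <- .cell_mu(sim$world, cells)[, genes, drop = FALSE] * exp(log_fold)
  set.seed(seed)
  block <- matrix(.rcounts(length(mu), as.vector(mu), sim$spec$dispersion),
                  nrow(mu), ncol(mu))
  counts <- as.matrix(sim$ds$counts)
  counts[cells, genes] <- block
  sim$ds <- ExpressionDataset(counts, sim$ds$cell_meta, sim$ds$gene_meta)
  sim$truth$perturbed[cells] <- TRUE
  attr(sim$truth, "perturbed_genes") <- genes
  attr(sim$truth, "perturbation_log_fold") <- log_fold
  sim
}

#' Program genes of a simulation
#'
#' The genes carrying planted structure: all marker-block genes plus the
#' maturation-axis genes. Perturbations placed on these genes emulate
#' disease or cytokine states that modulate cell-identity programs — the
#' kind of shift a reference embedding trained on atlas variation can see.
#' Perturbations on unstructured background genes are near-orthogonal to
#' any atlas-derived latent space and largely invisible to it.
#'
#' @param sim an `AtlasSimulation`
#' @return character vector of gene ids.
#' @export
sim_program_genes <- function(sim) {
  pg <- sim$programs
  unique(c(pg$genes[unlist(pg$marker_idx, use.names = FALSE)],
           pg$genes[pg$maturation_weights != 0]))
}

#' Build a marker taxonomy matching a simulation's ground truth
#'
#' Levels 1 and 2 of the planted world with the true marker blocks, usable
#' directly by [score_types()] / [annotate_hierarchy()].
#'
#' @param sim an `AtlasSimulation`
#' @return a [LabelTaxonomy()]
#' @export
sim_taxonomy <- function(sim) {
  pg <- sim$programs
  nodes <- list()
  for (l1 in unique(pg$combos$level1)) {
    kids <- unique(pg$combos$level2[pg$combos$level1 == l1])
    l1_markers <- pg$genes[unlist(pg$marker_idx[kids], use.names = FALSE)]
    nodes[[l1]] <- list(level = 1, markers = l1_markers)
    for (l2 in kids) {
      nodes[[l2]] <- list(level = 2, parent = l1,
                          markers = pg$genes[pg$marker_idx[[l2]]])
    }
  }
  LabelTaxonomy(nodes)
}
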