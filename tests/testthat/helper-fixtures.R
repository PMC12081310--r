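# Shared fixtures. Everything is generated in code; heavyweight worlds are
# memoized so several test files can reuse them within one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# a tiny deterministic dataset from explicit counts
make_ds <- function(counts, biotype = NULL, normalize = FALSE, ...) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("c%02d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("g%02d", seq_len(ncol(counts)))
  gm <- data.frame(gene_id = colnames(counts))
  if (!is.null(biotype)) gm$biotype <- biotype
  ds <- ExpressionDataset(counts, gene_meta = gm, ...)
  if (normalize) ds <- normalize_log1p(ds)
  ds
}

# random count dataset
random_ds <- function(n_cells = 50, n_genes = 20, seed = 1, lambda = 5,
                      normalize = FALSE) {
  set.seed(seed)
  m <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes)
  make_ds(m, normalize = normalize)
}

# small simulated world shared by mapping / assessment tests:
# 2400-cell reference with fitted model, scaled down from the acceptance
# world for speed (same generator, same structure)
small_world <- function() memo("small_world", {
  spec <- sim_spec(seed = 42, n_genes = 1000)
  ref <- simulate_reference(spec, n_cells = 2400)
  ref$ds <- normalize_log1p(ref$ds)
  hvg <- suppressWarnings(select_hvg(ref$ds, n = 1000))
  model <- fit_reference(ref$ds, hvg, d = 30)
  list(spec = spec, ref = ref, model = model)
})

# full-size acceptance world: 6000-cell reference, 3000 genes
acceptance_world <- function() memo("acceptance_world", {
  spec <- sim_spec(seed = 7)
  ref <- simulate_reference(spec, n_cells = 6000)
  ref$ds <- normalize_log1p(ref$ds)
  hvg <- suppressWarnings(select_hvg(ref$ds, n = 3000))
  model <- fit_reference(ref$ds, hvg, d = 30)
  list(spec = spec, ref = ref, model = model)
})

# brute-force kNN oracle: per-pair distance loop, ties by reference index
brute_knn <- function(ref, query, k) {
  idx <- matrix(NA_integer_, nrow(query), k)
  dst <- matrix(NA_real_, nrow(query), k)
  for (i in seq_len(nrow(query))) {
    d <- numeric(nrow(ref))
    for (j in seq_len(nrow(ref))) d[j] <- sqrt(sum((query[i, ] - ref[j, ])^2))
    o <- order(d, seq_along(d))[seq_len(k)]
    idx[i, ] <- o
    dst[i, ] <- d[o]
  }
  list(index = idx, dist = dst)
}

# exhaustive pair-counting AUC oracle
brute_auc <- function(x_in, x_out) {
  wins <- 0
  for (a in x_in) for (b in x_out) {
    wins <- wins + (a > b) + 0.5 * (a == b)
  }
  wins / (length(x_in) * length(x_out))
}
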