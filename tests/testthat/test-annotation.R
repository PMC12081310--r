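test_that("marker_auc matches exhaustive pair counting and handles ties", {
  expect_equal(marker_auc(c(1, 2, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(marker_auc(rep(3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(marker_auc(c(1, 3, 2, 4), c(TRUE, TRUE, FALSE, FALSE)), 0.25)
  expect_error(marker_auc(1:3, rep(TRUE, 3)), "non-empty")

  set.seed(21)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    x <- sample(0:5, n, replace = TRUE)  # discrete, so ties occur
    mask <- seq_len(n) %in% sample(n, sample(2:(n - 2), 1))
    expect_equal(marker_auc(x, mask), brute_auc(x[mask], x[!mask]),
                 tolerance = 1e-12)
    # class swap property
    expect_equal(marker_auc(x, mask), 1 - marker_auc(x, !mask),
                 tolerance = 1e-12)
    # strictly monotone transform invariance
    expect_equal(marker_auc(exp(x) + x, mask), marker_auc(x, mask))
  }
})

test_that("marker_fc is the difference of group means", {
  x <- c(2, 2, 0.5, 0.5)
  expect_equal(marker_fc(x, c(TRUE, TRUE, FALSE, FALSE)), 1.5)
  expect_equal(marker_fc(rep(1, 4), c(TRUE, TRUE, FALSE, FALSE)), 0)
  set.seed(22)
  y <- rnorm(30)
  m <- rep(c(TRUE, FALSE), 15)
  expect_equal(marker_fc(y, m), mean(y[m]) - mean(y[!m]))
})

test_that("cluster_graph separates well-separated blobs deterministically", {
  set.seed(31)
  emb <- rbind(matrix(rnorm(100 * 2), 100, 2),
               matrix(rnorm(100 * 2, mean = 10), 100, 2))
  rownames(emb) <- paste0("c", 1:200)
  # modularity optima on kNN graphs subdivide even pure Gaussian blobs at
  # resolution 1 (leidenalg behaves identically); the blobs come out whole
  # at a coarser resolution and are never mixed at resolution 1
  cl_coarse <- cluster_graph(emb, k = 30, resolution = 0.5, seed = 0)
  expect_equal(length(unique(cl_coarse$cluster)), 2)
  truth <- rep(0:1, each = 100)
  cl <- cluster_graph(emb, k = 30, resolution = 1, seed = 0)
  # purity 1.0: each cluster maps to exactly one blob
  expect_equal(max(table(cl$cluster, truth) %*% c(1, 1) -
                     apply(table(cl$cluster, truth), 1, max)), 0)
  cl2 <- cluster_graph(emb, k = 30, resolution = 1, seed = 0)
  expect_identical(cl$cluster, cl2$cluster)

  same <- matrix(1, 10, 2, dimnames = list(paste0("x", 1:10), NULL))
  expect_equal(length(unique(cluster_graph(same, k = 3, resolution = 1)$cluster)), 1)
  expect_error(cluster_graph(same, k = 10), "smaller")
})

test_that("score_types assigns planted programs and respects hierarchy", {
  # one cluster; label A has a perfectly up marker, label B a flat one
  lognorm <- cbind(gA = c(2, 2, 2, 0, 0, 0), gB = rep(1, 6))
  ds <- make_ds(matrix(1, 6, 2, dimnames = list(NULL, c("gA", "gB"))))
  ds$lognorm <- atlasq:::.as_dgc(matrix(lognorm, 6, 2,
                                        dimnames = dimnames(ds$counts)))
  tax <- LabelTaxonomy(list(A = list(level = 1, markers = "gA"),
                            B = list(level = 1, markers = "gB")))
  clusters <- setNames(c(0L, 0L, 0L, 1L, 1L, 1L), cell_ids(ds))
  tab <- score_types(ds, clusters, tax, level = 1)
  expect_equal(attr(tab, "assignment")[["0"]], "A")

  # identical markers tie, broken lexicographically and flagged
  tax2 <- LabelTaxonomy(list(Zeta = list(level = 1, markers = "gA"),
                             Alpha = list(level = 1, markers = "gA")))
  tab2 <- score_types(ds, clusters, tax2, level = 1)
  expect_equal(unname(attr(tab2, "assignment")), rep("Alpha", 2))
  expect_true(all(tab2$tie))

  # missing markers are dropped with a warning, label with none excluded
  tax3 <- LabelTaxonomy(list(A = list(level = 1, markers = c("gA", "gX")),
                             B = list(level = 1, markers = "gY")))
  warns <- capture_warnings(score_types(ds, clusters, tax3, 1))
  expect_true(any(grepl("missing", warns)))
  expect_true(any(grepl("excluded", warns)))
})

test_that("hierarchical annotation recovers a planted 3-type atlas", {
  w <- small_world()
  sub <- w$ref$ds[1:600, ]
  truth <- w$ref$truth[1:600, ]
  tax <- sim_taxonomy(w$ref)
  clusters <- setNames(as.integer(factor(truth$level2)) - 1L, cell_ids(sub))
  ann <- annotate_hierarchy(sub, clusters, tax, max_level = 2)
  lv1 <- ann$level1
  lv2 <- ann$level2
  for (cl in names(lv2)) {
    members <- clusters == as.integer(cl)
    expect_equal(unname(lv2[cl]), unique(truth$level2[members]))
    # hierarchy consistency: level-2 label is a child of the level-1 label
    expect_equal(w$ref$programs$combos$level1[
      match(lv2[cl], w$ref$programs$combos$level2)], unname(lv1[cl]))
  }
})

test_that("majority_reannotate follows the documented tie rules", {
  cl <- setNames(c(0L, 0L, 0L), c("a", "b", "c"))
  expect_equal(unname(majority_reannotate(cl, c("A", "A", "B"))), "A")
  # tie inside the cluster goes to the globally more abundant label
  cl2 <- setNames(c(0L, 0L, 1L, 1L, 1L), letters[1:5])
  expect_equal(unname(majority_reannotate(cl2, c("A", "B", "B", "B", "B"))[1]), "B")
  set.seed(33)
  memb <- setNames(sample(0:3, 200, replace = TRUE), paste0("c", 1:200))
  labs <- sample(LETTERS[1:5], 200, replace = TRUE)
  got <- majority_reannotate(memb, labs)
  for (cl0 in unique(memb)) {
    tab <- table(labs[memb == cl0])
    expect_true(got[as.character(cl0)] %in% names(tab)[tab == max(tab)])
  }
})

test_that("refine_markers ranks planted genes first and matches wilcox.test", {
  set.seed(34)
  n <- 60
  m <- matrix(rpois(n * 20, 4), n, 20)
  labs <- rep(c("A", "B"), each = n / 2)
  m[labs == "A", 7] <- m[labs == "A", 7] + 30   # planted marker for A
  ds <- make_ds(m, normalize = TRUE)
  res <- refine_markers(ds, labs, top_n = 3)
  expect_equal(res$markers$A[1], "g07")
  expect_s3_class(res$dendrogram, "hclust")

  # top gene equals a brute-force rank-sum scan over all genes
  X <- as.matrix(ds$lognorm)
  z <- vapply(seq_len(20), function(j) {
    r <- rank(X[, j])
    U <- sum(r[labs == "A"]) - (n / 2) * (n / 2 + 1) / 2
    tt <- table(X[, j])
    sig2 <- (n / 2)^2 / 12 * ((n + 1) - sum(tt^3 - tt) / (n * (n - 1)))
    (U - (n / 2)^2 / 2) / sqrt(sig2)
  }, numeric(1))
  expect_equal(res$markers$A[1], gene_ids(ds)[which.max(z)])

  # subsample >= n leaves everything in
  res2 <- refine_markers(ds, labs, subsample = 1e6, top_n = 3)
  expect_identical(res$markers, res2$markers)

  expect_warning(refine_markers(ds, c(rep("A", 2), rep("B", n - 2)), top_n = 2),
                 "skipped")
})
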