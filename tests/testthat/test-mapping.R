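test_that("fit_reference is self-consistent and captures low-rank structure", {
  w <- small_world()
  model <- w$model
  coords2 <- transform_query(model, w$ref$ds)
  expect_equal(unname(as.matrix(coords2)), unname(as.matrix(model$coords)),
               tolerance = 1e-8, ignore_attr = TRUE)

  # rank-2 synthetic data, d = 2: reconstruction error ~ 0
  set.seed(41)
  A <- matrix(rpois(40, 8), 20, 2)
  B <- matrix(sample(0:3, 2 * 15, replace = TRUE), 2, 15)
  m <- A %*% B
  ds <- make_ds(m)
  ds <- normalize_log1p(ds)
  hvg <- suppressWarnings(select_hvg(ds, n = 15))
  mod2 <- fit_reference(ds, hvg, d = 2)
  X <- as.matrix(ds$lognorm[, mod2$gene_ids])
  Xs <- sweep(sweep(X, 2, mod2$center), 2, mod2$scale, "/")
  recon <- mod2$coords %*% t(mod2$rotation)
  # lognorm of a rank-2 count matrix is approximately low-rank; projection on
  # 2 PCs must explain almost all variance
  expect_gt(1 - sum((Xs - recon)^2) / sum(Xs^2), 0.95)

  # disjoint programs separate in latent space
  truth <- w$ref$truth
  co <- as.matrix(model$coords)
  cent <- rowsum(co, truth$level2) / as.vector(table(truth$level2))
  between <- mean(dist(cent))
  within <- mean(sqrt(rowSums((co - cent[truth$level2, ])^2)))
  expect_gt(between, within)

  expect_error(fit_reference(w$ref$ds, gene_ids(w$ref$ds)[1:10], d = 20), "exceeds")
})

test_that("transform_query aligns by gene id and zero-fills missing genes", {
  w <- small_world()
  model <- w$model
  ds <- w$ref$ds
  one <- ds[5, ]
  expect_equal(as.numeric(transform_query(model, one)),
               as.numeric(model$coords[5, ]), tolerance = 1e-8)

  # permuted gene order changes nothing
  set.seed(42)
  perm <- sample(n_genes(ds))
  expect_equal(as.numeric(transform_query(model, ds[5, perm])),
               as.numeric(model$coords[5, ]), tolerance = 1e-10)

  # 10% of genes dropped: equals an explicit zero-fill oracle
  drop <- sample(model$gene_ids, length(model$gene_ids) %/% 10)
  q <- ds[3, setdiff(gene_ids(ds), drop)]
  got <- transform_query(model, q)
  expect_equal(attr(got, "n_zero_filled"), length(drop))
  X <- matrix(0, 1, length(model$gene_ids),
              dimnames = list("x", model$gene_ids))
  keep <- setdiff(model$gene_ids, drop)
  X[, keep] <- as.numeric(ds$lognorm[3, keep])
  want <- (sweep(sweep(X, 2, model$center), 2, model$scale, "/")) %*% model$rotation
  expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-10)

  # insufficient overlap is a hard error
  tiny <- ds[1, model$gene_ids[1:10]]
  expect_error(transform_query(model, tiny), "overlap")
})

test_that("knn_search equals brute force and breaks ties by index", {
  w <- small_world()
  set.seed(43)
  # 20-point reference oracle
  ref20 <- matrix(rnorm(20 * 3), 20, 3)
  model20 <- w$model
  model20$coords <- ref20
  q <- matrix(rnorm(5 * 3), 5, 3)
  got <- knn_search(model20, q, k = 6)
  want <- brute_knn(ref20, q, 6)
  expect_identical(got$index, want$index)
  expect_equal(got$dist, want$dist, tolerance = 1e-12)

  # larger random fixture
  ref <- matrix(rnorm(300 * 5), 300, 5)
  modelr <- w$model
  modelr$coords <- ref
  q2 <- matrix(rnorm(40 * 5), 40, 5)
  got2 <- knn_search(modelr, q2, k = 10)
  want2 <- brute_knn(ref, q2, 10)
  expect_identical(got2$index, want2$index)
  expect_equal(got2$dist, want2$dist, tolerance = 1e-12)

  # duplicated reference points: deterministic index-order tie-break
  dup <- rbind(c(1, 1), c(1, 1), c(5, 5))
  modeld <- w$model
  modeld$coords <- dup
  got3 <- knn_search(modeld, matrix(c(1, 1), 1), k = 2)
  expect_equal(got3$index[1, ], c(1L, 2L))
  expect_equal(got3$dist[1, ], c(0, 0))

  # query at a reference point, k = 1
  got4 <- knn_search(modeld, matrix(c(5, 5), 1), k = 1)
  expect_equal(got4$index[1, 1], 3L)
  expect_equal(got4$dist[1, 1], 0)
  expect_error(knn_search(modeld, matrix(0, 1, 2), k = 0), "positive")
})

test_that("transfer_labels votes, reports confidence, breaks ties as documented", {
  nn <- list(index = matrix(1:3, 1), dist = matrix(c(0.1, 0.2, 0.3), 1))
  expect_equal(transfer_labels(nn, c("A", "A", "B"), k = 3)$label, "A")
  expect_equal(transfer_labels(nn, c("A", "A", "B"), k = 3)$confidence, 2 / 3)
  expect_equal(transfer_labels(nn, c("C", "C", "C"), k = 3)$confidence, 1)
  # tie: B is closer (larger summed inverse distance)
  nn2 <- list(index = matrix(1:4, 1), dist = matrix(c(0.1, 0.2, 3, 4), 1))
  expect_equal(transfer_labels(nn2, c("B", "B", "A", "A"), k = 4)$label, "B")

  set.seed(44)
  labs <- sample(LETTERS[1:4], 50, replace = TRUE)
  idx <- t(replicate(20, sample(50, 10)))
  nn3 <- list(index = idx, dist = matrix(runif(200, 1, 2), 20, 10))
  got <- transfer_labels(nn3, labs, k = 10)
  for (i in 1:20) {
    tab <- table(labs[idx[i, ]])
    expect_equal(got$confidence[i], max(tab) / 10)
    expect_true(got$label[i] %in% names(tab)[tab == max(tab)])
  }
  expect_error(transfer_labels(nn3, c(labs[-1], NA), k = 10), "missing")
})

test_that("label-transfer self-map recovers reference labels with confidence 1", {
  w <- small_world()
  nn <- knn_search(w$model, w$model$coords, k = 1)
  tr <- transfer_labels(nn, w$model$labels, "level2", k = 1)
  expect_equal(tr$label, w$ref$truth$level2)
  expect_true(all(tr$confidence == 1))
})

test_that("on_target_fraction counts matches and group confidences", {
  got <- on_target_fraction(c("gut", "gut", "gut", "lung"), "gut",
                            confidence = c(1, 0.8, 0.9, 0.4))
  expect_equal(got$fraction, 0.75)
  expect_equal(got$mean_confidence_on, 0.9)
  expect_equal(got$mean_confidence_off, 0.4)
  all_on <- on_target_fraction(rep("gut", 3), "gut", confidence = rep(1, 3))
  expect_equal(all_on$fraction, 1)
  expect_null(all_on$mean_confidence_off)
})

test_that("transform_layout is barycentric with exact hits", {
  w <- small_world()
  model <- w$model
  pos <- transform_layout(model, model$coords[7, , drop = FALSE], k = 5)
  expect_equal(as.numeric(pos), as.numeric(model$layout[7, ]), tolerance = 1e-8)
  pos2 <- transform_layout(model, model$coords[7, , drop = FALSE], k = 5)
  expect_identical(pos, pos2)

  # 3-point reference with hand-computable inverse-distance weights
  m3 <- model
  m3$coords <- rbind(c(0, 0), c(2, 0), c(0, 2))
  m3$layout <- rbind(c(0, 0), c(10, 0), c(0, 10))
  q <- matrix(c(1, 0), 1)  # distances: 1, 1, sqrt(5)
  got <- transform_layout(m3, q, k = 3)
  wts <- c(1, 1, 1 / sqrt(5)); wts <- wts / sum(wts)
  expect_equal(as.numeric(got), as.numeric(wts %*% m3$layout), tolerance = 1e-12)
})

test_that("reference model round-trips through its text serialization", {
  w <- small_world()
  dir <- withr::local_tempdir()
  write_reference(w$model, dir)
  back <- read_reference(dir)
  expect_equal(back$gene_ids, w$model$gene_ids)
  expect_equal(unname(back$rotation), unname(w$model$rotation), tolerance = 1e-6)
  co <- transform_query(back, w$ref$ds[1:3, ])
  expect_equal(unname(as.matrix(co)), unname(as.matrix(w$model$coords[1:3, ])),
               tolerance = 1e-4, ignore_attr = TRUE)
})
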