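test_that("paired F statistic matches hand arithmetic and its identity", {
  # dbar = 0: F hits the floor (n-1)/n exactly
  q <- cbind(g1 = c(-1, 1, -1, 1))
  m <- cbind(g1 = rep(0, 4))
  res <- paired_f_test(q, m, min_cells_detected = 0)
  expect_equal(res$F, 0.75)
  expect_equal(res$p, 1)

  # d = (2,2,2,2,0): msd 3.2, var 0.8, F 4
  res2 <- paired_f_test(cbind(g1 = c(2, 2, 2, 2, 0)),
                        cbind(g1 = rep(0, 5)), min_cells_detected = 0)
  expect_equal(res2$mean_diff, 1.6)
  expect_equal(res2$msd, 3.2)
  expect_equal(res2$var_diff, 0.8)
  expect_equal(res2$F, 4.0)
  # p from the exact null law: n*F - (n-1) = 16 ~ F(1, 4)
  expect_equal(res2$p, pf(16, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # constant non-zero shift: zero variance, maximal significance
  res3 <- paired_f_test(cbind(g1 = rep(2, 5)), cbind(g1 = rep(0, 5)),
                        min_cells_detected = 0)
  expect_equal(res3$F, Inf)
  expect_equal(res3$p, .Machine$double.xmin)
  # constant zero difference: p = 1
  res4 <- paired_f_test(cbind(g1 = rep(2, 5)), cbind(g1 = rep(2, 5)),
                        min_cells_detected = 0)
  expect_equal(res4$p, 1)

  expect_error(paired_f_test(q[1:2, , drop = FALSE], m[1:2, , drop = FALSE]),
               "at least 3")
  expect_error(paired_f_test(q, m[1:3, , drop = FALSE]), "shapes")

  # identity on random fixtures: F = (n-1)/n + dbar^2/var
  set.seed(71)
  n <- 40
  Q <- matrix(rnorm(n * 50, 1), n, 50, dimnames = list(NULL, paste0("g", 1:50)))
  M <- matrix(rnorm(n * 50), n, 50, dimnames = list(NULL, paste0("g", 1:50)))
  res5 <- paired_f_test(Q, M, min_cells_detected = 0)
  D <- Q - M
  want <- (n - 1) / n + colMeans(D)^2 / apply(D, 2, var)
  expect_equal(res5$F, unname(want), tolerance = 1e-12)
  # BH monotone in p
  ord <- order(res5$p)
  expect_true(all(diff(res5$p_adj[ord]) >= -1e-15))
})

test_that("detection filter masks rarely observed genes", {
  Q <- cbind(g1 = c(1, 1, 1, 0), g2 = c(1, 0, 0, 0))
  M <- Q * 0
  res <- paired_f_test(Q, M, min_cells_detected = 3)
  expect_false(is.na(res$p[1]))
  expect_true(is.na(res$p[2]))
  expect_equal(res$direction[2], "none")
})

test_that("paired F test is calibrated and powerful", {
  set.seed(72)
  n <- 100; G <- 2000
  D <- matrix(rnorm(n * G, 0, 1), n, G, dimnames = list(NULL, paste0("g", 1:G)))
  base <- matrix(1, n, G, dimnames = dimnames(D))
  res <- paired_f_test(base + D, base, min_cells_detected = 0)
  rej <- mean(res$p < 0.05)
  expect_gte(rej, 0.02)
  expect_lte(rej, 0.09)

  shifted <- c(rep(TRUE, 50), rep(FALSE, G - 50))
  D2 <- D + outer(rep(1, n), ifelse(shifted, 1, 0))
  res2 <- paired_f_test(base + D2, base, min_cells_detected = 0)
  called <- res2$p_adj < 0.05
  expect_gte(mean(called[shifted]), 0.9)           # sensitivity
  expect_lte(sum(called & !shifted) / max(1, sum(called)), 0.1)  # FDR
})

test_that("wilcoxon_de agrees with stats::wilcox.test", {
  ds <- random_ds(40, 10, seed = 73, normalize = TRUE)
  mask <- rep(c(TRUE, FALSE), 20)
  res <- wilcoxon_de(ds, mask)
  X <- as.matrix(ds$lognorm)
  for (j in 1:10) {
    want <- wilcox.test(X[mask, j], X[!mask, j], exact = FALSE,
                        correct = FALSE)$p.value
    expect_equal(res$p[j], want, tolerance = 1e-10)
  }

  # identical groups: all p = 1 (duplicate each cell across groups)
  X2 <- rbind(X, X)
  ds2 <- make_ds(matrix(1, 80, 10))
  ds2$lognorm <- atlasq:::.as_dgc(matrix(X2, 80, 10,
                                         dimnames = dimnames(ds2$counts)))
  res2 <- wilcoxon_de(ds2, rep(c(TRUE, FALSE), each = 40))
  expect_true(all(res2$p > 0.9))

  # complete separation
  sep <- make_ds(rbind(matrix(5, 20, 1), matrix(0, 20, 1)), normalize = FALSE)
  sep$lognorm <- atlasq:::.as_dgc(sep$counts)
  expect_lt(wilcoxon_de(sep, rep(c(TRUE, FALSE), each = 20))$p[1], 1e-6)
  expect_error(wilcoxon_de(ds, rep(c(TRUE, FALSE), c(2, 38))), "at least 3")
})

test_that("categorize_degs separates the four planted blocks", {
  # trivial rules
  deA <- data.frame(gene = c("a", "b"), mean_diff = c(1, 1),
                    p_adj = c(0.01, 0.5))
  deB <- data.frame(gene = c("a", "b"), mean_diff = c(1, 1),
                    p_adj = c(0.5, 0.01))
  cats <- categorize_degs(deA, deB)
  expect_equal(cats$specific_to_A, "a")
  expect_equal(cats$specific_to_B, "b")

  # planted 4-block design: 50 A-only, 50 B-only, 50 shared, 50 atlas-up,
  # 1.5 natural-log fold, n = 300 cells
  set.seed(74)
  n <- 300; G <- 400
  genes <- paste0("g", sprintf("%03d", 1:G))
  blockA <- 1:50; blockB <- 51:100; blockS <- 101:150; blockU <- 151:200
  base <- matrix(rnorm(n * G, 2, 0.8), n, G, dimnames = list(NULL, genes))
  effA <- effB <- rep(0, G)
  effA[c(blockA, blockS)] <- 1.5
  effB[c(blockB, blockS)] <- 1.5
  effA[blockU] <- -1.5
  effB[blockU] <- -1.5
  QA <- base + outer(rep(1, n), effA) + matrix(rnorm(n * G, 0, 0.8), n, G)
  QB <- base + outer(rep(1, n), effB) + matrix(rnorm(n * G, 0, 0.8), n, G)
  resA <- paired_f_test(QA, base, min_cells_detected = 0)
  resB <- paired_f_test(QB, base, min_cells_detected = 0)
  cats2 <- categorize_degs(resA, resB)
  expect_gte(mean(genes[blockA] %in% cats2$specific_to_A), 0.9)
  expect_gte(mean(genes[blockB] %in% cats2$specific_to_B), 0.9)
  expect_gte(mean(genes[blockS] %in% cats2$shared_up), 0.9)
  expect_gte(mean(genes[blockU] %in% cats2$atlas_up), 0.9)
  # disjointness
  all_sets <- unlist(cats2)
  expect_equal(anyDuplicated(all_sets), 0)
  expect_error(categorize_degs(deA, deB[1, ]), "universes")
})

test_that("fisher_enrichment matches the hypergeometric closed form", {
  universe <- paste0("g", 1:20)
  degs <- universe[1:10]
  sets <- list(hit = universe[1:10], miss = universe[11:20])
  res <- fisher_enrichment(degs, sets, universe)
  # closed form: P(overlap >= 10) + P(overlap <= 0) under hypergeometric
  p_want <- dhyper(10, 10, 10, 10) + dhyper(0, 10, 10, 10)
  expect_equal(res$p[res$set == "hit"], p_want, tolerance = 1e-12)
  expect_gt(res$odds_ratio[res$set == "hit"], 100)  # Haldane-corrected, finite
  expect_true(is.finite(res$odds_ratio[res$set == "hit"]))

  expect_warning(fisher_enrichment(degs, list(x = c("zz"), ok = universe[1:5]),
                                   universe),
                 "disjoint")

  # null: DEG set independent of gene sets -> p super-uniform (Fisher p is
  # discrete, so a KS test against the uniform rejects by construction; the
  # operational property is that rejection never exceeds the nominal level)
  set.seed(75)
  uni <- paste0("u", 1:500)
  ps <- replicate(400, {
    dg <- sample(uni, 50)
    gs <- list(s = sample(uni, 40))
    fisher_enrichment(dg, gs, uni)$p
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    expect_lte(mean(ps < alpha), alpha + 2.5 * sqrt(alpha * (1 - alpha) / 400))
  }
  expect_gte(mean(ps), 0.45)
})

test_that("signature_group_compare reduces to per-gene tests and has power", {
  set.seed(76)
  tab <- matrix(rnorm(20 * 30, 5), 20, 30,
                dimnames = list(paste0("s", 1:20), paste0("g", 1:30)))
  groups <- rep(c("ctrl", "treat"), each = 10)

  # identical groups: p not small
  same <- tab; same[11:20, ] <- same[1:10, ]
  res0 <- signature_group_compare(same, paste0("g", 1:5), groups)
  expect_gt(res0$pairwise$p, 0.9)

  # planted +1 shift in all set genes
  shifted <- tab
  shifted[11:20, 1:10] <- shifted[11:20, 1:10] + 1
  res1 <- signature_group_compare(shifted, paste0("g", 1:10), groups)
  expect_lt(res1$pairwise$p, 0.01)

  # singleton set equals the direct per-gene comparison
  res2 <- signature_group_compare(tab, "g7", groups)
  want <- wilcox.test(tab[1:10, "g7"], tab[11:20, "g7"], exact = FALSE)$p.value
  expect_equal(res2$pairwise$p, want, tolerance = 1e-12)

  expect_error(signature_group_compare(tab, "nope", groups), "no genes")
})

test_that("read_gmt parses sets with descriptions", {
  f <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\turl\tg9"), f)
  sets <- read_gmt(f)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g9")
})
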