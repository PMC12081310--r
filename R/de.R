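#' Paired F test against the matched atlas reference
#'
#' For each gene, with per-cell paired differences
#' `d_i = query_i - matched_i` (log-normalized scale, n cell pairs):
#' `msd = sum(d_i^2) / n` (mean squared difference) is compared with the
#' sample variance `var_diff = sum((d_i - dbar)^2) / (n - 1)` through
#' `F = msd / var_diff`, upper-tail p.
#'
#' Algebraically `F = (n-1)/n + dbar^2 / var_diff`, so the statistic is a
#' location-shift test: it exceeds its no-shift floor `(n-1)/n` exactly when
#' the mean paired difference is non-zero. Because numerator and denominator
#' share the variance component, F is not distributed as a textbook
#' F(n, n-1) under the null; its exact null law follows from the identity:
#' `n * F - (n - 1)` is F(1, n-1) distributed (the squared paired t
#' statistic). The p value is computed from that exact law, which makes the
#' test calibrated — treating the ratio as an independent-sample F(n, n-1)
#' would be conservative by many orders of magnitude.
#'
#' Edge handling: `var_diff = 0, msd = 0` gives p = 1; `var_diff = 0,
#' msd > 0` (a constant non-zero shift) gives `F = Inf` and the smallest
#' representable positive p.
#'
#' @param query_lognorm cells x genes matrix of query expression
#' @param matched_lognorm cells x genes matrix of matched reference
#'   profiles, aligned cell-for-cell and gene-for-gene (e.g.
#'   `matched_reference()$profile`)
#' @param alpha significance level used to call direction (BH-adjusted)
#' @param min_cells_detected genes detected (count > 0 in the query) in
#'   fewer cells are not tested (NA statistics). Set 0 to test everything.
#' @return a `DEResult` data.frame: gene, n_pairs, mean_diff, msd, var_diff,
#'   F, p, p_adj, direction.
#' @export
paired_f_test <- function(query_lognorm, matched_lognorm, alpha = 0.05,
                          min_cells_detected = 3) {
  Q <- .dense(query_lognorm)
  M <- .dense(matched_lognorm)
  .stop_if(!identical(dim(Q), dim(M)), "query and matched shapes differ")
  n <- nrow(Q)
  .stop_if(n < 3, "need at least 3 cell pairs")
  D <- Q - M
  dbar <- colMeans(D)
  ss <- colSums(D * D)
  msd <- ss / n
  var_diff <- (ss - n * dbar^2) / (n - 1)
  var_diff <- pmax(var_diff, 0)          # guard tiny negative rounding
  Fstat <- ifelse(var_diff > 0, msd / var_diff, NA_real_)
  # exact null law of F via the identity: n*F - (n-1) ~ F(1, n-1)
  t2 <- pmax(n * Fstat - (n - 1), 0)
  p <- ifelse(var_diff > 0,
              stats::pf(t2, 1, n - 1, lower.tail = FALSE),
              NA_real_)
  zero_var <- var_diff == 0
  p[zero_var & msd == 0] <- 1
  Fstat[zero_var & msd > 0] <- Inf
  p[zero_var & msd > 0] <- .Machine$double.xmin
  tested <- rep(TRUE, ncol(Q))
  if (min_cells_detected > 0) {
    tested <- colSums(Q > 0) >= min_cells_detected
    Fstat[!tested] <- NA_real_
    p[!tested] <- NA_real_
  }
  p_adj <- rep(NA_real_, length(p))
  p_adj[tested] <- stats::p.adjust(p[tested], method = "BH")
  direction <- rep("none", length(p))
  sig <- tested & !is.na(p_adj) & p_adj < alpha
  direction[sig & dbar > 0] <- "query_up"
  direction[sig & dbar < 0] <- "atlas_up"
  out <- data.frame(gene = colnames(Q), n_pairs = n, mean_diff = dbar,
                    msd = msd, var_diff = var_diff, F = Fstat, p = p,
                    p_adj = p_adj, direction = direction,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("DEResult", "data.frame")
  out
}

#' Wilcoxon rank-sum differential expression between two cell groups
#'
#' Tie-corrected two-sided rank-sum test per gene with normal approximation
#' and Benjamini-Hochberg correction across genes.
#'
#' @param ds a normalized [ExpressionDataset()]
#' @param group_mask logical per cell; TRUE = group of interest
#' @return data.frame: gene, auc, z, p, p_adj.
#' @export
wilcoxon_de <- function(ds, group_mask) {
  .stop_if(is.null(ds$lognorm), "dataset must be normalized")
  .stop_if(sum(group_mask) < 3 || sum(!group_mask) < 3,
           "both groups need at least 3 cells")
  st <- .rank_sum_stats(.dense(ds$lognorm), group_mask)
  data.frame(gene = gene_ids(ds), auc = st$auc, z = st$z, p = st$p,
             p_adj = stats::p.adjust(st$p, method = "BH"),
             stringsAsFactors = FALSE)
}

#' Categorize differential genes across two conditions
#'
#' Given two paired-F DE results against the same atlas cohort (e.g. two
#' cytokine treatments), genes are placed into four disjoint sets:
#' significantly up in condition A only (`specific_to_A`), in B only
#' (`specific_to_B`), up in both (`shared_up`), and significantly higher in
#' the atlas in both (`atlas_up`).
#'
#' @param deA,deB [paired_f_test()] results over the same gene universe
#' @param alpha BH-adjusted significance threshold
#' @return a `DEGCategories` list of four character vectors.
#' @export
categorize_degs <- function(deA, deB, alpha = 0.05) {
  .stop_if(!identical(deA$gene, deB$gene), "gene universes differ")
  sigA_up <- !is.na(deA$p_adj) & deA$p_adj < alpha & deA$mean_diff > 0
  sigB_up <- !is.na(deB$p_adj) & deB$p_adj < alpha & deB$mean_diff > 0
  sigA_dn <- !is.na(deA$p_adj) & deA$p_adj < alpha & deA$mean_diff < 0
  sigB_dn <- !is.na(deB$p_adj) & deB$p_adj < alpha & deB$mean_diff < 0
  structure(list(
    specific_to_A = deA$gene[sigA_up & !sigB_up],
    specific_to_B = deA$gene[sigB_up & !sigA_up],
    shared_up = deA$gene[sigA_up & sigB_up],
    atlas_up = deA$gene[sigA_dn & sigB_dn]),
    class = "DEGCategories")
}

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

#' Fisher exact gene-set enrichment of a DEG list
#'
#' For each gene set, a 2x2 table (in DEG x in set, over the universe) is
#' tested with the two-sided Fisher exact test. The reported odds ratio is
#' the sample odds ratio with a Haldane 0.5 correction whenever a table cell
#' is zero. Sets disjoint from the universe are skipped with a warning.
#'
#' @param deg_set character vector of significant genes
#' @param gene_sets named list (e.g. [read_gmt()])
#' @param universe all tested genes; must contain `deg_set`
#' @return data.frame: set, n_set, n_overlap, odds_ratio, p, q (BH).
#' @export
fisher_enrichment <- function(deg_set, gene_sets, universe) {
  .stop_if(length(universe) == 0, "empty universe")
  universe <- unique(universe)
  .stop_if(!all(deg_set %in% universe), "deg_set must be within the universe")
  in_deg <- universe %in% deg_set
  rows <- list()
  for (nm in names(gene_sets)) {
    gs <- intersect(gene_sets[[nm]], universe)
    if (length(gs) == 0) {
      warning(sprintf("gene set %s disjoint from universe; skipped", nm))
      next
    }
    in_set <- universe %in% gs
    a <- sum(in_deg & in_set); b <- sum(in_deg & !in_set)
    c0 <- sum(!in_deg & in_set); d <- sum(!in_deg & !in_set)
    p <- stats::fisher.test(matrix(c(a, b, c0, d), 2, byrow = TRUE))$p.value
    or <- if (any(c(a, b, c0, d) == 0)) {
      (a + 0.5) * (d + 0.5) / ((b + 0.5) * (c0 + 0.5))
    } else a * d / (b * c0)
    rows[[nm]] <- data.frame(set = nm, n_set = length(gs), n_overlap = a,
                             odds_ratio = or, p = p, stringsAsFactors = FALSE)
  }
  .stop_if(length(rows) == 0, "no scorable gene sets")
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Compare a gene-set score between sample groups on pseudo-bulk
#'
#' Computes the mean expression of a gene set per individual (pseudo-bulk
#' row) and compares groups pairwise with two-sided Mann-Whitney tests.
#'
#' @param pseudobulk_table sample x gene numeric matrix (e.g. the `log`
#'   layer of [pseudobulk()])
#' @param gene_set character vector of genes
#' @param group_labels group per sample (row)
#' @return list with `scores` (per sample), `group_means`, and `pairwise`
#'   data.frame of Mann-Whitney p values.
#' @export
signature_group_compare <- function(pseudobulk_table, gene_set, group_labels) {
  M <- .dense(pseudobulk_table)
  genes <- intersect(gene_set, colnames(M))
  .stop_if(length(genes) == 0, "gene set shares no genes with the table")
  groups <- as.character(group_labels)
  tab <- table(groups)
  .stop_if(length(tab) < 2 || any(tab < 3),
           "need >= 2 groups with >= 3 individuals each")
  scores <- rowMeans(M[, genes, drop = FALSE])
  gm <- tapply(scores, groups, mean)
  combos <- utils::combn(sort(unique(groups)), 2)
  pw <- apply(combos, 2, function(pr) {
    stats::wilcox.test(scores[groups == pr[1]], scores[groups == pr[2]],
                       exact = FALSE)$p.value
  })
  list(scores = scores,
       group_means = gm,
       pairwise = data.frame(group_a = combos[1, ], group_b = combos[2, ],
                             p = pw, stringsAsFactors = FALSE))
}
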