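sep_lines_sim <- function(seed = 4) {
  simulate_counts(sim_config(n_genes = 500, seed = seed,
    groups = tibble::tibble(line = c("A", "B"), treatment = "none",
                            n_cells = 30),
    line_effects = list(B = list(genes = sprintf("G%04d", 50:120),
                                 mean_fold = 6))))
}

test_that("strongly separated lines are recovered exactly at K = 2", {
  sim <- sep_lines_sim()
  expr <- compute_rpkm_from(sim)
  cl <- cluster_cells(expr, sprintf("G%04d", 50:120), k = 2)
  labels <- stats::setNames(sim$metadata$line, sim$metadata$cell)
  pur <- cluster_purity(cl, labels, n_perm = 200, seed = 1)
  expect_equal(pur$purity, 1)
  expect_false(pur$degenerate)
})

test_that("shuffled labels give chance-level purity", {
  sim <- sep_lines_sim()
  expr <- compute_rpkm_from(sim)
  cl <- cluster_cells(expr, sprintf("G%04d", 50:120), k = 2)
  labels <- withr::with_seed(9,
    stats::setNames(sample(sim$metadata$line), sim$metadata$cell))
  pur <- cluster_purity(cl, labels, n_perm = 500, seed = 2)
  expect_lt(pur$purity, pur$baseline_mean + 3 * pur$baseline_sd)
})

test_that("duplicated cells co-cluster at the lowest merge", {
  sim <- simulate_counts(sim_config(n_genes = 200, seed = 7,
    groups = tibble::tibble(line = "L", treatment = "none", n_cells = 10)))
  cm <- sim$matrix
  dup <- count_matrix(cbind(cm$counts,
                            DUP = cm$counts[, 1]),
                      is_spikein = genes(cm)[cm$is_spikein])
  expr <- compute_rpkm(dup, sim$gene_lengths)
  cl <- cluster_cells(expr, genes(cm)[!cm$is_spikein], k = 2)
  tree <- attr(cl, "tree")
  # the first merge joins the duplicate pair (distance 0)
  expect_equal(tree$height[1], 0)
  first <- -tree$merge[1, ]
  expect_setequal(tree$labels[first], c(cells(cm)[1], "DUP"))
})

test_that("a gene subset disjoint from the matrix is an error; K bounds hold", {
  sim <- simulate_counts(sim_config(n_genes = 100, seed = 3,
    groups = tibble::tibble(line = "L", treatment = "none", n_cells = 8)))
  expr <- compute_rpkm_from(sim)
  expect_error(cluster_cells(expr, c("NOPE1", "NOPE2"), k = 2), "disjoint")
  expect_error(cluster_cells(expr, genes(sim$matrix)[1:10], k = 1), "at least 2")
  expect_error(cluster_cells(expr, genes(sim$matrix)[1:10], k = 50),
               "exceeds the number of cells")
})

test_that("purity handles the hand-computable cases", {
  asg <- tibble::tibble(cell = sprintf("C%02d", 1:8),
                        cluster = factor(rep(c(1, 2), each = 4)))
  labels <- stats::setNames(rep(c("x", "y"), each = 4), asg$cell)
  expect_equal(cluster_purity(asg, labels, n_perm = 50)$purity, 1)
  # one cluster, two equally frequent labels -> purity 1/2
  asg1 <- tibble::tibble(cell = asg$cell, cluster = factor(rep(1, 8)))
  expect_equal(cluster_purity(asg1, labels, n_perm = 50)$purity, 0.5)
})

test_that("rank-one structure loads on the first principal component", {
  cells_n <- 20
  base <- seq(-2, 2, length.out = cells_n)
  m <- outer(c(1, 2, 3, 0.5), base)  # rank-1 in log space after centering
  rpkm <- 10^(m + 2)
  dimnames(rpkm) <- list(paste0("G", 1:4), paste0("C", 1:cells_n))
  expr <- structure(list(rpkm = rpkm,
                         library_sizes = stats::setNames(rep(1e6, cells_n),
                                                         colnames(rpkm)),
                         is_spikein = stats::setNames(rep(FALSE, 4),
                                                      rownames(rpkm))),
                    class = "expression_matrix")
  emb <- pca_cells(expr, rownames(rpkm), k = 2)
  expect_gt(attr(emb, "explained")[1], 0.99)
  expect_true(all(diff(attr(emb, "explained")) <= 1e-12))
})

test_that("the embedding is invariant to cell order up to the fixed sign rule", {
  sim <- sep_lines_sim(seed = 6)
  expr <- compute_rpkm_from(sim)
  subset <- sprintf("G%04d", 50:120)
  e1 <- pca_cells(expr, subset, k = 2)
  perm <- rev(seq_len(ncol(expr$rpkm)))
  expr2 <- structure(list(rpkm = expr$rpkm[, perm],
                          library_sizes = expr$library_sizes[perm],
                          is_spikein = expr$is_spikein),
                     class = "expression_matrix")
  e2 <- pca_cells(expr2, subset, k = 2)
  j <- dplyr::inner_join(tibble::as_tibble(e1), tibble::as_tibble(e2),
                         by = "cell")
  expect_equal(j$PC1.x, j$PC1.y, tolerance = 1e-8)
  expect_equal(j$PC2.x, j$PC2.y, tolerance = 1e-8)
})

test_that("excluded genes have no influence on clustering or PCA", {
  sim <- sep_lines_sim(seed = 8)
  expr <- compute_rpkm_from(sim)
  subset <- sprintf("G%04d", 50:120)
  cl1 <- cluster_cells(expr, subset, k = 2)
  # perturb genes outside the subset
  rpkm2 <- expr$rpkm
  outside <- setdiff(rownames(rpkm2), subset)
  rpkm2[outside, ] <- rpkm2[outside, ] * 100
  expr2 <- structure(list(rpkm = rpkm2, library_sizes = expr$library_sizes,
                          is_spikein = expr$is_spikein),
                     class = "expression_matrix")
  cl2 <- cluster_cells(expr2, subset, k = 2)
  expect_identical(cl1$cluster, cl2$cluster)
  expect_equal(tibble::as_tibble(pca_cells(expr, subset, k = 2)),
               tibble::as_tibble(pca_cells(expr2, subset, k = 2)))
})

test_that("two separated lines split positively in silhouette on PC1-PC2", {
  sim <- sep_lines_sim(seed = 10)
  expr <- compute_rpkm_from(sim)
  emb <- pca_cells(expr, sprintf("G%04d", 50:120), k = 2)
  lab <- stats::setNames(sim$metadata$line, sim$metadata$cell)[emb$cell]
  x <- as.matrix(tibble::as_tibble(emb)[, c("PC1", "PC2")])
  d <- as.matrix(stats::dist(x))
  sil <- vapply(seq_along(lab), function(i) {
    same <- which(lab == lab[i] & seq_along(lab) != i)
    a <- mean(d[i, same])
    b <- mean(d[i, lab != lab[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})

test_that("dendrograms export as readable Newick", {
  sim <- sep_lines_sim(seed = 12)
  expr <- compute_rpkm_from(sim)
  cl <- cluster_cells(expr, sprintf("G%04d", 50:120), k = 2)
  path <- withr::local_tempfile(fileext = ".nwk")
  write_dendrogram(cl, path)
  tree <- ape::read.tree(path)
  expect_setequal(tree$tip.label, cl$cell)
})
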