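#' Hierarchical clustering of cells on a gene subset
#'
#' Agglomerative clustering of cells on `log10(rpkm + eps)`-transformed,
#' per-gene standardized values of the chosen gene subset; Euclidean
#' distance, complete linkage by default. Deterministic given data and
#' settings. The fitted dendrogram is attached and can be exported as
#' Newick.
#'
#' @param expr An `expression_matrix`.
#' @param gene_subset Character vector of gene ids (intersected with the
#'   matrix; empty intersection is an error).
#' @param k Number of clusters to cut (>= 2).
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param eps rpkm offset inside the log transform.
#' @return A tibble of class `cluster_assignment`: `cell`, `cluster`
#'   (factor with `k` levels), carrying the `hclust` tree as attribute
#'   `tree` and the settings as attributes.
#' @export
cluster_cells <- function(expr, gene_subset, k, linkage = "complete",
                          eps = 0.01) {
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  m <- embedding_input(expr, gene_subset, eps, standardize = TRUE)
  if (k > ncol(m)) stop("k exceeds the number of cells", call. = FALSE)
  tree <- stats::hclust(stats::dist(t(m)), method = linkage)
  cl <- stats::cutree(tree, k = k)
  out <- tibble::tibble(cell = colnames(m), cluster = factor(cl[colnames(m)]))
  structure(out, class = c("cluster_assignment", class(out)),
            tree = tree, linkage = linkage, k = k,
            gene_subset = rownames(m))
}

embedding_input <- function(expr, gene_subset, eps, standardize) {
  stopifnot(inherits(expr, "expression_matrix"))
  keep <- intersect(gene_subset, rownames(expr$rpkm))
  if (length(keep) == 0L) {
    stop("gene subset disjoint from matrix genes", call. = FALSE)
  }
  m <- log10(expr$rpkm[keep, , drop = FALSE] + eps)
  ctr <- m - rowMeans(m)
  if (standardize) {
    s <- apply(m, 1, stats::sd)
    ctr <- ctr[s > 0, , drop = FALSE] / s[s > 0]
  }
  ctr
}

#' Export a cluster dendrogram as Newick
#'
#' @param assignment A [cluster_cells()] result.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
write_dendrogram <- function(assignment, path) {
  tree <- attr(assignment, "tree")
  if (is.null(tree)) stop("assignment carries no dendrogram", call. = FALSE)
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Purity of a clustering against known cell labels
#'
#' `purity = (1/n) * sum over clusters of the majority label count`: the
#' fraction of cells sitting in a cluster whose majority label matches.
#' Reported with a permutation baseline (labels shuffled) giving the chance
#' level for this cluster-size/label-frequency configuration.
#'
#' @param assignment A [cluster_cells()] result (or tibble `cell`,
#'   `cluster`).
#' @param labels Named character vector or tibble `cell` + label column
#'   giving each cell's true label (e.g. cell line).
#' @param n_perm Number of label permutations for the baseline.
#' @param seed Integer seed for the permutations.
#' @return Tibble with one row: `purity`, `baseline_mean`, `baseline_sd`,
#'   `n_cells`, `degenerate` (single cluster and single label).
#' @export
cluster_purity <- function(assignment, labels, n_perm = 1000, seed = 1L) {
  if (is.data.frame(labels)) {
    lab_col <- setdiff(names(labels), "cell")[1L]
    labels <- stats::setNames(labels[[lab_col]], labels$cell)
  }
  lab <- labels[assignment$cell]
  if (anyNA(lab)) stop("labels missing for some cells", call. = FALSE)
  cl <- assignment$cluster
  purity_of <- function(l) {
    sum(tapply(l, cl, function(v) max(table(v)))) / length(l)
  }
  p <- purity_of(lab)
  base <- withr::with_seed(seed,
    vapply(seq_len(n_perm), function(i) purity_of(sample(lab)), numeric(1)))
  tibble::tibble(purity = p, baseline_mean = mean(base),
                 baseline_sd = stats::sd(base), n_cells = length(lab),
                 degenerate = nlevels(droplevels(cl)) == 1L &&
                   length(unique(lab)) == 1L)
}

#' Principal component analysis of cells on a gene subset
#'
#' PCA of cells on the log10(rpkm + eps)-transformed, per-gene centered
#' subset matrix. For determinism the sign of each component is fixed so
#' that its largest-magnitude gene loading is positive.
#'
#' @param expr An `expression_matrix`.
#' @param gene_subset Character vector of gene ids.
#' @param k Number of components (>= 1, at most min(cells, genes)).
#' @param eps rpkm offset inside the log transform.
#' @return A tibble of class `cell_embedding`: `cell` plus `PC1..PCk`
#'   coordinate columns, with attributes `explained` (variance fractions,
#'   non-increasing) and `gene_subset`.
#' @export
pca_cells <- function(expr, gene_subset, k, eps = 0.01) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  m <- embedding_input(expr, gene_subset, eps, standardize = FALSE)
  k_max <- min(ncol(m), nrow(m))
  if (k > k_max) stop("k exceeds min(n_cells, subset size)", call. = FALSE)
  pc <- stats::prcomp(t(m), center = FALSE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {  # fixed sign convention
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  out <- tibble::as_tibble(scores, rownames = "cell")
  structure(out, class = c("cell_embedding", class(out)),
            explained = expl[seq_len(k)], gene_subset = rownames(m),
            loadings = rot)
}

#' Variance explained by a cell embedding
#' @param x A `cell_embedding`.
#' @param ... Unused.
#' @return Tibble: component, explained-variance fraction.
#' @export
glance.cell_embedding <- function(x, ...) {
  tibble::tibble(component = paste0("PC", seq_along(attr(x, "explained"))),
                 explained = attr(x, "explained"))
}
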