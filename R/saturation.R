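#' Binomial thinning of a count matrix to a target depth
#'
#' Each cell's counts are thinned gene-by-gene with a binomial keep
#' probability `p_c = target_depth / depth_c`, so expected counts are scaled
#' by `p_c` and relative expression is preserved in expectation. Cells whose
#' depth is already at or below the target are kept unthinned and recorded
#' in the `unthinned_cells` attribute.
#'
#' @param counts A [count_matrix()].
#' @param target_depth Target tags per cell (> 0); depth is the per-cell
#'   total over all rows, spike-ins included.
#' @param seed Optional integer seed for reproducible thinning.
#' @return A [count_matrix()] of the same shape.
#' @export
thin_counts <- function(counts, target_depth, seed = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  if (!is.finite(target_depth) || target_depth <= 0) {
    stop("target_depth must be positive", call. = FALSE)
  }
  run <- function() {
    depth <- colSums(counts$counts)
    p <- pmin(1, target_depth / depth)
    m <- counts$counts
    for (j in which(p < 1)) {
      m[, j] <- stats::rbinom(nrow(m), m[, j], p[j])
    }
    out <- count_matrix(m, is_spikein = genes(counts)[counts$is_spikein])
    attr(out, "unthinned_cells") <- cells(counts)[p >= 1]
    out
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

default_strata <- c(1, 5, 10, 50, 100, 500)

stratify_genes <- function(table, breaks = default_strata) {
  labels <- paste0(utils::head(breaks, -1), "-", breaks[-1], " rpkm")
  tibble::tibble(gene = table$gene,
                 stratum = cut(table$mean, breaks = breaks, labels = labels,
                               include.lowest = FALSE, right = TRUE))
}

#' Relative divergence as a function of sequencing depth
#'
#' Thins the matrix to each depth on a grid, recomputes rpkm and the
#' divergence table, and averages the relative divergence within expression
#' strata. Strata are assigned once from the full-depth table and frozen
#' across the grid, so stratum migration cannot confound the curve.
#'
#' @param counts A [count_matrix()].
#' @param lengths Gene-length tibble for [compute_rpkm()].
#' @param depth_grid Strictly increasing vector of target depths (tags per
#'   cell).
#' @param strata Stratum boundaries in rpkm (defaults to 1, 5, 10, 50, 100,
#'   500). Empty strata are omitted with a warning.
#' @param replicates Thinning replicates per depth.
#' @param seed Integer seed.
#' @return A tibble of class `saturation_curve` with attribute
#'   `axis = "depth"`: `depth`, `stratum`, `mean_cv` (replicate mean of the
#'   stratum-average cv), `sd_cv` (across replicates), `n_genes`.
#' @export
depth_curve <- function(counts, lengths, depth_grid, strata = default_strata,
                        replicates = 3, seed = 1L) {
  if (is.unsorted(depth_grid, strictly = TRUE)) {
    stop("depth_grid must be strictly increasing", call. = FALSE)
  }
  full <- divergence_table(compute_rpkm(counts, lengths))
  strat <- stratify_genes(full, strata)
  present <- table(strat$stratum)
  if (any(present == 0)) {
    warning("empty expression stratum omitted: ",
            paste(names(present)[present == 0], collapse = ", "))
  }
  grid <- tidyr::expand_grid(depth = depth_grid, rep = seq_len(replicates))
  rows <- purrr::pmap_dfr(grid, function(depth, rep) {
    thinned <- thin_counts(counts, depth, seed = seed + 7919L * rep + round(depth %% 7907))
    tab <- divergence_table(compute_rpkm(thinned, lengths))
    dplyr::inner_join(tab, strat, by = "gene") |>
      dplyr::filter(!is.na(.data$stratum), is.finite(.data$cv)) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(cv = mean(.data$cv), n_genes = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(depth = depth, rep = rep)
  })
  out <- rows |>
    dplyr::group_by(.data$depth, .data$stratum) |>
    dplyr::summarise(mean_cv = mean(.data$cv),
                     sd_cv = stats::sd(.data$cv),
                     n_genes = .data$n_genes[1L], .groups = "drop")
  structure(out, class = c("saturation_curve", class(out)), axis = "depth")
}

#' Relative divergence as a function of the number of cells
#'
#' For each cell count on the grid, samples that many cells without
#' replacement, recomputes the divergence table, and reports the mean and
#' across-replicate standard deviation of the stratum-average relative
#' divergence. The stability of the estimate with growing n indicates the
#' minimum number of cells needed to measure divergence reliably.
#'
#' @param counts A [count_matrix()].
#' @param lengths Gene-length tibble.
#' @param n_grid Strictly increasing cell counts, each >= 2 and at most the
#'   number of available cells.
#' @param strata Stratum boundaries in rpkm (assigned at full cell count).
#' @param replicates Subsampling replicates per n (default 20).
#' @param seed Integer seed.
#' @return A tibble of class `saturation_curve` with attribute
#'   `axis = "cells"`: `n_cells`, `stratum`, `mean_cv`, `sd_cv`, `n_genes`.
#' @export
cell_count_curve <- function(counts, lengths, n_grid, strata = default_strata,
                             replicates = 20, seed = 1L) {
  if (any(n_grid < 2)) stop("need at least 2 cells per subsample", call. = FALSE)
  if (max(n_grid) > ncol(counts$counts)) {
    stop("n_grid exceeds available cells", call. = FALSE)
  }
  if (is.unsorted(n_grid, strictly = TRUE)) {
    stop("n_grid must be strictly increasing", call. = FALSE)
  }
  full <- divergence_table(compute_rpkm(counts, lengths))
  strat <- stratify_genes(full, strata)
  grid <- tidyr::expand_grid(n = n_grid, rep = seq_len(replicates))
  rows <- withr::with_seed(seed, purrr::pmap_dfr(grid, function(n, rep) {
    sub <- subset_cells(counts, sort(sample.int(ncol(counts$counts), n)))
    tab <- divergence_table(compute_rpkm(sub, lengths))
    dplyr::inner_join(tab, strat, by = "gene") |>
      dplyr::filter(!is.na(.data$stratum), is.finite(.data$cv)) |>
      dplyr::group_by(.data$stratum) |>
      dplyr::summarise(cv = mean(.data$cv), n_genes = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(n_cells = n, rep = rep)
  }))
  out <- rows |>
    dplyr::group_by(.data$n_cells, .data$stratum) |>
    dplyr::summarise(mean_cv = mean(.data$cv),
                     sd_cv = stats::sd(.data$cv),
                     n_genes = .data$n_genes[1L], .groups = "drop")
  structure(out, class = c("saturation_curve", class(out)), axis = "cells")
}
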