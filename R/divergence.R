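#' Per-gene relative divergence table
#'
#' For every gene, the mean rpkm across cells, the sample (n-1) standard
#' deviation, and the relative divergence — the coefficient of variation,
#' sd / mean. A gene whose mean is 0 has an undefined relative divergence
#' and is flagged `NA`, never 0. Genes at or below the expression floor are
#' carried in the table but marked not testable. Spike-in rows are excluded.
#'
#' @param expr An `expression_matrix` from [compute_rpkm()], or a bare
#'   gene-by-cell rpkm matrix.
#' @param min_mean_rpkm Expression floor above which a gene is testable.
#' @return A tibble of class `divergence_table`: `gene`, `mean`, `sd`, `cv`,
#'   `n_cells`, `testable`.
#' @export
divergence_table <- function(expr, min_mean_rpkm = 5) {
  m <- if (inherits(expr, "expression_matrix")) {
    expr$rpkm[!expr$is_spikein[rownames(expr$rpkm)], , drop = FALSE]
  } else {
    as.matrix(expr)
  }
  if (ncol(m) < 2L) {
    stop("relative divergence needs at least 2 cells (sd undefined)", call. = FALSE)
  }
  mu <- rowMeans(m)
  sd_ <- apply(m, 1, stats::sd)
  cv <- ifelse(mu > 0, sd_ / mu, NA_real_)
  out <- tibble::tibble(gene = rownames(m), mean = unname(mu), sd = unname(sd_),
                        cv = unname(cv), n_cells = ncol(m),
                        testable = unname(mu > min_mean_rpkm & !is.na(cv)))
  class(out) <- c("divergence_table", class(out))
  out
}

#' Expression-matched control genes
#'
#' Controls for a tested gene are the other genes whose mean expression
#' falls within `fold_window`-fold of the tested gene's mean (closed
#' interval, so boundary ties are included deterministically). When more
#' than `max_controls` genes qualify, a uniform random sample without
#' replacement of exactly `max_controls` is drawn, reproducibly from `seed`.
#'
#' @param gene Gene id to match.
#' @param table A [divergence_table()].
#' @param fold_window Expression window (fold).
#' @param max_controls Cap on the control set size.
#' @param seed Integer seed for the subsample; `NULL` uses the current RNG
#'   state.
#' @return Character vector of control gene ids (possibly empty: the gene is
#'   then untestable).
#' @export
match_controls <- function(gene, table, fold_window = 2, max_controls = 1000,
                           seed = NULL) {
  i <- match(gene, table$gene)
  if (is.na(i)) stop("gene not in table: ", gene, call. = FALSE)
  mu <- table$mean[i]
  if (!is.finite(mu) || mu <= 0) stop("gene mean must be positive: ", gene, call. = FALSE)
  ok <- table$mean >= mu / fold_window & table$mean <= mu * fold_window &
    table$gene != gene & is.finite(table$cv)
  ctrl <- table$gene[which(ok)]
  if (length(ctrl) > max_controls) {
    if (!is.null(seed)) {
      ctrl <- withr::with_seed(seed, sample(ctrl, max_controls))
    } else {
      ctrl <- sample(ctrl, max_controls)
    }
  }
  ctrl
}

#' Variance-ratio test of a gene's relative divergence against matched controls
#'
#' The squared relative divergence of the tested gene is compared with the
#' median squared relative divergence of its expression-matched controls
#' through the variance-ratio statistic `F = cv_gene^2 / median(cv_ctrl^2)`,
#' referred to the F distribution with (n_cells - 1, n_cells - 1) degrees of
#' freedom; the two-sided p-value is `2 * min(P[F >= f], P[F <= f])` capped
#' at 1. Direction is "more" (diverse) when F > 1, else "less". An
#' empirical alternative uses the two-sided rank of the gene's cv among the
#' controls instead of the F reference.
#'
#' @param gene Gene id.
#' @param controls Character vector of control gene ids (from
#'   [match_controls()]).
#' @param table A [divergence_table()].
#' @param method `"f"` (default) or `"empirical"`.
#' @param min_controls Minimum control set size for a valid test.
#' @return Tibble with one row: `gene`, `p`, `direction`, `f_stat`,
#'   `n_controls`. p is `NA` when the gene is untestable.
#' @export
divergence_test <- function(gene, controls, table, method = c("f", "empirical"),
                            min_controls = 10) {
  method <- match.arg(method)
  i <- match(gene, table$gene)
  cv_g <- table$cv[i]
  n <- table$n_cells[i]
  cvs <- table$cv[match(controls, table$gene)]
  cvs <- cvs[is.finite(cvs)]
  untestable <- tibble::tibble(gene = gene, p = NA_real_,
                               direction = NA_character_, f_stat = NA_real_,
                               n_controls = length(cvs))
  if (!is.finite(cv_g) || length(cvs) < min_controls) return(untestable)
  med <- stats::median(cvs^2)
  if (med == 0) return(untestable)
  f <- cv_g^2 / med
  if (method == "f") {
    df <- n - 1
    p <- 2 * min(stats::pf(f, df, df), stats::pf(f, df, df, lower.tail = FALSE))
  } else {
    k <- length(cvs)
    lo <- (sum(cvs <= cv_g) + 1) / (k + 1)
    hi <- (sum(cvs >= cv_g) + 1) / (k + 1)
    p <- 2 * min(lo, hi)
  }
  tibble::tibble(gene = gene, p = min(p, 1),
                 direction = if (f > 1) "more" else "less",
                 f_stat = f, n_controls = length(cvs))
}

#' Classify genes as more or less diverse than expression-matched controls
#'
#' Runs [match_controls()] and [divergence_test()] for every testable gene
#' (mean above the expression floor, defined cv) and splits the genes with
#' p below `alpha_divergence` by direction. No multiple-testing correction
#' is applied by default (raw P < 0.05 selection); Benjamini-Hochberg is
#' available via `adjust = "BH"`. Fully deterministic given `config$seed`.
#'
#' @param table A [divergence_table()].
#' @param config A [diverge_config()].
#' @param method Test flavour, see [divergence_test()].
#' @param adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return A list of class `divergence_calls`: `more` and `less` (gene id
#'   vectors), `calls` (per-gene tibble with p, direction, significance),
#'   `untestable` (gene ids), `alpha`.
#' @export
classify_divergent <- function(table, config = diverge_config(),
                               method = c("f", "empirical"), adjust = "none") {
  method <- match.arg(method)
  cand <- table$gene[table$testable]
  ord <- order(match(cand, table$gene))
  cand <- cand[ord]
  calls <- withr::with_seed(config$seed, {
    purrr::map_dfr(cand, function(g) {
      ctrl <- match_controls(g, table,
                             fold_window = config$control_fold_window,
                             max_controls = config$max_controls, seed = NULL)
      divergence_test(g, ctrl, table, method = method)
    })
  })
  if (nrow(calls) == 0L) {
    calls <- tibble::tibble(gene = character(), p = numeric(),
                            direction = character(), f_stat = numeric(),
                            n_controls = integer())
  }
  p_use <- if (adjust == "none") calls$p else stats::p.adjust(calls$p, method = adjust)
  calls$significant <- !is.na(p_use) & p_use < config$alpha_divergence
  structure(list(
    more = calls$gene[calls$significant & calls$direction == "more"],
    less = calls$gene[calls$significant & calls$direction == "less"],
    calls = calls,
    untestable = c(setdiff(table$gene, cand), calls$gene[is.na(calls$p)]),
    alpha = config$alpha_divergence),
    class = "divergence_calls")
}

#' @export
print.divergence_calls <- function(x, ...) {
  cat(sprintf("<divergence_calls> %d tested; %d more diverse, %d less diverse (alpha = %g)\n",
              sum(!is.na(x$calls$p)), length(x$more), length(x$less), x$alpha))
  invisible(x)
}

#' Per-gene tibble of divergence calls
#' @param x A `divergence_calls` object.
#' @param ... Unused.
#' @return The per-gene calls tibble.
#' @export
tidy.divergence_calls <- function(x, ...) x$calls

#' One-row summary of divergence calls
#' @param x A `divergence_calls` object.
#' @param ... Unused.
#' @return Tibble: counts of tested, more-, less-diverse and untestable genes.
#' @export
glance.divergence_calls <- function(x, ...) {
  tibble::tibble(n_tested = sum(!is.na(x$calls$p)),
                 n_more = length(x$more), n_less = length(x$less),
                 n_untestable = length(x$untestable), alpha = x$alpha)
}
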