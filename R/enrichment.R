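#' Fisher's exact enrichment of a gene list in one gene set
#'
#' Builds the 2x2 table (in-list & in-set, in-list & not, out-of-list & in-set,
#' out-of-list & not) over the given universe and computes the two-sided
#' exact hypergeometric p-value (probability-mass rule: the sum over all
#' tables with fixed margins whose probability does not exceed the
#' observed one). Set members are intersected with the universe first.
#'
#' @param selected Character vector of selected gene ids (subset of
#'   `universe`).
#' @param set_members Character vector of gene-set member ids.
#' @param universe Character vector: the eligible gene universe.
#' @return Tibble with one row: `a`, `b`, `c`, `d` (table cells), `odds_ratio`
#'   (sample odds ratio, `Inf`/0 on zero cells, unadjusted), `p`.
#' @export
fisher_enrichment <- function(selected, set_members, universe) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty gene universe", call. = FALSE)
  selected <- unique(selected)
  if (length(selected) == 0L) stop("empty selected gene list", call. = FALSE)
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe", call. = FALSE)
  }
  members <- intersect(unique(set_members), universe)
  a <- length(intersect(selected, members))
  b <- length(selected) - a
  cc <- length(members) - a
  d <- length(universe) - a - b - cc
  p <- stats::fisher.test(matrix(c(a, b, cc, d), nrow = 2, byrow = TRUE))$p.value
  or <- if (b == 0L || cc == 0L) {
    if (a == 0L || d == 0L) NA_real_ else Inf
  } else {
    (a * d) / (b * cc)
  }
  tibble::tibble(a = a, b = b, c = cc, d = d, odds_ratio = or, p = min(p, 1))
}

#' Enrichment of more- and less-diverse gene lists across gene sets
#'
#' One Fisher test per (gene set, list) pair; rows with p below `alpha` are
#' flagged. No multiple-testing correction is applied by default (raw
#' P < 0.05 selection); gene sets empty after intersection with the
#' universe are skipped with a warning.
#'
#' @param lists Named list of gene id vectors (typically
#'   `list(more = ..., less = ...)` from [classify_divergent()]).
#' @param gene_sets Named list of gene-set member vectors (see
#'   [read_gene_sets()]).
#' @param universe Eligible gene universe (testable genes).
#' @param alpha Significance level for flagging.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method applied
#'   within each list.
#' @return Tibble: `set`, `list`, table cells, `odds_ratio`, `p`,
#'   `significant`.
#' @export
enrich_all <- function(lists, gene_sets, universe, alpha = 0.05,
                       adjust = "none") {
  stopifnot(is.list(lists), !is.null(names(lists)))
  rows <- purrr::imap_dfr(gene_sets, function(members, set_name) {
    if (length(intersect(members, universe)) == 0L) {
      warning("gene set '", set_name, "' empty after universe intersection; skipped")
      return(NULL)
    }
    purrr::imap_dfr(lists, function(sel, list_name) {
      if (length(sel) == 0L) return(NULL)
      dplyr::mutate(fisher_enrichment(sel, members, universe),
                    set = set_name, list = list_name, .before = 1)
    })
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(set = character(), list = character(), a = integer(),
                          b = integer(), c = integer(), d = integer(),
                          odds_ratio = numeric(), p = numeric(),
                          significant = logical()))
  }
  rows |>
    dplyr::group_by(.data$list) |>
    dplyr::mutate(p_use = if (adjust == "none") .data$p
                  else stats::p.adjust(.data$p, method = adjust)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_use < alpha) |>
    dplyr::select(-"p_use")
}
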