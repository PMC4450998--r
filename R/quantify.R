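#' Normalize tag counts to rpkm
#'
#' rpkm = tags per million mapped tags per kilobase of transcript:
#' `count / (length_kb * library_size / 1e6)`. The per-cell library size is,
#' by default, the total of gene-assigned (non-spike-in) tags in that cell,
#' so that for every cell the identity `sum(rpkm * length_kb) = 1e6` holds
#' exactly over endogenous genes. Externally determined totals (e.g. all
#' mapped tags including intergenic ones) can be supplied instead. Spike-in
#' rows never enter the denominator; their rpkm-scale values are carried
#' along, flagged, for diagnostics only.
#'
#' @param counts A [count_matrix()].
#' @param lengths Tibble `gene`, `length` covering every non-spike-in gene
#'   (missing genes are an error, not a silent drop). Spike-ins without an
#'   annotated length are assigned 1 kb for display purposes.
#' @param denominator `"gene_total"` (default) or `"mapped"`; the latter
#'   requires `library_sizes`.
#' @param library_sizes Named numeric vector of per-cell mapped-tag totals,
#'   used when `denominator = "mapped"`.
#'
#' @return An `expression_matrix`: list with `rpkm` (gene-by-cell matrix),
#'   `library_sizes` (named vector), `is_spikein` (named logical).
#'   Cells with zero library size are dropped with a warning.
#' @export
compute_rpkm <- function(counts, lengths, denominator = c("gene_total", "mapped"),
                         library_sizes = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  denominator <- match.arg(denominator)
  gid <- genes(counts)
  endo <- gid[!counts$is_spikein]
  missing <- setdiff(endo, lengths$gene)
  if (length(missing)) {
    stop("no transcript length for gene(s): ",
         paste(utils::head(missing, 3), collapse = ", "),
         if (length(missing) > 3) sprintf(" (+%d more)", length(missing) - 3),
         call. = FALSE)
  }
  len <- stats::setNames(lengths$length, lengths$gene)[gid]
  len[is.na(len)] <- 1000  # unannotated spike-ins: display scale only
  if (any(len <= 0)) stop("transcript lengths must be positive", call. = FALSE)

  if (denominator == "gene_total") {
    lib <- colSums(counts$counts[!counts$is_spikein, , drop = FALSE])
  } else {
    if (is.null(library_sizes)) {
      stop("denominator = \"mapped\" needs library_sizes", call. = FALSE)
    }
    lib <- library_sizes[cells(counts)]
    if (anyNA(lib)) stop("library_sizes missing for some cells", call. = FALSE)
  }
  zero <- lib <= 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " cell(s) with zero library size: ",
            paste(cells(counts)[zero], collapse = ", "))
  }
  keep <- !zero
  m <- counts$counts[, keep, drop = FALSE]
  lib <- lib[keep]
  rpkm <- sweep(m / (len / 1000), 2, lib / 1e6, "/")
  structure(list(rpkm = rpkm, library_sizes = lib,
                 is_spikein = counts$is_spikein),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d cells (rpkm); median library %s tags\n",
              nrow(x$rpkm), ncol(x$rpkm),
              format(stats::median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$rpkm)

#' Long-format view of an expression matrix
#' @param x An `expression_matrix`.
#' @param ... Unused.
#' @return Tibble `gene`, `cell`, `rpkm`, `is_spikein`.
#' @export
tidy.expression_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$rpkm), .name_repair = "minimal") |>
    rlang::set_names(c("gene", "cell", "rpkm")) |>
    dplyr::mutate(is_spikein = unname(x$is_spikein[.data$gene]))
}

#' Percentage of mapped tags falling in annotated gene regions
#'
#' @param mapped_total Total mapped tags (vectorized).
#' @param in_gene_total Tags mapped within gene regions.
#' @return Integer percentage(s), `round(100 * in_gene_total / mapped_total)`.
#' @export
refseq_fraction <- function(mapped_total, in_gene_total) {
  if (any(mapped_total <= 0)) stop("mapped_total must be positive", call. = FALSE)
  if (any(in_gene_total < 0 | in_gene_total > mapped_total)) {
    stop("in_gene_total must lie in [0, mapped_total]", call. = FALSE)
  }
  as.integer(round(100 * in_gene_total / mapped_total))
}

#' Library complexity: mean tag multiplicity per mapping coordinate
#'
#' Tags sharing identical start and end mapping coordinates are presumed PCR
#' duplicates; complexity is the average number of tags per distinct
#' coordinate pair (1.0 = no duplication).
#'
#' @param tags A data frame with columns `start` and `end` (one row per tag;
#'   an optional `chrom` column joins the coordinate key), or a path to a
#'   BED-like 3-column file (chrom, start, end; 0-based half-open).
#' @return Mean multiplicity, a number >= 1.
#' @export
complexity <- function(tags) {
  if (is.character(tags)) {
    tags <- utils::read.delim(tags, header = FALSE,
                              col.names = c("chrom", "start", "end"))
  }
  tags <- as.data.frame(tags)
  if (nrow(tags) == 0L) stop("no tags supplied", call. = FALSE)
  key_cols <- intersect(c("chrom", "start", "end"), names(tags))
  if (!all(c("start", "end") %in% key_cols)) {
    stop("tags need start and end columns", call. = FALSE)
  }
  key <- do.call(paste, c(tags[key_cols], sep = ":"))
  nrow(tags) / length(unique(key))
}

#' Per-cell library summary
#'
#' @param counts A [count_matrix()].
#' @param mapped_totals Optional named vector of all-mapped tag totals per
#'   cell; defaults to the in-matrix totals (then the fraction is 1 by
#'   construction and only reported for completeness).
#' @return Tibble per cell: `cell`, `mapped_tags`, `gene_tags`,
#'   `gene_fraction_pct`.
#' @export
library_summary <- function(counts, mapped_totals = NULL) {
  stopifnot(inherits(counts, "count_matrix"))
  gene_tags <- colSums(counts$counts[!counts$is_spikein, , drop = FALSE])
  mapped <- (mapped_totals %||% colSums(counts$counts))[cells(counts)]
  tibble::tibble(cell = cells(counts),
                 mapped_tags = unname(mapped),
                 gene_tags = unname(gene_tags),
                 gene_fraction_pct = refseq_fraction(unname(mapped), unname(gene_tags)))
}

#' Reproducibility of means and relative divergences between replicates
#'
#' Pearson correlation of per-gene log10 mean rpkm and of per-gene relative
#' divergence (CV) between two divergence tables, restricted to genes whose
#' mean exceeds `min_mean_rpkm` in both tables and whose CV is defined.
#'
#' @param table_a,table_b Divergence tables (see [divergence_table()]) over a
#'   shared gene universe.
#' @param min_mean_rpkm Expression floor applied in both tables.
#' @param log_eps rpkm offset inside the log10 transform of means.
#' @return Tibble with one row: `r_means`, `r_cvs`, `n_genes`.
#' @export
compare_replicates <- function(table_a, table_b, min_mean_rpkm = 5,
                               log_eps = 0.01) {
  j <- dplyr::inner_join(table_a, table_b, by = "gene",
                         suffix = c("_a", "_b")) |>
    dplyr::filter(.data$mean_a > min_mean_rpkm, .data$mean_b > min_mean_rpkm,
                  is.finite(.data$cv_a), is.finite(.data$cv_b))
  if (nrow(j) < 3L) stop("fewer than 3 shared genes above the expression floor",
                         call. = FALSE)
  tibble::tibble(
    r_means = stats::cor(log10(j$mean_a + log_eps), log10(j$mean_b + log_eps)),
    r_cvs = stats::cor(j$cv_a, j$cv_b),
    n_genes = nrow(j))
}
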