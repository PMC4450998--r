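#' Construct a tag-count matrix
#'
#' A `count_matrix` holds gene-by-cell non-negative integer tag counts with a
#' per-gene spike-in flag. It is the entry point of every analysis in the
#' package: quality control, rpkm quantification and everything downstream
#' operate on this container.
#'
#' @param counts Numeric matrix of non-negative integers, genes in rows and
#'   cells in columns. Row and column names are required and must be unique.
#' @param is_spikein Logical vector, one entry per gene (recycled from a
#'   character vector of spike-in gene ids if given as such). Defaults to no
#'   spike-ins.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `is_spikein` (named logical).
#' @export
count_matrix <- function(counts, is_spikein = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix needs gene row names and cell column names", call. = FALSE)
  }
  if (nrow(counts) < 1L || ncol(counts) < 1L) {
    stop("count matrix needs at least one gene and one cell", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene identifier: ",
         rownames(counts)[anyDuplicated(rownames(counts))], call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate cell identifier: ",
         colnames(counts)[anyDuplicated(colnames(counts))], call. = FALSE)
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf("non-integer or negative count '%s' at gene %s, cell %s",
                 format(counts[bad[1L]]), rownames(counts)[i[1L]],
                 colnames(counts)[i[2L]]), call. = FALSE)
  }
  storage.mode(counts) <- "integer"
  if (is.null(is_spikein)) {
    is_spikein <- rep(FALSE, nrow(counts))
  } else if (is.character(is_spikein)) {
    is_spikein <- rownames(counts) %in% is_spikein
  }
  stopifnot(length(is_spikein) == nrow(counts))
  names(is_spikein) <- rownames(counts)
  structure(list(counts = counts, is_spikein = is_spikein),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d genes (%d spike-ins) x %d cells; %d total tags\n",
              nrow(x$counts), sum(x$is_spikein), ncol(x$counts),
              sum(x$counts)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Gene and cell identifiers of a count matrix
#' @param x A `count_matrix`.
#' @return Character vector of identifiers.
#' @export
genes <- function(x) rownames(x$counts)

#' @rdname genes
#' @export
cells <- function(x) colnames(x$counts)

#' Restrict a count matrix to a subset of cells (order preserved)
#' @param x A `count_matrix`.
#' @param keep Character vector of cell ids, or logical/integer index.
#' @return A `count_matrix` with the selected cells.
#' @export
subset_cells <- function(x, keep) {
  stopifnot(inherits(x, "count_matrix"))
  m <- x$counts[, keep, drop = FALSE]
  if (is.character(keep)) m <- x$counts[, colnames(x$counts) %in% keep, drop = FALSE]
  count_matrix(m, is_spikein = x$is_spikein)
}

#' Convert a count matrix to a long tibble
#'
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `gene`, `cell`, `count`, `is_spikein`.
#' @export
tidy.count_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$counts), .name_repair = "minimal") |>
    rlang::set_names(c("gene", "cell", "count")) |>
    dplyr::mutate(is_spikein = unname(x$is_spikein[.data$gene]),
                  count = as.integer(.data$count))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' One-row summary of a count matrix
#' @param x A `count_matrix`.
#' @param ... Unused.
#' @return A one-row tibble: gene/cell/spike-in counts and total tags.
#' @export
glance.count_matrix <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$counts), n_cells = ncol(x$counts),
                 n_spikeins = sum(x$is_spikein),
                 total_tags = sum(as.numeric(x$counts)))
}
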