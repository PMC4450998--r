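#' Read a gene-by-cell tag-count matrix
#'
#' TSV layout: genes as rows, cells as columns, first column holding the gene
#' identifier, header row of cell identifiers. MatrixMarket layout: a `.mtx`
#' file accompanied by plain-text sidecar files listing gene ids and cell ids,
#' one per line.
#'
#' @param path Path to the TSV or MTX file.
#' @param format `"tsv"` or `"mtx"`. Guessed from the file extension when
#'   omitted.
#' @param spikein_spec Optional spike-in specification (see
#'   [read_spikein_spec()]) or character vector of spike-in gene ids; matching
#'   rows are flagged.
#' @param genes_file,cells_file Sidecar paths for MTX input; default to
#'   `<stem>.genes.txt` and `<stem>.cells.txt` next to the `.mtx` file.
#'
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx"), spikein_spec = NULL,
                              genes_file = NULL, cells_file = NULL) {
  if (missing(format)) {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                             colClasses = "character")
    if (ncol(tab) < 2L) stop("malformed header in ", path, call. = FALSE)
    gene_ids <- tab[[1L]]
    vals <- as.matrix(tab[, -1L, drop = FALSE])
    num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
    bad <- which(is.na(num) | num != round(num) | num < 0)
    if (length(bad)) {
      i <- arrayInd(bad[1L], dim(num))
      stop(sprintf("non-integer count '%s' at gene %s, cell %s in %s",
                   vals[bad[1L]], gene_ids[i[1L]], colnames(vals)[i[2L]], path),
           call. = FALSE)
    }
    dimnames(num) <- list(gene_ids, colnames(vals))
    m <- num
  } else {
    stem <- sub("\\.mtx$", "", path)
    genes_file <- genes_file %||% paste0(stem, ".genes.txt")
    cells_file <- cells_file %||% paste0(stem, ".cells.txt")
    for (f in c(genes_file, cells_file)) {
      if (!file.exists(f)) stop("missing MTX sidecar file: ", f, call. = FALSE)
    }
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes_file)
    colnames(m) <- readLines(cells_file)
  }
  spike_ids <- if (is.data.frame(spikein_spec)) spikein_spec$spikein else spikein_spec
  count_matrix(m, is_spikein = spike_ids)
}

#' Write a count matrix to disk
#'
#' @param x A [count_matrix()].
#' @param path Destination file (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"` (guessed from the extension).
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  stopifnot(inherits(x, "count_matrix"))
  if (missing(format)) format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(gene = genes(x), x$counts, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(genes(x), paste0(stem, ".genes.txt"))
    writeLines(cells(x), paste0(stem, ".cells.txt"))
  }
  invisible(path)
}

#' Read per-gene transcript lengths
#'
#' TSV input gives literal lengths (columns `gene`, `length`). GTF input
#' gives, for each `gene_id`, the length of the union of its exon intervals —
#' overlapping exons are merged, not summed, so alternative isoforms do not
#' double-count shared bases. GTF coordinates are 1-based inclusive; strand is
#' ignored (lengths are strand-symmetric).
#'
#' @param path Path to the TSV or GTF file.
#' @param format `"tsv"` or `"gtf"` (guessed from the extension).
#' @return A tibble with columns `gene` and `length` (positive integer bases).
#' @export
read_gene_lengths <- function(path, format = c("tsv", "gtf")) {
  if (missing(format)) {
    format <- if (grepl("\\.gtf(\\.gz)?$", path)) "gtf" else "tsv"
  }
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- two_column_tsv(path, c("gene", "length"))
    tab$length <- suppressWarnings(as.numeric(tab$length))
    if (any(!is.finite(tab$length) | tab$length <= 0)) {
      stop("non-positive transcript length for gene ",
           tab$gene[which(!is.finite(tab$length) | tab$length <= 0)[1L]],
           call. = FALSE)
    }
    out <- tibble::tibble(gene = tab$gene, length = as.integer(tab$length))
  } else {
    gr <- rtracklayer::import(path, format = "gtf")
    gr <- gr[gr$type == "exon"]
    if (length(gr) == 0L) stop("no exon features in ", path, call. = FALSE)
    if (is.null(gr$gene_id) || anyNA(gr$gene_id)) {
      stop("exon feature without gene_id in ", path, call. = FALSE)
    }
    GenomicRanges::strand(gr) <- "*"  # lengths are strand-symmetric
    merged <- GenomicRanges::reduce(GenomicRanges::split(gr, gr$gene_id))
    lens <- vapply(GenomicRanges::width(merged), sum, numeric(1))
    out <- tibble::tibble(gene = names(lens), length = as.integer(lens))
  }
  if (anyDuplicated(out$gene)) {
    stop("duplicate gene id in length annotation: ",
         out$gene[anyDuplicated(out$gene)], call. = FALSE)
  }
  out
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated fields `name`, `description`,
#' then member gene ids. Duplicate members within a line are collapsed.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors of member gene ids.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop(sprintf("GMT line %d has fewer than 3 fields in %s", short[1L], path),
         call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Destination path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- mapply(function(nm, desc, members) {
    paste(c(nm, desc, members), collapse = "\t")
  }, names(sets), descriptions, sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read a spike-in specification
#'
#' Two-column TSV mapping spike-in gene id to known input copy number.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `spikein` and `copies`.
#' @export
read_spikein_spec <- function(path) {
  tab <- two_column_tsv(path, c("spikein", "copies"))
  tab$copies <- suppressWarnings(as.numeric(tab$copies))
  if (any(!is.finite(tab$copies) | tab$copies <= 0)) {
    stop("spike-in copy numbers must be positive", call. = FALSE)
  }
  tibble::tibble(spikein = tab$spikein, copies = tab$copies)
}

#' Read cell metadata
#'
#' TSV with header `cell`, `line`, `treatment`, `replicate` (replicate
#' optional).
#'
#' @param path Path to the TSV.
#' @return A tibble with one row per cell.
#' @export
read_cell_metadata <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  needed <- c("cell", "line", "treatment")
  if (!all(needed %in% names(tab))) {
    stop("cell metadata needs columns: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  if (!"replicate" %in% names(tab)) tab$replicate <- "r1"
  tibble::as_tibble(tab)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# read a two-column whitespace/tab table as character, dropping an optional
# header row (detected by a non-numeric second field)
two_column_tsv <- function(path, names) {
  tab <- utils::read.delim(path, header = FALSE, sep = "",
                           colClasses = "character", col.names = names)
  if (nrow(tab) && is.na(suppressWarnings(as.numeric(tab[[2L]][1L])))) {
    tab <- tab[-1L, , drop = FALSE]
  }
  tab
}
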