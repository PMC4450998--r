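#' Leave-one-out spike-in z-scores per cell
#'
#' For each cell and spike-in channel, the deviation of the cell's spike-in
#' tag count from the other cells: `z = (x - mean(others)) / sd(others)`,
#' with the sample (n-1) standard deviation, on either a log10(count+1)
#' scale (default — spike-in counts span orders of magnitude) or the raw
#' count scale. When the other cells are exactly constant, z is 0 if the
#' cell matches the common value and +/-Inf otherwise.
#'
#' @param counts A [count_matrix()].
#' @param spikein_spec Tibble `spikein`, `copies` (see [read_spikein_spec()]);
#'   exactly these channels are used. Defaults to all flagged spike-in rows.
#' @param scale `"log"` or `"linear"`.
#' @return Tibble per cell x spike-in: `cell`, `spikein`, `count`, `z`.
#' @export
spikein_zscores <- function(counts, spikein_spec = NULL,
                            scale = c("log", "linear")) {
  stopifnot(inherits(counts, "count_matrix"))
  scale <- match.arg(scale)
  ids <- if (is.null(spikein_spec)) genes(counts)[counts$is_spikein] else spikein_spec$spikein
  missing <- setdiff(ids, genes(counts))
  if (length(missing)) {
    stop("spike-in not present in matrix: ", missing[1L], call. = FALSE)
  }
  if (!all(counts$is_spikein[ids])) {
    stop("spike-in spec lists a gene not flagged is_spikein", call. = FALSE)
  }
  if (length(ids) == 0L) stop("no spike-in channels to assess", call. = FALSE)
  n <- ncol(counts$counts)
  if (n < 3L) stop("need at least 3 cells for leave-one-out z-scores", call. = FALSE)

  x <- counts$counts[ids, , drop = FALSE]
  v <- if (scale == "log") log10(x + 1) else x * 1.0

  # leave-one-out mean and sd from centered sums (numerically stable);
  # an exact-tie sd of 0 gives z = 0 on agreement, +/-Inf otherwise
  m <- rowMeans(v)
  dev <- v - m
  ss <- rowSums(dev^2)
  loo_mean <- (n * m - v) / (n - 1)
  loo_var <- pmax(0, (ss - dev^2 * n / (n - 1)) / (n - 2))
  tol <- 1e-10 * (ss / n + 1)
  loo_var[loo_var < tol] <- 0
  loo_sd <- sqrt(loo_var)
  delta <- v - loo_mean
  delta[abs(delta) < 1e-8 * (abs(loo_mean) + 1)] <- 0
  z <- delta / loo_sd
  z[loo_sd == 0] <- ifelse(delta[loo_sd == 0] == 0, 0,
                           Inf * sign(delta[loo_sd == 0]))

  tibble::as_tibble(as.table(z), .name_repair = "minimal") |>
    rlang::set_names(c("spikein", "cell", "z")) |>
    dplyr::mutate(count = as.integer(x[cbind(.data$spikein, .data$cell)])) |>
    dplyr::select("cell", "spikein", "count", "z") |>
    dplyr::arrange(match(.data$cell, cells(counts)))
}

#' Spike-in quality-control report
#'
#' A cell fails when any spike-in channel deviates by more than
#' `sd_threshold` standard deviations from the other cells.
#'
#' @param counts A [count_matrix()].
#' @param spikein_spec Tibble `spikein`, `copies`, or `NULL` for all flagged
#'   spike-ins.
#' @param sd_threshold Deviation threshold in standard deviations.
#' @param scale `"log"` (default) or `"linear"` (see [spikein_zscores()]).
#' @return An object of class `cell_qc_report`: tibble per cell with `cell`,
#'   `pass`, `max_abs_z`, `failing_spikeins` (comma-separated), carrying the
#'   full z-score table as attribute `zscores` and the threshold as
#'   attribute `sd_threshold`.
#' @export
spikein_qc <- function(counts, spikein_spec = NULL, sd_threshold = 2,
                       scale = c("log", "linear")) {
  if (sd_threshold <= 0) stop("sd_threshold must be positive", call. = FALSE)
  zs <- spikein_zscores(counts, spikein_spec, scale = match.arg(scale))
  report <- zs |>
    dplyr::group_by(.data$cell) |>
    dplyr::summarise(
      max_abs_z = max(abs(.data$z)),
      failing_spikeins = paste(.data$spikein[abs(.data$z) > sd_threshold],
                               collapse = ","),
      .groups = "drop") |>
    dplyr::mutate(pass = .data$max_abs_z <= sd_threshold) |>
    dplyr::select("cell", "pass", "max_abs_z", "failing_spikeins") |>
    dplyr::arrange(match(.data$cell, cells(counts)))
  structure(report, class = c("cell_qc_report", class(report)),
            zscores = zs, sd_threshold = sd_threshold)
}

#' One-row summary of a QC report
#' @param x A `cell_qc_report`.
#' @param ... Unused.
#' @return Tibble: cells assessed, passed, failed, threshold.
#' @export
glance.cell_qc_report <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x), n_pass = sum(x$pass),
                 n_fail = sum(!x$pass),
                 sd_threshold = attr(x, "sd_threshold"))
}

#' Drop cells that fail spike-in quality control
#'
#' @param counts A [count_matrix()].
#' @param report A `cell_qc_report` from [spikein_qc()] covering exactly the
#'   matrix's cells.
#' @return A [count_matrix()] restricted to passing cells, original order
#'   and counts untouched.
#' @export
filter_cells <- function(counts, report) {
  stopifnot(inherits(counts, "count_matrix"), inherits(report, "cell_qc_report"))
  if (!setequal(report$cell, cells(counts))) {
    stop("QC report does not match matrix cells", call. = FALSE)
  }
  passing <- report$cell[report$pass]
  if (length(passing) == 0L) {
    stop("all cells fail spike-in QC; review the SD threshold", call. = FALSE)
  }
  keep <- cells(counts) %in% passing
  count_matrix(counts$counts[, keep, drop = FALSE],
               is_spikein = genes(counts)[counts$is_spikein])
}
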