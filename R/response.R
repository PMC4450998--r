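#' Compare two conditions: fold changes of means and relative divergences
#'
#' For every shared gene, the fold change of mean expression
#' `(mean_B + pc) / (mean_A + pc)` (pseudocount `pc` guards zeros) and of
#' relative divergence `cv_B / cv_A` (left unregularized; undefined when
#' either cv is 0 or undefined). Condition A is the reference (untreated /
#' parental). A gene is eligible when its mean exceeds `min_mean_rpkm` in at
#' least one condition and both cvs are defined; otherwise it is classed
#' `ineligible`. Eligible genes are classed `induced` / `repressed` when the
#' mean fold change exceeds `fc_threshold` / falls below its reciprocal
#' (strict inequalities), else `unchanged`.
#'
#' @param table_a,table_b [divergence_table()]s for the reference and the
#'   comparison condition, over a shared gene universe.
#' @param config A [diverge_config()] (uses `min_mean_rpkm`, `pseudocount`,
#'   `fc_threshold`).
#' @return A tibble of class `response_comparison`: `gene`, `mean_a`,
#'   `mean_b`, `cv_a`, `cv_b`, `mean_fc`, `cv_fc`, `class`.
#' @export
compare_conditions <- function(table_a, table_b, config = diverge_config()) {
  j <- dplyr::inner_join(table_a, table_b, by = "gene", suffix = c("_a", "_b"))
  if (nrow(j) == 0L) stop("disjoint gene universes", call. = FALSE)
  pc <- config$pseudocount
  out <- j |>
    dplyr::transmute(
      gene = .data$gene,
      mean_a = .data$mean_a, mean_b = .data$mean_b,
      cv_a = .data$cv_a, cv_b = .data$cv_b,
      mean_fc = (.data$mean_b + pc) / (.data$mean_a + pc),
      cv_fc = dplyr::if_else(is.finite(.data$cv_a) & is.finite(.data$cv_b) &
                               .data$cv_a > 0 & .data$cv_b > 0,
                             .data$cv_b / .data$cv_a, NA_real_),
      eligible = (.data$mean_a > config$min_mean_rpkm |
                    .data$mean_b > config$min_mean_rpkm) &
        is.finite(.data$cv_a) & is.finite(.data$cv_b)) |>
    dplyr::mutate(class = dplyr::case_when(
      !.data$eligible ~ "ineligible",
      .data$mean_fc > config$fc_threshold ~ "induced",
      .data$mean_fc < 1 / config$fc_threshold ~ "repressed",
      TRUE ~ "unchanged")) |>
    dplyr::select(-"eligible")
  class(out) <- c("response_comparison", class(out))
  out
}

#' Responder genes: more than threshold-fold change of mean expression
#'
#' @param cmp A [compare_conditions()] result.
#' @param fc_threshold Fold-change threshold (> 1); strict inequalities.
#' @return List with `induced` and `repressed` gene id vectors (eligible
#'   genes only).
#' @export
select_responders <- function(cmp, fc_threshold = 2) {
  if (fc_threshold <= 1) stop("fc_threshold must exceed 1", call. = FALSE)
  el <- cmp[cmp$class != "ineligible", ]
  list(induced = el$gene[el$mean_fc > fc_threshold],
       repressed = el$gene[el$mean_fc < 1 / fc_threshold])
}

#' Quadrant summary of mean and divergence shifts
#'
#' Counts eligible genes in each quadrant of the (log2 mean fold change,
#' log2 cv fold change) plane and reports median shifts, overall and per
#' gene group (e.g. ribosomal, cancer-related, pathway panels supplied as a
#' GMT-style named list). A drug response that dampens cell-to-cell
#' variability without shifting means shows up as mass in the upper-left
#' quadrants' mirror (mean_fc < 1 kept, cv_fc < 1).
#'
#' @param cmp A [compare_conditions()] result.
#' @param groups Optional named list of gene id vectors.
#' @return Tibble per group (`"all"` first): gene counts per quadrant
#'   (`q_pp` = mean up & cv up, `q_pm` = mean up & cv down, `q_mp`, `q_mm`,
#'   zeros on an axis excluded), `median_log2_mean_fc`, `median_log2_cv_fc`,
#'   `n_genes`.
#' @export
shift_summary <- function(cmp, groups = NULL) {
  el <- cmp[cmp$class != "ineligible" & is.finite(cmp$cv_fc), ]
  one <- function(genes, label) {
    g <- el[el$gene %in% genes, ]
    lm <- log2(g$mean_fc)
    lc <- log2(g$cv_fc)
    tibble::tibble(group = label,
                   q_pp = sum(lm > 0 & lc > 0), q_pm = sum(lm > 0 & lc < 0),
                   q_mp = sum(lm < 0 & lc > 0), q_mm = sum(lm < 0 & lc < 0),
                   median_log2_mean_fc = if (nrow(g)) stats::median(lm) else NA_real_,
                   median_log2_cv_fc = if (nrow(g)) stats::median(lc) else NA_real_,
                   n_genes = nrow(g))
  }
  out <- one(el$gene, "all")
  if (!is.null(groups)) {
    out <- dplyr::bind_rows(out, purrr::imap_dfr(groups, one))
  }
  out
}
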