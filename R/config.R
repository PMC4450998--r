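#' Analysis configuration
#'
#' Collects the tunable thresholds used across the pipeline. Defaults mirror
#' the published analysis: cells are discarded when any spike-in deviates by
#' more than 2 standard deviations from the other cells; genes enter the
#' divergence test above 5 rpkm mean expression; expression-matched controls
#' lie within a two-fold window, capped at 1,000 randomly chosen genes; raw
#' P < 0.05 selects divergent genes and enriched gene sets; responders change
#' more than two-fold.
#'
#' @param qc_sd_threshold Spike-in z-score threshold for discarding cells.
#' @param min_mean_rpkm Minimum mean rpkm for a gene to be testable.
#' @param control_fold_window Expression window (fold) for matched controls.
#' @param max_controls Cap on the number of matched controls per gene.
#' @param alpha_divergence Significance level for the divergence F-test.
#' @param alpha_enrichment Significance level for Fisher enrichment.
#' @param fc_threshold Fold-change threshold for responder selection.
#' @param pseudocount rpkm pseudocount used in mean fold changes.
#' @param log_eps rpkm offset used inside log10 transforms.
#' @param seed Base random seed for control sampling and simulation.
#'
#' @return A list of class `diverge_config`.
#' @export
diverge_config <- function(qc_sd_threshold = 2,
                           min_mean_rpkm = 5,
                           control_fold_window = 2,
                           max_controls = 1000,
                           alpha_divergence = 0.05,
                           alpha_enrichment = 0.05,
                           fc_threshold = 2,
                           pseudocount = 0.1,
                           log_eps = 0.01,
                           seed = 1L) {
  cfg <- list(qc_sd_threshold = qc_sd_threshold,
              min_mean_rpkm = min_mean_rpkm,
              control_fold_window = control_fold_window,
              max_controls = max_controls,
              alpha_divergence = alpha_divergence,
              alpha_enrichment = alpha_enrichment,
              fc_threshold = fc_threshold,
              pseudocount = pseudocount,
              log_eps = log_eps,
              seed = as.integer(seed))
  validate_config(cfg)
  structure(cfg, class = "diverge_config")
}

validate_config <- function(cfg) {
  pos <- c("qc_sd_threshold", "min_mean_rpkm", "control_fold_window",
           "max_controls", "fc_threshold", "pseudocount", "log_eps")
  for (nm in pos) {
    if (!is.numeric(cfg[[nm]]) || !is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      stop("config field '", nm, "' must be a positive number", call. = FALSE)
    }
  }
  for (nm in c("alpha_divergence", "alpha_enrichment")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) {
      stop("config field '", nm, "' must lie in [0, 1)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Read an analysis configuration from YAML
#'
#' Fields absent from the file keep their [diverge_config()] defaults;
#' unknown fields are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `diverge_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(diverge_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop("unknown config field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  do.call(diverge_config, vals)
}

#' @export
print.diverge_config <- function(x, ...) {
  cat("<diverge_config>\n")
  for (nm in names(x)) cat(sprintf("  %-20s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
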