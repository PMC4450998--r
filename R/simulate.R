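#' Simulation configuration
#'
#' Describes a synthetic single-cell tag-count experiment with the statistical
#' structure the analysis assumes: a Zipf-like (power-law over expression
#' ranks) profile of average expression, gene-specific negative-binomial
#' overdispersion producing the characteristic mean-CV dependence, extra
#' dropout for lowly expressed genes, three spike-in channels whose expected
#' counts are linear in their input copy numbers, per-line and per-treatment
#' shifts of means and CVs for gene subsets, and planted outlier cells whose
#' spike-in counts are distorted so that quality control can be validated
#' independently of the biology.
#'
#' @param n_genes Number of endogenous genes.
#' @param groups Tibble with columns `line`, `treatment`, `n_cells` (and
#'   optionally `replicate`), one row per cell group.
#' @param depth Nominal tags per cell before the per-cell depth factor.
#' @param depth_sdlog Log-normal sdlog of the per-cell depth factor
#'   (library-size variation).
#' @param zipf_exponent Power-law exponent of mean expression over ranks.
#' @param phi_meanlog,phi_sdlog Log-normal parameters of the per-gene
#'   negative-binomial dispersion phi (CV^2 = 1/mu + phi).
#' @param dropout_max,dropout_scale Dropout law: a count is zeroed with
#'   probability `dropout_max * exp(-mean_rpkm / dropout_scale)`.
#' @param spikein_copies Named numeric vector of input copy numbers for the
#'   spike-in channels.
#' @param spikein_efficiency Capture efficiency: expected spike-in count =
#'   copies x efficiency x cell depth factor.
#' @param line_effects Named list, one entry per non-reference line:
#'   `list(genes =, mean_fold =, cv_fold =)`. `genes` may be gene ids or a
#'   single number in (0,1) giving the fraction of genes to shift (drawn
#'   reproducibly from the seed).
#' @param treatment_effects Same shape, keyed by treatment label.
#' @param n_outlier_cells Number of planted QC-outlier cells.
#' @param outlier_distortion Multiplier applied to the spike-in expectations
#'   of outlier cells.
#' @param length_meanlog,length_sdlog Log-normal parameters of transcript
#'   lengths (bases).
#' @param seed Random seed; same seed, same outputs, bit for bit.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 5000,
                       groups = tibble::tibble(line = "L1", treatment = "none",
                                               n_cells = 46),
                       depth = 5e5,
                       depth_sdlog = 0.25,
                       zipf_exponent = 1.3,
                       phi_meanlog = log(0.4),
                       phi_sdlog = 0.6,
                       dropout_max = 0.3,
                       dropout_scale = 5,
                       spikein_copies = c(SPIKE1 = 1e3, SPIKE2 = 1e4, SPIKE3 = 1e5),
                       spikein_efficiency = 0.05,
                       line_effects = list(),
                       treatment_effects = list(),
                       n_outlier_cells = 0,
                       outlier_distortion = 10,
                       length_meanlog = log(2000),
                       length_sdlog = 0.5,
                       seed = 1L) {
  groups <- tibble::as_tibble(groups)
  if (!all(c("line", "treatment", "n_cells") %in% names(groups))) {
    stop("groups needs columns line, treatment, n_cells", call. = FALSE)
  }
  if (!"replicate" %in% names(groups)) groups$replicate <- "r1"
  if (any(groups$n_cells < 1)) stop("empty cell group", call. = FALSE)
  num <- c(n_genes = n_genes, depth = depth, depth_sdlog = depth_sdlog,
           zipf_exponent = zipf_exponent, dropout_max = dropout_max,
           dropout_scale = dropout_scale,
           spikein_efficiency = spikein_efficiency,
           n_outlier_cells = n_outlier_cells,
           outlier_distortion = outlier_distortion)
  if (any(!is.finite(num)) || any(num < 0)) {
    stop("non-finite or negative simulation parameter", call. = FALSE)
  }
  if (any(!is.finite(spikein_copies)) || any(spikein_copies <= 0)) {
    stop("spike-in copies must be positive and finite", call. = FALSE)
  }
  structure(list(n_genes = as.integer(n_genes), groups = groups, depth = depth,
                 depth_sdlog = depth_sdlog, zipf_exponent = zipf_exponent,
                 phi_meanlog = phi_meanlog, phi_sdlog = phi_sdlog,
                 dropout_max = dropout_max, dropout_scale = dropout_scale,
                 spikein_copies = spikein_copies,
                 spikein_efficiency = spikein_efficiency,
                 line_effects = line_effects,
                 treatment_effects = treatment_effects,
                 n_outlier_cells = as.integer(n_outlier_cells),
                 outlier_distortion = outlier_distortion,
                 length_meanlog = length_meanlog, length_sdlog = length_sdlog,
                 seed = as.integer(seed)),
            class = "sim_config")
}

lookup_set <- function(sets, key) {
  if (key %in% names(sets)) sets[[key]] else character()
}

resolve_effect_genes <- function(effect, gene_ids) {
  g <- effect$genes
  if (is.null(g)) g <- 0.1
  if (is.numeric(g) && length(g) == 1L && g < 1) {
    sample(gene_ids, size = max(1L, round(g * length(gene_ids))))
  } else if (is.numeric(g)) {
    gene_ids[g]
  } else {
    bad <- setdiff(g, gene_ids)
    if (length(bad)) stop("effect gene not simulated: ", bad[1L], call. = FALSE)
    g
  }
}

#' Simulate a single-cell tag-count experiment
#'
#' Draws gene-by-cell counts from a negative-binomial law with gene- and
#' group-specific mean and dispersion, applies extra dropout for lowly
#' expressed genes, adds three Poisson spike-in channels linear in input
#' copies, and plants QC-outlier cells by distorting their spike-in
#' expectations only. A truth table records every generative parameter so
#' downstream estimators can be validated against it.
#'
#' Baseline mean expression follows a power law over gene ranks, scaled so
#' that the expression profile is expressed in rpkm-like units (the sum of
#' mean rpkm times length in kb is 10^6). Per-gene CV^2 under this model is
#' 1/mu + phi, so CV falls with increasing mean and plateaus at sqrt(phi)
#' for well-expressed genes. CV shifts requested through `line_effects` or
#' `treatment_effects` are realised by re-solving phi for the target CV
#' (floored at the Poisson limit phi = 0).
#'
#' @param config A [sim_config()].
#' @return A list with elements `matrix` ([count_matrix()]), `metadata`
#'   (cell tibble), `spikein_spec` (tibble `spikein`, `copies`),
#'   `gene_lengths` (tibble `gene`, `length`) and `truth` (list of tibbles
#'   `genes` — per gene x group generative parameters — and `cells`).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ng <- config$n_genes
  gene_ids <- sprintf("G%04d", seq_len(ng))
  lengths <- pmax(200L, as.integer(round(
    stats::rlnorm(ng, config$length_meanlog, config$length_sdlog))))
  len_kb <- lengths / 1000

  # Zipf-like mean profile in rpkm units, normalised so sum(rpkm * kb) = 1e6
  raw <- seq_len(ng)^(-config$zipf_exponent)
  base_rpkm <- raw * 1e6 / sum(raw * len_kb)
  phi <- stats::rlnorm(ng, config$phi_meanlog, config$phi_sdlog)

  groups <- config$groups
  line_sets <- lapply(config$line_effects, resolve_effect_genes, gene_ids = gene_ids)
  treat_sets <- lapply(config$treatment_effects, resolve_effect_genes, gene_ids = gene_ids)

  # per-group generative parameters
  truth_genes <- purrr::pmap_dfr(groups, function(line, treatment, n_cells, replicate) {
    rpkm_g <- base_rpkm
    phi_g <- phi
    mean_fold <- rep(1, ng)
    cv_fold <- rep(1, ng)
    apply_effect <- function(eff, members) {
      idx <- match(members, gene_ids)
      mean_fold[idx] <<- mean_fold[idx] * (eff$mean_fold %||% 1)
      cv_fold[idx] <<- cv_fold[idx] * (eff$cv_fold %||% 1)
    }
    if (line %in% names(line_sets)) {
      apply_effect(config$line_effects[[line]], line_sets[[line]])
    }
    if (treatment %in% names(treat_sets)) {
      apply_effect(config$treatment_effects[[treatment]], treat_sets[[treatment]])
    }
    rpkm_g <- rpkm_g * mean_fold
    mu_g <- rpkm_g * len_kb * config$depth / 1e6
    # re-solve phi for the requested CV fold: CV^2 = 1/mu + phi
    shift <- cv_fold != 1
    if (any(shift)) {
      target <- cv_fold[shift]^2 * (1 / mu_g[shift] + phi_g[shift])
      phi_g[shift] <- pmax(0, target - 1 / mu_g[shift])
    }
    in_line <- gene_ids %in% lookup_set(line_sets, line)
    in_treat <- gene_ids %in% lookup_set(treat_sets, treatment)
    tibble::tibble(gene = gene_ids, line = line, treatment = treatment,
                   replicate = replicate,
                   true_rpkm = rpkm_g, true_mu = mu_g, phi = phi_g,
                   mean_fold = mean_fold, cv_fold = cv_fold,
                   in_line_set = in_line, in_treatment_set = in_treat)
  })

  cell_meta <- purrr::pmap_dfr(groups, function(line, treatment, n_cells, replicate) {
    tibble::tibble(line = line, treatment = treatment, replicate = replicate,
                   idx = seq_len(n_cells))
  })
  n_cells <- nrow(cell_meta)
  cell_ids <- sprintf("C%03d", seq_len(n_cells))
  depth_factor <- stats::rlnorm(n_cells, 0, config$depth_sdlog)
  outlier <- rep(FALSE, n_cells)
  if (config$n_outlier_cells > 0) {
    if (config$n_outlier_cells > n_cells) stop("more outliers than cells", call. = FALSE)
    outlier[sample.int(n_cells, config$n_outlier_cells)] <- TRUE
  }

  counts <- matrix(0L, nrow = ng, ncol = n_cells,
                   dimnames = list(gene_ids, cell_ids))
  grp_key <- paste(cell_meta$line, cell_meta$treatment, cell_meta$replicate)
  truth_key <- paste(truth_genes$line, truth_genes$treatment, truth_genes$replicate)
  drop_p <- config$dropout_max * exp(-base_rpkm / config$dropout_scale)
  for (key in unique(grp_key)) {
    cols <- which(grp_key == key)
    tg <- truth_genes[truth_key == key, ]
    mu <- tg$true_mu
    phig <- tg$phi
    for (j in cols) {
      m <- mu * depth_factor[j]
      x <- ifelse(phig > 0,
                  stats::rnbinom(ng, mu = m, size = 1 / phig),
                  stats::rpois(ng, m))
      keep <- stats::rbinom(ng, 1L, 1 - drop_p)
      counts[, j] <- as.integer(x * keep)
    }
  }

  sp <- config$spikein_copies
  sp_counts <- matrix(0L, nrow = length(sp), ncol = n_cells,
                      dimnames = list(names(sp), cell_ids))
  for (j in seq_len(n_cells)) {
    lambda <- sp * config$spikein_efficiency * depth_factor[j]
    if (outlier[j]) lambda <- lambda * config$outlier_distortion
    sp_counts[, j] <- stats::rpois(length(sp), lambda)
  }

  mat <- count_matrix(rbind(counts, sp_counts), is_spikein = names(sp))
  metadata <- tibble::tibble(cell = cell_ids, line = cell_meta$line,
                             treatment = cell_meta$treatment,
                             replicate = cell_meta$replicate)
  truth_cells <- dplyr::mutate(metadata, depth_factor = depth_factor,
                               outlier = outlier)
  list(matrix = mat,
       metadata = metadata,
       spikein_spec = tibble::tibble(spikein = names(sp), copies = unname(sp)),
       gene_lengths = tibble::tibble(gene = gene_ids, length = lengths),
       truth = list(genes = truth_genes, cells = truth_cells))
}

#' Write all simulation artifacts to a directory
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_count_matrix(sim$matrix, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$metadata, file.path(dir, "cells.tsv"))
  readr::write_tsv(sim$spikein_spec, file.path(dir, "spikeins.tsv"))
  readr::write_tsv(sim$gene_lengths, file.path(dir, "gene_lengths.tsv"))
  readr::write_tsv(sim$truth$genes, file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(sim$truth$cells, file.path(dir, "truth_cells.tsv"))
  invisible(dir)
}

#' Published per-gene expression summaries for five cancer-related genes
#'
#' Mean and standard deviation of single-cell rpkm for EGFR, RET, MYC, KRAS
#' and TP53 across five lung adenocarcinoma cell populations (LC2/ad, an
#' independent LC2/ad replicate, the vandetanib-resistant derivative
#' LC2/ad-R, PC-9 and VMRC-LCD), as printed in the source study. Used as a
#' worked-example fixture for the relative-divergence arithmetic: e.g. the
#' relative divergence of EGFR is 14/13 in LC2/ad versus 34/56 in PC-9, a
#' 1.8-fold narrowing in the EGFR-mutant line.
#'
#' @return A tibble with columns `gene`, `line`, `mean`, `sd`.
#' @export
table2_fixture <- function() {
  lines <- c("LC2/ad", "LC2/ad (rep)", "LC2/ad-R", "PC-9", "VMRC-LCD")
  vals <- list(
    EGFR = list(mean = c(13, 17, 12, 56, 0.03),    sd = c(14, 15, 14, 34, 0.1)),
    RET  = list(mean = c(1.9, 2.0, 1.6, 0.005, 1.0), sd = c(5, 4, 5, 0.015, 7)),
    MYC  = list(mean = c(99, 84, 179, 23, 0.05),   sd = c(117, 95, 123, 23, 0.2)),
    KRAS = list(mean = c(29, 27, 17, 21, 26),      sd = c(17, 19, 14, 15, 19)),
    TP53 = list(mean = c(22, 25, 105, 126, 14),    sd = c(15, 14, 94, 43, 9)))
  purrr::imap_dfr(vals, function(v, g) {
    tibble::tibble(gene = g, line = lines, mean = v$mean, sd = v$sd)
  })
}
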