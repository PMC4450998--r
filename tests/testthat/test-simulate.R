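test_that("the same seed reproduces the simulation bit for bit", {
  cfg <- sim_config(n_genes = 200, seed = 9,
                    groups = tibble::tibble(line = "L", treatment = "none",
                                            n_cells = 10),
                    n_outlier_cells = 2)
  a <- simulate_counts(cfg)
  b <- simulate_counts(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_identical(a$truth$cells, b$truth$cells)
})

test_that("degenerate config (no dispersion, no noise) gives CV 0 everywhere", {
  cfg <- sim_config(n_genes = 20, depth = 1e4, depth_sdlog = 0,
                    phi_meanlog = -Inf, phi_sdlog = 0, dropout_max = 0,
                    groups = tibble::tibble(line = "L", treatment = "none",
                                            n_cells = 8),
                    seed = 1)
  # Poisson noise remains in counts; the degenerate limit is checked on the
  # generative law itself: zero dispersion means variance = mean (Poisson)
  sim <- simulate_counts(cfg)
  expect_true(all(sim$truth$genes$phi == 0))
  # and a fully deterministic matrix arises when means are large enough that
  # CV -> 0: top genes should have empirical CV << 1
  tab <- divergence_table(compute_rpkm(sim$matrix, sim$gene_lengths))
  top <- dplyr::slice_max(tab, mean, n = 3)
  expect_true(all(top$cv < 0.1))
})

test_that("negative-binomial counts match the mu + phi*mu^2 variance law", {
  # single-gene config: the simulated mean equals `depth` exactly
  cfg <- sim_config(n_genes = 1, depth = 10, depth_sdlog = 0,
                    phi_meanlog = log(0.5), phi_sdlog = 0, dropout_max = 0,
                    groups = tibble::tibble(line = "L", treatment = "none",
                                            n_cells = 10000),
                    seed = 31)
  sim <- simulate_counts(cfg)
  x <- as.numeric(sim$matrix$counts[1, ])
  expect_equal(mean(x), 10, tolerance = 0.05)
  expect_equal(var(x), 10 + 0.5 * 100, tolerance = 0.10)
})

test_that("rank-mean profile follows the configured power law", {
  cfg <- sim_config(n_genes = 1000, zipf_exponent = 1, seed = 5)
  sim <- simulate_counts(cfg)
  tg <- sim$truth$genes
  fit <- stats::lm(log(true_rpkm) ~ log(seq_along(true_rpkm)), data = tg)
  expect_equal(unname(stats::coef(fit)[2]), -1, tolerance = 0.1)
})

test_that("spike-in expected counts are linear in input copies", {
  sim <- simulate_counts(sim_config(n_genes = 50, seed = 21,
    groups = tibble::tibble(line = "L", treatment = "none", n_cells = 200)))
  sp <- sim$matrix$counts[sim$matrix$is_spikein, ]
  means <- rowMeans(sp)
  copies <- sim$spikein_spec$copies[match(rownames(sp), sim$spikein_spec$spikein)]
  fit <- stats::lm(means ~ copies)
  expect_gt(summary(fit)$r.squared, 0.999)
  # ratio of channel means tracks the ratio of copies
  expect_equal(means[which.max(copies)] / means[which.min(copies)],
               max(copies) / min(copies), tolerance = 0.1,
               ignore_attr = TRUE)
})

test_that("with constant dispersion, CV decreases with the mean across genes", {
  sim <- simulate_counts(sim_config(n_genes = 2000, phi_sdlog = 0,
    phi_meanlog = log(0.3), dropout_max = 0, seed = 13, depth = 5e4,
    groups = tibble::tibble(line = "L", treatment = "none", n_cells = 60)))
  tab <- divergence_table(compute_rpkm(sim$matrix, sim$gene_lengths))
  # expected CV^2 = 1/mu + phi: the mean-dependence lives where the Poisson
  # term matters, so test the sampling-noise-dominated range (mu < 50 tags);
  # above it the curve plateaus at sqrt(phi) and ranks are pure noise
  tg <- sim$truth$genes
  low <- tg$gene[tg$true_mu < 50]
  ok <- tab$gene %in% low & is.finite(tab$cv) & tab$mean > 0
  expect_lt(stats::cor(tab$mean[ok], tab$cv[ok], method = "spearman"), -0.5)
  # and the generative law itself is monotone over all genes
  true_cv <- with(tg, sqrt(1 / true_mu + phi))
  expect_true(all(diff(true_cv[order(tg$true_mu)]) <= 0))
})

test_that("planted high-CV genes exceed expression-matched non-planted genes", {
  planted <- sprintf("G%04d", seq(100, 590, by = 10))  # 50 well-expressed genes
  sim <- simulate_counts(sim_config(
    groups = tibble::tibble(line = "L", treatment = "t", n_cells = 50),
    treatment_effects = list(t = list(genes = planted, cv_fold = 2)),
    n_genes = 2000, seed = 17))
  tab <- divergence_table(compute_rpkm(sim$matrix, sim$gene_lengths))
  tab <- dplyr::filter(tab, is.finite(cv))
  other <- dplyr::filter(tab, !gene %in% planted)
  wins <- vapply(planted, function(g) {
    mu <- tab$mean[tab$gene == g]
    partner <- other$gene[which.min(abs(log(other$mean) - log(mu)))]
    tab$cv[tab$gene == g] > tab$cv[tab$gene == partner]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("planted mean folds are recorded and realised in the truth table", {
  planted <- c("G0010", "G0020")
  sim <- simulate_counts(sim_config(n_genes = 100, seed = 2,
    groups = tibble::tibble(line = c("A", "B"), treatment = "none",
                            n_cells = 5),
    line_effects = list(B = list(genes = planted, mean_fold = 4))))
  tg <- sim$truth$genes
  a <- dplyr::filter(tg, line == "A", gene %in% planted)
  b <- dplyr::filter(tg, line == "B", gene %in% planted)
  expect_equal(b$true_rpkm / a$true_rpkm, c(4, 4))
  expect_true(all(b$in_line_set))
})

test_that("simulation artifacts round-trip through their on-disk formats", {
  sim <- simulate_counts(sim_config(n_genes = 40, seed = 8,
    groups = tibble::tibble(line = "L", treatment = "none", n_cells = 6)))
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  cm <- read_count_matrix(file.path(dir, "counts.tsv"),
                          spikein_spec = read_spikein_spec(file.path(dir, "spikeins.tsv")))
  expect_identical(cm$counts, sim$matrix$counts)
  expect_identical(cm$is_spikein, sim$matrix$is_spikein)
  meta <- read_cell_metadata(file.path(dir, "cells.tsv"))
  expect_equal(meta$cell, sim$metadata$cell)
  lens <- read_gene_lengths(file.path(dir, "gene_lengths.tsv"))
  expect_equal(lens$length, sim$gene_lengths$length)
})

test_that("published five-gene expression fixture holds the printed values", {
  fx <- table2_fixture()
  pick <- function(g, l) unlist(fx[fx$gene == g & fx$line == l, c("mean", "sd")])
  expect_equal(pick("EGFR", "PC-9"), c(mean = 56, sd = 34))
  expect_equal(pick("KRAS", "VMRC-LCD"), c(mean = 26, sd = 19))
  expect_equal(pick("TP53", "LC2/ad-R"), c(mean = 105, sd = 94))
  expect_equal(pick("EGFR", "LC2/ad"), c(mean = 13, sd = 14))
  expect_equal(pick("MYC", "LC2/ad"), c(mean = 99, sd = 117))
  expect_identical(dim(fx), c(25L, 4L))  # 5 genes x 5 cell populations
})

test_that("invalid simulation configs are rejected", {
  expect_error(sim_config(groups = tibble::tibble(line = "L", treatment = "n",
                                                  n_cells = 0)), "empty")
  expect_error(sim_config(depth = -5), "negative")
  expect_error(sim_config(spikein_copies = c(A = 0)), "positive")
})
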