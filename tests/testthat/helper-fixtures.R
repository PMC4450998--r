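# small in-code fixtures shared across test files

tiny_counts <- function(vals = c(1, 3, 2, 4), genes = c("G1", "G2"),
                        cells = c("C1", "C2"), spikeins = NULL) {
  count_matrix(matrix(vals, nrow = length(genes),
                      dimnames = list(genes, cells)),
               is_spikein = spikeins)
}

# exact two-sided Fisher p by exhaustive enumeration over all 2x2 tables
# with the observed margins (probability-mass rule); independent of
# stats::fisher.test and of the package code under test
brute_fisher_p <- function(a, b, c, d) {
  r1 <- a + b
  c1 <- a + c
  n <- a + b + c + d
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  prob <- vapply(ks, function(k) {
    exp(lchoose(c1, k) + lchoose(n - c1, r1 - k) - lchoose(n, r1))
  }, numeric(1))
  obs <- prob[ks == a]
  sum(prob[prob <= obs * (1 + 1e-7)])
}

uniform_lengths <- function(counts, length = 1000L) {
  tibble::tibble(gene = genes(counts), length = length)
}

compute_rpkm_from <- function(sim) compute_rpkm(sim$matrix, sim$gene_lengths)
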