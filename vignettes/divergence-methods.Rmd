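---
title: "Measuring and testing cell-to-cell expression divergence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and testing cell-to-cell expression divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scdiverge)
```

## The statistic

For a gene $g$ measured in $n$ cells, `scdiverge` summarises expression by
the mean rpkm $\bar{x}_g$, the sample standard deviation $s_g$ (with the
$n-1$ denominator, for small-$n$ correctness), and the **relative
divergence**

$$\mathrm{CV}_g = s_g / \bar{x}_g,$$

the coefficient of variation of rpkm across cells. A gene whose mean is
zero has no defined CV; such genes are flagged `NA`, never coerced to 0.
rpkm is computed as count / (kb × million mapped tags); by default the
per-cell denominator is the total of gene-assigned, non-spike-in tags,
which makes the identity $\sum_g \mathrm{rpkm}_{gc}\,\ell_g = 10^6$ hold
exactly per cell ($\ell_g$ in kb) and keeps the pipeline self-contained
given only a count matrix. An externally supplied all-mapped-tags
denominator is available through the `denominator` switch for data where
intergenic tags should count.

The CV is a useful but imperfect summary: a gene expressed in only half
the cells can have a large CV purely from its on/off pattern, so single
extreme subpopulations inflate it. It is, however, scale-free
(invariant to multiplying a gene's expression by any constant), which is
what makes cross-gene and cross-condition comparisons meaningful.

## Why expression-matched controls

Under a negative-binomial count model with mean $\mu$ and dispersion
$\varphi$,

$$\mathrm{CV}^2 \approx 1/\mu + \varphi:$$

lowly expressed genes have large CVs simply because tag sampling noise
dominates, and the curve plateaus at $\sqrt{\varphi}$ once $1/\mu$ is
negligible. Comparing CVs across genes with different means therefore
confounds biology with depth. The test implemented here never compares a
gene against the transcriptome at large: its null is formed from
**expression-matched controls** — other genes whose mean lies within a
two-fold window (closed interval, so boundary ties behave
deterministically). When more than 1,000 genes qualify, exactly 1,000 are
sampled uniformly without replacement, reproducibly from the configured
seed. A gene with no eligible controls, fewer than 10 usable controls, or
an all-zero control background is reported untestable rather than forced
through the test.

## The divergence test

The named test statistic is a variance ratio,

$$F_g = \mathrm{CV}_g^2 \,/\, \mathrm{median}_{g' \in \mathrm{ctrl}}
\mathrm{CV}_{g'}^2,$$

referred to the $F(n-1,\,n-1)$ distribution, two-sided:
$p = 2\min\{P[F \ge F_g],\, P[F \le F_g]\}$, capped at 1. The choices
here were genuinely open and deserve justification:

- **Median, not mean, of the control CV²** — the control background mixes
  genes with heterogeneous dispersions and is right-skewed; the median is
  a robust centre and makes a single wild control harmless.
- **$(n-1, n-1)$ degrees of freedom** — the gene's CV² estimate carries
  roughly the uncertainty of a variance estimated from $n$ cells, while
  the control median (typically over hundreds of genes) is nearly fixed.
  The reference distribution is therefore approximate, and deliberately
  slightly wide. Its actual operating characteristics are measured, not
  assumed: on an identically distributed null (Gaussian per-cell
  expression, equal means, 50 cells, 2,500 genes) the empirical rejection
  rate at $\alpha = 0.05$ lands in the 0.05–0.07 range (the acceptance
  script recomputes it on every run). The null's true CV is set to 0.8
  because that is the regime the test operates in: relative divergences
  of well-expressed genes plateau a little below 1. The calibration is
  CV-dependent — at small true CV the ratio statistic is narrower than
  the $F$ reference and the test turns conservative — which is another
  reason genes are compared only within an expression window.
- **Two-sided** — both unusually diverse and unusually uniform genes are
  of interest; the direction label (`more` / `less`) is the side of
  $F_g = 1$.
- **No multiple-testing correction by default** — divergent-gene lists
  are selected at raw $P < 0.05$; a Benjamini–Hochberg option exists
  (`adjust = "BH"`) but is off by default so that list sizes remain
  comparable with threshold-based selections.
- An **empirical-percentile alternative** (`method = "empirical"`, the
  two-sided rank of the gene's CV among its controls) is provided for
  users who prefer no distributional reference at all; it is less
  powerful at the default control-set sizes.

Genes enter testing only above a mean of 5 rpkm (configurable). Below
that floor, CV estimates are dominated by sampling noise at typical
depths, and fold-change analyses become pseudocount-driven.

## Enrichment, condition comparisons and responders

Enrichment of the more/less-diverse lists in gene sets (GMT input) uses
Fisher's exact test, two-sided by the probability-mass rule, over a
universe consisting of the *testable* genes — genes that never entered
the divergence test cannot meaningfully deplete a pathway. The exact
p-values are verified in the test suite against brute-force enumeration
of all 2×2 tables with the observed margins.

Condition comparisons report per-gene mean fold changes
$(\bar{x}_B + c)/(\bar{x}_A + c)$ with a pseudocount $c = 0.1$ rpkm
(well below the 5 rpkm eligibility floor, so it only tames zeros), and CV
fold changes $\mathrm{CV}_B/\mathrm{CV}_A$ left unregularised — a zero or
undefined CV makes the ratio undefined rather than silently shrunk.
Eligibility requires a mean above 5 rpkm in *at least one* condition, so
strong on/off switches remain visible. Responders are genes with mean
fold change strictly above 2 (induced) or strictly below 1/2 (repressed);
the strict inequality makes behaviour at the boundary deterministic.

## Spike-in quality control

Each cell is judged per spike-in channel by a leave-one-out z-score on
the $\log_{10}(\mathrm{count}+1)$ scale (spike-in counts span orders of
magnitude; a linear mode is retained as an option), and discarded when
any channel exceeds 2 SD. Leave-one-out means the cell under scrutiny
never contaminates its own reference. The filter runs once — no
iteration — and is monotone in the threshold. When the other cells are
exactly constant the z-score is defined as 0 on agreement and infinite
otherwise; near-degenerate variances are snapped to zero with a relative
tolerance so floating-point dust cannot manufacture infinite scores.

## The simulator and what it does (and does not) emulate

`simulate_counts()` draws counts per gene × cell from a negative binomial
with gene-specific mean and dispersion, then applies extra dropout for
lowly expressed genes. Its defaults describe the kind of experiment the
pipeline targets; they were fixed once, up front:

| knob | default | why |
|---|---|---|
| genes | 5,000 | enough to populate all five expression strata |
| cells per group | 46 | a typical single-capture library count |
| mean profile | power law over ranks, exponent 1.3 | Zipf-like decay; over a 5,000-gene detected set this exponent spans ~2–2,000 rpkm, matching the analysed dynamic range |
| depth | 5 × 10⁵ tags/cell, log-normal factor sdlog 0.25 | desk-scale stand-in for multi-million-tag libraries; library-size variation of the expected magnitude |
| dispersion $\varphi$ | log-normal, median 0.4, sdlog 0.6 | produces the observed CV plateau near 1 for the most dispersed well-expressed genes |
| dropout | $0.3\,e^{-\mathrm{rpkm}/5}$ | extra zeros for lowly expressed genes only |
| spike-ins | 3 channels, 10³/10⁴/10⁵ copies, 5% efficiency | expected counts linear in copies; the smallest channel still averages ~50 tags so QC is not Poisson-limited |
| outliers | spike-in expectations × 10 | distort spike-ins *only*, so QC validation is independent of the biology |

CV shifts requested for planted gene sets are realised by re-solving the
dispersion for the target CV, floored at the Poisson limit
$\varphi = 0$ — a requested CV below $\sqrt{1/\mu}$ is not reachable
within the count model, and the truth table records what was actually
applied. Replicate experiments are emulated as two cell groups inside
one simulation: they share every gene-level parameter and differ only in
the cells drawn, which is what makes replicate CV correlations high
(~0.77 at 40+40 cells) while two simulations from different seeds share
only the mean profile.

The simulator does *not* emulate: amplification bias shared between
genes, cell-cycle structure, bursty transcription beyond what a
negative binomial captures, UMIs, batch effects, or correlated gene
modules (beyond the planted effect sets). Tests passing on simulated
data therefore demonstrate the estimators' correctness under the stated
model, not robustness to every artefact of real libraries. One stated
degenerate case is unreachable by construction: "zero dispersion, zero
noise implies identical cells" holds for the generative *law* (the truth
table shows $\varphi = 0$), but sampled counts retain Poisson noise —
the test suite checks the law and the vanishing-CV limit instead.

## Saturation analyses

Depth dependence is probed by binomial thinning: each cell's counts are
kept independently with probability $p_c = \mathrm{target}/\mathrm{depth}_c$,
which preserves relative expression in expectation and has the same
first-moment behaviour as re-sequencing at lower depth (the historical
protocol subsampled reads; a count matrix admits exactly this
surrogate). Cells already below the target are kept unthinned and
flagged. Expression strata (1–5, 5–10, 10–50, 50–100, 100–500 rpkm) are
assigned at full depth and frozen across the grid so stratum migration
cannot bend the curves. Cell-number dependence subsamples cells without
replacement, 20 replicates by default, reporting the across-replicate
spread of the CV estimate — the quantity whose stabilisation indicates a
sufficient cell count. Default problem sizes throughout (5,000 genes,
tens of cells, 5-point grids) keep any analysis in seconds while leaving
every stratum populated.

## Clustering and PCA

Cells are clustered on $\log_{10}(\mathrm{rpkm}+0.01)$-transformed,
per-gene standardized values of a chosen gene panel: Euclidean distance,
complete linkage — deliberately plain, declared choices rather than
inferences about any particular published figure, since transformation,
distance and linkage are rarely stated in the literature this package
serves. $K$ defaults to the number of distinct cell groups under
comparison. Purity (fraction of cells in clusters whose majority label
matches their own) is always reported against a label-permutation
baseline, because purity without a chance level is uninterpretable. PCA
uses the same transform without standardization (per-gene centering
only) and fixes each component's sign by making its largest-magnitude
loading positive, so embeddings are reproducible across platforms; the
$\varepsilon = 0.01$ rpkm offset sits two orders of magnitude below the
expression floor and only keeps zeros finite.

## Numerical and degenerate-input conventions

- Counts must be non-negative integers; violations are reported with the
  offending gene and cell, never coerced.
- A cell with zero library size cannot be normalised: dropped with a
  warning, not an error, so one empty well does not kill a run.
- A gene missing from the length annotation is a hard error — silent
  drops change every downstream denominator.
- GTF gene lengths are exon-interval unions per `gene_id` (merged, not
  summed; strand ignored), the standard single-number-per-gene
  convention when the defining isoform is unknown.
- All stochastic steps (control subsampling, thinning, subsampling,
  permutation baselines, the simulator) take explicit seeds; identical
  seeds give bit-identical results.

## Known limitations

- The F reference for the divergence test is approximate (see above);
  its calibration is verified empirically at the shipped defaults, and
  users changing `n_cells` regimes drastically should re-examine it.
- The CV conflates on/off heterogeneity with graded variability.
- Enrichment assumes gene sets are meaningful subsets of the testable
  universe; sets emptied by the universe intersection are skipped.
- The per-set "average P" style of summary sometimes seen in the
  literature is not reproduced; one exact p per (set, list) pair is
  reported.
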