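---
title: "Detecting and imputing dropout zeros in single-cell RNA-seq"
author: "scDropImpute"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and imputing dropout zeros in single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scDropImpute)
```

## The problem

Single-cell RNA-seq matrices are dominated by zeros, and a large part
of them are not biological: low capture efficiency and stochastic
amplification silence genes that the cell actually expressed
(*dropout* events). Overall missing rates around 30% are common even
after noise reduction. Any imputation method therefore faces three
questions in order: *where* is data missing, *how much* is missing,
and *what* were the values. Imputing all zeros indiscriminately
destroys real biological zeros; this package instead detects dropout
positions with high specificity first and only then imputes.

The pipeline has three stages:

1. **Detection** — a large linear classifier trained element-wise on
   richly expressed (housekeeping) genes proposes candidate dropout
   positions among the zeros.
2. **Refinement** — candidates are intersected with two independent
   detectors: a zero-inflated Poisson/negative-binomial mixture over
   cell pairs (ZIM) and per-cell false-negative detection curves
   (FNC), each thresholded at a data-derived fraction $\eta$.
3. **Imputation** — a linear support vector regression (SVR), trained
   on the same element-wise samples with value labels, fills the
   surviving positions.

## Element-wise problem modeling

Let $X$ be the genes $\times$ cells matrix, $m$ genes, $n$ cells.
Genes are split into a richly expressed set (housekeeping genes,
expected to be detected in essentially every cell) and the remaining
non-richly expressed set. Every element $x[i,j]$ becomes one sample
whose features are the same gene's values at the other $n-1$ cells
(matrix cell order with the sample's own cell deleted) and whose
label is $\mathrm{sgn}(x[i,j])$: $+1$ if observed, $-1$ if zero. The
richly expressed genes supply $m_r \times n$ training samples — their
zeros are, by assumption, dropouts, which is exactly the label
noise the classifier is meant to capture — and the non-richly
expressed genes supply the test set. A zero test element predicted
positive ("this gene should have been observed here") is a candidate
dropout.

The classifier minimizes
$$\min_w \tfrac12 w^Tw + C\sum_i \xi(w; s_i, y_i)$$
with either the logistic loss (L2-regularized logistic regression) or
the squared hinge loss (L2-loss SVM). The smooth primal problems are
solved with L-BFGS; liblinear-style dual coordinate descent is
available for the SVM and is used for the SVR variants whose primal
is not smooth. The bias is an augmented constant feature and is
therefore regularized, the standard liblinear convention; the label
translation-equivariance of the SVR consequently holds exactly only
in the large-$C$ limit, which the tests exercise. An exactly-zero
decision value is classified $-1$: the pipeline never flags a
position without positive evidence.

## The threshold $\eta$

The refinement detectors produce *probability matrices*, not calls,
so a cutoff is needed. $\eta$ is computed from the classifier: the
number of zero test elements predicted positive divided by the number
of zero test elements. Each probability detector then contributes its
$\lceil \eta D \rceil$ highest-scoring available zero elements ($D$ =
elements it scored), with ties broken deterministically by (gene,
cell) index. The classifier's own candidate set is its
positive-predicted zeros — it is not re-thresholded. The final call
set is the strict intersection; a lenient mode (per-element
intersection over covering detectors only) exists as an escape hatch
for sparse ZIM coverage.

## Zero-inflated mixture (ZIM)

For a pair of cells $(c_i, c_j)$ from the same subpopulation, each
gene's counts $(r_i, r_j)$ follow a three-component mixture:
dropout in $c_i$ ($r_i \sim \mathrm{Pois}(\lambda_0)$, $r_j \sim$ NB),
amplified (both NB), and dropout in $c_j$ (symmetric), with
background rate $\lambda_0 = 0.1$ by default. The mixture weights
are a three-class softmax in the mixing covariate
$m = \log(r_i + 1) + \log(r_j + 1)$ — the pseudocount is needed
because zero counts, the object of interest, would otherwise have an
undefined covariate. The model is fitted by EM.

Two parameterization choices were genuinely open and are recorded
here:

* **NB means.** The amplified mean for each side is a pair-level
  expected magnitude $e_g$ — the mean of the pair's library-size
  normalized positive counts — scaled back by each cell's library
  factor. When one side is zero this reduces exactly to the
  counterpart cell's scaled count, i.e. the natural "what this gene
  should look like if amplified" reference.
* **Dispersion.** A single dispersion $\theta$ is shared by all NB
  terms of a pair and updated inside EM by direct coordinate
  maximization of the expected complete-data log-likelihood (located
  on a deterministic gene subsample, then accepted only if it
  improves the full-data objective). Together with the guarded
  softmax update this makes every EM step a generalized EM step, so
  the log-likelihood trace is monotone non-decreasing — a property
  the tests assert on every fitted pair.

Genes whose posterior argmax is "amplified" in at least 20% of the
pair comparisons within a subpopulation form the amplified set; only
their zero elements receive ZIM probabilities. The per-element
probability is the mean, over all fitted pairs involving the cell, of
the dropout-in-that-cell posterior. The mean was chosen over max/vote
because it is the natural Monte-Carlo estimate of the cell-level
dropout posterior under random pair sampling. ZIM requires count-like
data and refuses RPKM input unless forced, since the Poisson/NB laws
have no meaning on normalized values.

All pairs within a subpopulation are fitted when feasible; above
`pairBudget` (default 100 per subpopulation) a seeded random sample
of pairs is used. The per-element aggregation is a mean over the
pairs involving each cell — with 100 pairs over, say, 100 cells each
cell is still covered by several pairs, and in practice the
aggregated posteriors stabilize well below full enumeration, which is
$O(n^2)$ and quickly dominates runtime. Full enumeration remains
available with `pairBudget = Inf`.

## False-negative curves (FNC)

Housekeeping genes are near-ubiquitously expressed, so their zeros
measure each cell's technical detection efficiency. Per gene, the
expected expression conditioned on detection is
$\mu^*_g$ = mean of the gene's nonzero values across all cells (a
per-subpopulation $\mu^*$ is not computed by default; "mean of
nonzeros over all cells" is the simplest operational reading and is
recorded as this package's interpretation, with the covariate on the
natural-log scale because expression spans decades). Per cell $c$, a
logistic regression of the housekeeping detection indicator on
$\log \mu^*$ gives the detection curve $F_c(\mu)$, and
$1 - F_c(\mu^*_g)$ is the missing probability of any zero element.
Cells whose housekeeping genes are all detected (or none), have
fewer than 5 usable points, or separate perfectly get a degenerate
constant curve at the observed detection rate clipped to
$[0.01, 0.99]$ rather than infinite slopes.

## Imputation

The SVR minimizes
$$\min_w \tfrac12 w^Tw + C\sum_i \max(0, |y_i - w^Tx_i| - \varepsilon)^p$$
with $p \in \{1, 2\}$, trained on the richly expressed genes'
element-wise samples with the element's own (normalized) expression
as label. Three variants are available — the $p=1$ dual, and the
$p=2$ primal and dual (the smooth $p=2$ primal is the default; primal
and dual agree in objective, which the tests check via the duality
gap). Predictions at the final missing positions are clamped at zero;
no observed nonzero value is ever modified, and an element-wise
report is attached to the imputed matrix. A mean-smoothing baseline
along a supplied cell ordering (trajectory) imputes each missing
element from the up-to-$\gamma$ preceding and following cells
($\gamma = 3$ by default, windows truncated at the ends, zeros
included in the window mean unless excluded by flag); the package
does not compute trajectories itself.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `C` | 1 (presets: 2 SVM / 104.858 LR) | classifier penalty; class imbalance is left to `C`, no resampling |
| `svrC`, `svrP`, `svrEpsilon` | 1, 2, 0.1 | SVR penalty, loss exponent, insensitivity (expression units) |
| `tol`, `maxIter` | 1e-4, 1000 | relative objective tolerance; non-convergence warns, never fails |
| `lambda0` | 0.1 | Poisson background rate of the dropout component (counts) |
| `amplifiedThreshold` | 0.2 | amplified-set fraction of pair comparisons |
| `pairBudget` | 100 | ZIM pairs per subpopulation |
| `etaOverride` | NULL | fix $\eta$ instead of deriving it from the classifier |
| `gamma` | 3 | baseline smoother half-window (cells) |

The presets `pipelinePresets()` bundle the settings published for the
two dataset scales the method was demonstrated on (an FDR-filtered
CML stem-cell matrix without raw counts, where the ZIM detector is
unavailable and the intersection falls back to classifier + FNC; and
a mouse cortex/hippocampus UMI matrix).

## The synthetic-data generator

Every statistical claim in the test suite is made against seeded
synthetic data with known ground truth, generated to match the
assumptions of the detectors: true expression is negative binomial
(gene means log-uniform over [2, 200], shared dispersion 2,
group-specific log-normal shifts for 30% of genes across 3
subpopulations); detection is per-cell logistic in log true
expression (slope 0.6, per-cell intercept jitter 0.3) so that dropout
is expression- and cell-dependent; dropped entries become 0 or a
Poisson(0.1) background count; housekeeping genes (100 of 2,000) are
drawn from the top quartile of the mean range with an extra detection
offset (+1.5 logits), making them near-ubiquitously detected. The
default intercept (-0.87) puts the overall dropout fraction near 30%,
the missing rate regime the method targets. Sub-seeds are derived per
stage so that changing one stage never shifts another's draws.

What the generator does *not* emulate: batch effects, doublets,
ambient RNA, UMI saturation, and gene-gene correlation beyond the
group structure. Passing tests therefore show that each component
recovers the structure it models and that the ensemble refines
precision under those assumptions — not that the method is robust to
every artifact of real data.

## Numerical choices and degenerate inputs

* `sign(0) = -1` everywhere a decision value is thresholded.
* Candidate ranking ties break by (gene, cell) ascending, so runs are
  byte-reproducible at fixed seed.
* EM: tolerance 1e-6 relative log-likelihood, at most 100 iterations,
  responsibilities initialized from the hard rule count < 1 →
  dropout side; seeds affect only pair subsampling.
* A cell with no nonzero gene is a hard error for ZIM (degenerate
  pair); all-zero genes are excluded from $\mu^*$ with a warning.
* The missing-rate denominator is the full matrix size.

## Problem sizes in the test suite

Unit tests run on matrices up to a few hundred genes and tens of
cells; statistical acceptance checks use the default generator
conditions (2,000 x 300, ten seeds for the ensemble-refinement and
imputation-error claims, with cross-validation disabled inside the
ten-seed loop since it re-fits the same classifier five more times
per seed without affecting the quantities under test), a 2,000-gene
cell pair for mixture recovery, and 400-gene cells for detection
curve recovery. The published sample-count arithmetic
(41,876/215,992 and 1,220,030/58,795,830 samples with 3,004
features) is checked on sparse shell matrices of exactly the
published dimensions, since the counts depend on dimensions alone.

## Known limitations

* FNC scores depend on the element only through $\mu^*$ and the
  cell's curve, and they *decrease* in $\mu^*$: the score is the
  prior probability that a gene of that magnitude drops out, not the
  posterior that an observed zero is technical. Biological zeros
  concentrate at weakly expressed genes, which therefore receive the
  highest FNC scores — on its own, FNC cannot separate them from
  dropouts, which is precisely why it enters the ensemble only
  through the intersection with the classifier and the mixture
  model. The tests assert the mechanism FNC does guarantee
  (monotonicity in $\mu^*$, higher scores in lower-efficiency cells)
  rather than a dropout-vs-biological separation it cannot provide.
* The classifier's feature space concatenates genes of very
  different scales; no per-gene scaling is applied, which follows the
  element-wise model exactly but means high-expression genes dominate
  the margin. A per-sample scaling option exists and defaults off.
* ZIM coverage is limited to the amplified gene set; under strict
  intersection, uncovered elements cannot be called (use `lenient`
  to relax).
* The SVR is trained on housekeeping genes, whose expression is
  higher than average; imputed values for weakly expressed genes
  inherit a linear extrapolation from that regime.
* $\eta$ is a single global fraction; no per-cell or per-gene
  threshold is attempted.
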