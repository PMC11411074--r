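---
title: "Analysing multiplex single-cell CRISPRa screens"
author: "crisprascreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multiplex single-cell CRISPRa screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprascreen)
library(Matrix)
```

## The screening design

A multiplex CRISPRa screen introduces a library of guide RNAs into a
population of cells carrying a dCas9-activator, at a high multiplicity of
integration, so that each cell receives a random combination of several
guides. Single-cell RNA-seq with guide-transcript capture then yields, for
every cell, an expression profile and the set of guides it carries. Because
each transcriptome is informative about every guide in that cell, the design
is far more powerful per cell than one-guide-per-cell screens.

The analysis is an iterative partitioning: for each guide, cells are split
into *carriers* (guide assigned) and *controls* (all other cells — including
cells carrying other guides, which is inherent to the multiplex design), and
every gene whose interval overlaps the ±1 Mb window around the guide's target
site is tested for differential expression with a two-tailed Wilcoxon
rank-sum test on log-normalized expression. Non-targeting control (NTC)
guides, which have no genomic site, are run through the identical machinery
against the union of all cis-window genes; their P-values form an empirical
null that absorbs every source of noise the targeting tests are exposed to —
sparsity, ties, detection filtering, multiplexing.

Hit calling converts each targeting raw P-value into an empirical P-value

$$p_{emp} = \frac{\#\{\,p^{NTC} < p_{raw}\,\} + 1}{N_{NTC} + 1},$$

applies Benjamini–Hochberg across the targeting tests only (the NTC rows are
null material, not hypotheses), and flags pairs with adjusted values strictly
below the empirical FDR threshold (default 0.1). The attainable floor of
$p_{emp}$ is $1/(N_{NTC}+1)$, so a small NTC set provably limits
significance; the package warns when fewer than 100 NTC tests are available.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `max_mito_fraction` | 0.10 | fraction | QC ceiling; cells strictly above are removed (0.17 for the neuron-like setting) |
| `min_total_umi` | 4000 | UMIs | QC floor; cells strictly below are removed (1500 for neurons) |
| `assign_min_umi` | 5 | UMIs | capture threshold: a guide is assigned at **≥ 5** UMIs (the "at least" reading of the 5-UMI rule; configurable) |
| `window_radius` | 1e6 | bases | cis-window half-width: a 2 Mb window, the upper estimate of mammalian TAD size |
| `detection_threshold` | 0.002 | fraction | a test runs only if the gene is detected in **strictly more** than 0.2% of carrier *and* control cells |
| `efdr_threshold` | 0.1 | — | hits are `p_adj` strictly below this |
| `scale_factor` | 1e4 | — | normalization: `ln(1 + 1e4 · count / total)` |

Boundary conventions follow the filtering phrasing "greater than … and less
than … were filtered out": QC boundary values are retained, the assignment
and detection comparisons are as marked above, and both the empirical count
(`<`) and the hit rule (`<`) are strict, so a tie with an NTC P-value counts
against significance and `p_adj = 0.1` is not a hit.

## Normalization and fold changes

Expression is normalized as `ln(1 + scale · count / cell_total)`.
`normalize_expression()` defaults to row-sum totals (so the operation is
self-contained and scale-invariant), but the pipeline passes the metadata
total UMIs instead: the analysed matrix covers only the cis-window gene
panel, and normalizing a small panel by its own sum would let one strongly
activated gene depress the normalized values of every other gene in its
window — whole-cell depth is what the original single-cell workflow divides
by.

Fold changes use the de-logged group means with a pseudocount,

$$\mathrm{log2fc} = \log_2(\overline{e^{x}-1}_{carrier} + 1) -
\log_2(\overline{e^{x}-1}_{control} + 1),$$

reproducing the fold-change semantics of the common single-cell toolkits.
One consequence worth knowing: when `scale · count / total` is of order 1 —
e.g. a gene at 0.5–1.5 UMI per cell in cells with ~8,000 total UMIs — the
pseudocount compresses the estimate, and a true fold-4 activation reads as
log2fc ≈ 1.4–1.6 rather than 2. This is a property of the estimator, not of
the test: recovery of programmed effects at the hit-calling level is
unaffected, and the package's recovery tests show the estimate is unbiased
(within ±0.3 of log2 f) whenever the de-logged means are well above 1.

## The rank-sum test

The Wilcoxon test is implemented in two regimes:

* pooled size ≤ 12 (`exact_limit`): exact enumeration of all
  $\binom{n}{n_1}$ label assignments, counting rank sums at least as far from
  their expectation as observed — correct under ties, and the reference for
  the test suite's independent bitmask oracle;
* larger: normal approximation with tie correction and continuity
  correction, verified against `stats::wilcox.test` to 1e-12.

`run_all_tests()` vectorizes the large-sample path: per gene, cells are
ranked once and the tie term computed once; each guide then only needs the
rank sum over its carriers. A property test pins the vectorized path to the
scalar `test_guide_gene()` implementation. The singleton bulk-validation test
(3 gRNA lines vs 21 controls) forces the exact path across all
$\binom{24}{3} = 2024$ assignments; complete separation gives the attainable
two-tailed floor $2/2024$.

All genomic intervals are 0-based half-open internally; the cis-window is
`[site − R, site + R]` and a gene belongs to it when its `[start, end)`
interval overlaps the window on the same chromosome. Conversions to 1-based
triplet coordinates happen only in the MatrixMarket I/O layer.

## What the synthetic generator emulates — and what it does not

`simulate_screen()` produces a screen with known ground truth:

* integrations per cell are Poisson(`moi_mean`), including zeros — both
  unintegrated cells and sub-threshold capture contribute to the unassigned
  fraction observed in real screens; guides within a cell are sampled
  without replacement;
* baseline expression means are log-normal with a configurable near-silent
  fraction (mean ≈ 0.005 UMI/cell) mimicking genes that are not expressed in
  the assayed cell type yet can be strongly activated;
* counts are negative binomial with per-cell log-normal size factors;
  programmed effects multiply the target-gene mean in carrier cells and
  compose multiplicatively when a cell carries several guides for one gene
  (the standard log-scale assumption; the per-guide folds are configurable);
* capture UMIs per true integration are NB(mu = 20, size = 2), putting
  ~10% of true integrations below the 5-UMI threshold so that assignment is
  a real filter;
* metadata include a mitochondrial fraction (Beta), a small injected
  low-quality population (high mito, low depth) and per-cell total UMIs =
  panel counts + an off-panel background (log-normal around 8,000, scaled by
  the cell's size factor) so the real QC thresholds are exercisable.

Not emulated: ambient guide contamination, doublets, batch effects beyond a
label, gene–gene correlation beyond size factors, and read-level data. A
green test suite therefore demonstrates the statistical machinery, not
robustness to those artifacts.

Every stochastic step draws from a named substream derived from one seed
(layout, library, expression parameters, effects, integrations, capture,
expression, QC metadata, NTC subsampling, QQ downsampling, proximity null),
so runs are bit-for-bit reproducible and the streams cannot alias.

## Choices where the design was open

* **≥ 5 vs > 5 UMIs**: the assignment rule is read as "at least 5";
  configurable.
* **NTC test set**: the full union of cis-window genes by default; a seeded
  subsample is opt-in (`ntc_gene_subsample`) and recorded in the log.
* **BH scope**: correction is applied within one analysis run (one cellular
  context).
* **Sign-proportion test**: a 2×2 Fisher exact test of targeting vs NTC
  against positive vs non-positive log2fc; a one-sample binomial against 0.5
  is available behind `method = "binomial"`.
* **Proximity null**: NTC guides have no genomic site, so no distance to a
  gene is defined for them. The null assigns each NTC a targeting guide's
  window uniformly at random (seeded) and then a gene uniformly within that
  window; the hit distances are compared against this by a one-sided
  rank-sum test. Distances use the strand-aware TSS, since activation acts
  at promoters.
* **Within-round ranking in guide selection**: the printed round criteria do
  not say how more than k passers are ordered; the package ranks by
  on-target score (descending), then |TSS distance| (ascending), then spacer
  lexicographically, which keeps selection deterministic and order-invariant.
* **Duplicate gene symbols** on input are collapsed by summing counts (with
  a warning) rather than dropped.

## Test and simulation scale

The suite runs screens of 400–5,000 cells with 20–150 guides and 30–60
genes; the calibration check uses ten 2,000-cell null screens (no programmed
effects) and asserts ≤ 2 EFDR hits per 1,000 targeting tests, and the
recovery check uses five 5,000-cell screens with twenty fold-4 effects and
≥ 300 carrier cells per programmed guide. These sizes give the power the
assertions need while keeping a full run in the low minutes. One statistical
note: raw P-values across *all* tests of a screen are not mutually
independent (tests share genes and control cells, and the detection filter
selects anti-conservative outcomes for near-silent genes), so the uniformity
check applies the Kolmogorov–Smirnov test to one test per guide — the
independent unit — rather than to the pooled table.

## Known limitations

* No covariate adjustment (lane, depth, cell state); the empirical FDR
  absorbs global miscalibration but not covariate-specific confounding.
* Cells from one starting population are treated as pseudo-replicates, as in
  the underlying screening framework.
* The fold-change estimator compresses at low abundance (see above); treat
  reported log2fc near the detection limit as a lower bound on effect size.
* The empirical-P floor ties significance to the size of the NTC test set.

## A minimal run

```{r example, eval = FALSE}
sim <- simulate_screen(sim_config(n_cells = 2000, seed = 7))
cfg <- run_config(max_mito_fraction = 0.15, min_total_umi = 2000,
                  out_dir = "results", seed = 7)
bundle <- run_pipeline(cfg, dataset = sim$dataset)
head(bundle$hits)
bundle$moi
```
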