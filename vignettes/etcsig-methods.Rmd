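---
title: "Methods: statistical machinery of the ETC-inhibition signature pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: statistical machinery of the ETC-inhibition signature pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`etcsig` analyses targeted transcriptomic count data from concentration
series of mitochondrial electron-transport-chain (ETC) inhibitors in
renal cells, together with matched respirometry (OCR) and viability
endpoints. This vignette describes the statistical models, the defaults
and why they were chosen, what the bundled synthetic-data generator does
and does not emulate, and the numerical decisions taken where the design
was genuinely open.

## Differential expression

Counts for probe $i$ in sample $j$ are modelled as negative binomial
with mean $s_j q_{ij}$ and dispersion $\alpha_i$
($\mathrm{Var} = \mu + \alpha_i \mu^2$).

**Library-size QC.** Samples with fewer than 200,000 total reads are
removed before any estimation (`filter_library_size()`, strict `<`). The
threshold is the conventional depth floor for ~3,000-probe targeted
panels, below which per-probe counts become too sparse for stable
dispersion estimates.

**Normalization.** `size_factors()` implements the median-of-ratios
estimator: per sample, the median over genes (restricted to genes with a
positive geometric mean across samples, or to a positive-count
pseudo-reference on request) of the ratio between the sample's count and
the gene's geometric mean. The median is taken on the ratio scale; a
log-scale midpoint convention differs only in the even-count tie-break.
Factors are rescaled to geometric mean 1, so they are interpretable as
relative depths. Median-of-ratios assumes the majority of genes are
unchanged between samples; when a planted (or real) global shift affects
most genes, the shift is absorbed into the size factors by construction.

**Dispersion.** Per gene, a method-of-moments estimate is formed inside
each replicate group, combined weighted by degrees of freedom, and
truncated at zero. Because three replicates give extremely noisy
moment estimates, each gene is shrunk toward a mean–dispersion trend
$\alpha_{tr}(\mu) = a_0 + a_1/\mu$ fitted across genes by least squares
(coefficients clamped non-negative), with shrinkage weight 0.8 and a
floor of $10^{-8}$. The weight was chosen so that the Wald test on
3-vs-3 designs holds its nominal size (the test suite verifies type-I
error in $[0.03, 0.08]$ at $\alpha = 0.05$); smaller weights are
anti-conservative at this replicate number, while full pooling ignores
genuine dispersion heterogeneity. This is a deliberately simplified
relative of empirical-Bayes dispersion machinery: there is no posterior
per-gene estimate, no outlier handling (Cook's-distance style), and no
fold-change moderation. DE gene counts obtained from real data will
therefore differ slightly from a shrinkage-based analysis of the same
tables; the test suite cross-checks fold-change agreement against DESeq2
on shared simulated data.

**GLM and Wald test.** `nb_wald_test()` fits, per gene, an NB log-link
GLM (intercept + optional batch terms + condition) by iteratively
reweighted least squares with the log size factors as offset, fixed
dispersion, a deviance convergence tolerance of $10^{-8}$ and at most
100 iterations; non-converged genes are flagged, never dropped. The
reported `log2FoldChange` is the condition coefficient divided by
$\ln 2$; p-values use the standard-normal reference for the Wald
statistic. Rank-deficient designs (e.g. a condition present in only one
batch when a batch term is requested) are rejected with the collinear
columns named. Significance uses the strict cut-offs baseMean > 10,
BH-adjusted p < 0.05 and |log2FC| > 0.585 (1.5-fold).

## Class analysis

A per-compound *reference concentration* is the concentration with the
most DEGs strictly below the cytotoxicity LOEL (ties toward the lower
concentration). Class datasets concatenate each member compound's
reference-concentration samples with the vehicle samples of every
experiment involved, and the class test uses the batch-aware
`~ experiment + class` design so that the class effect is the marginal
effect across experiments. The three per-class significant sets are
partitioned into the seven Venn regions; "unique" means significant in
exactly one class at the stated thresholds.

Fold-change concordance over the triple intersection is the squared
correlation of pooled pairwise log2FC pairs. Because the plotting
convention (which class on which axis, pooled or per pair) is not
canonical, both modes are provided; the default pools every ordered pair
in both orientations, which makes the statistic exactly invariant to
class order.

## Probe-panel harmonization

When two panel versions measure the same genes with partly different
probes, probes with identical identifiers are kept outright. For a gene
measured by differing probes, the per-gene log2 fold changes of a common
reference treatment are compared between panels; the gene is kept when
their sample standard deviation $SD_p$ (for a pair, $|\Delta|/\sqrt 2$)
falls below 0.1 log2 units. The algebraic definition of $SD_p$ and the
choice of a single reference condition are package decisions — the
similarity rule is exposed with the reference condition as a parameter
so other conventions can be swapped in.

## Over-representation analysis

With $N$ measured genes, $R$ selected, and a set containing $n$ measured
genes of which $r$ are selected,
$$Z = \frac{r - nR/N}{\sqrt{n \frac{R}{N}\left(1-\frac{R}{N}\right)\left(1-\frac{n-1}{N-1}\right)}},$$
i.e. the selected-in-set count standardized by its exact hypergeometric
mean and finite-population variance (verified in the tests against
exhaustive enumeration for every universe up to $N = 30$). The
permutation p permutes selection labels over the measured universe
(one-sided, add-one corrected, 1,000 permutations by default, one joint
set of permutations across the database). The measured universe is the
baseMean-filtered gene list of the differential-expression analysis —
"measured" is read as "analysed", and is parameterizable. Selection is
direction-blind by default. A set is significant at |Z| > 2 and permuted
p < 0.05.

## Upstream regulators

For a regulator with signed, weighted edges to targets, the activation
z-score over the differentially expressed overlap is
$z = \sum_v w\, s_R s_D / \sqrt{\sum_v w^2}$; $|z| \ge 2$ predicts
activation or inhibition. Unobserved targets are excluded from the sums;
zero overlap yields an undefined, flagged score. Overlap significance is
the right tail of Fisher's exact test on the 2×2 membership table,
BH-adjusted across regulators. Networks are plain 4-column signed edge
lists supplied by the user; no attempt is made to reproduce any
proprietary knowledge base — only the scoring mathematics.

## Dose–response and benchmark doses

**Williams trend prefilter.** Dose-group means are amalgamated under an
isotonic constraint by weighted pool-adjacent-violators; the statistic
compares the highest amalgamated treated mean to the control mean,
scaled by the pooled within-group standard error. The direction
(increasing/decreasing) with the larger statistic is taken. Because the
classical critical-value tables depend on the dose count, significance
comes from permuting the replicate-to-group assignment (default 10,000
permutations; 200 in the pipeline stage, where the fold-change gate is
applied first so permutations are spent only on genes that could pass).
The prefilter keeps genes with p < 0.05 and maximal group-mean fold
change above 1.5.

**Exp5 fits.** The four-parameter exponential
$m(d) = a\,(c - (c-1)e^{-(bd)^g})$ is fitted by Levenberg–Marquardt
least squares with a multi-start grid (log-spaced $b$ across the tested
dose range, several $c$ and $g$ starts); a flat candidate ($c = 1$) is
always in the pool, so the returned RSS never exceeds the constant
model's. Two numerically consequential conventions:

* the shape exponent is bounded below at $g = 1$ by default (the
  restricted-power convention for continuous BMD models); unrestricted
  shapes allow unbounded slope at dose zero and destabilize low-dose
  benchmark estimates;
* expression-like responses with multiplicative noise can be fitted on
  the log scale (`fit_log = TRUE`, used by the pipeline's BMD stage for
  positive normalized counts); this is the efficient estimator under
  log-normal error and measurably tightens benchmark-dose recovery.

**BMD.** The benchmark response defaults to a 10% relative change of the
modelled control response in the curve's direction, with a control-SD
option. Inversion is closed-form; targets outside $(a, ac)$ give an
undefined, flagged BMD. Accumulation curves are right-continuous step
functions of the per-gene BMDs.

**OCR and LOELs.** Raw rates are mapped to percent of control by
subtracting the positive-control mean (non-mitochondrial respiration)
and scaling the vehicle basal mean to 100%, with optional rescaling to
designated non-effective concentrations. LOELs use one-way ANOVA with
Dunnett single-step many-to-one comparisons (`multcomp`). The mitotoxic
subset keeps compound–concentration pairs with OCR ≤ 60% and viability
≥ 75% of control.

## The synthetic-data generator

`generate_experiment()` emulates the study design the pipeline assumes:
~3,000 probes; two experiments (batches) with compounds split between
them and vehicles in both; three classes of four compounds; five-point
log-spaced concentration series with three replicates; NB counts with
constant dispersion 0.05 (the replicate-to-replicate variance of the
real system is not published; the value is a conventional figure for
technical-plus-biological noise in targeted assays and is exposed in the
configuration); library sizes log-normal around $10^6$ reads with CV
0.4, so occasional samples fall below the 200,000-read QC floor; a
gene-wise multiplicative batch factor, log-normal with $\sigma = 0.1$ —
small enough that the batch-aware design removes it, large enough to be
detectable; a common signature (10% of genes) responding to all three
classes plus 3% class-unique genes per class, with Exp5-shaped response
curves (peak |log2FC| = 2, rates log-uniform across the tested range)
and balanced up/down directions. Companion generators plant an enriched
gene set among size-matched decoys, a signed regulator network with a
configurable fraction of direction-consistent edges, and OCR/viability
tables in which only CI and CIII compounds depress respiration — the
pattern the mitotoxic-subset rule is designed to isolate.

What the generator does **not** emulate: probe-level sequence biases,
correlated gene programs (genes respond independently), heavy-tailed
dispersion across genes, batch effects on dispersion, partial-response
compounds within a class, and count outliers. Passing tests on this
material therefore demonstrate the correctness and calibration of the
statistical machinery under the assumed model, not robustness to every
artefact of real TempO-Seq data.

## Problem sizes and determinism

The test suite and the acceptance script run end-to-end studies at 250 to
800 genes with one or two compounds per class, calibration simulations at
2,000 genes, benchmark-dose recovery at 200 genes, and 200 to 10,000
permutations depending on the resolution a check needs; these sizes give
each check comfortable Monte-Carlo resolution while keeping a full run in
the minutes range on one core. Every stochastic step takes an explicit
seed, generators restore the RNG state on exit, and a pipeline run with a
fixed seed writes byte-identical report tables; the run manifest records
seeds, thresholds, package version and warning counts.

## Known limitations

* The DE stage deliberately omits empirical-Bayes dispersion posteriors,
  fold-change shrinkage and outlier replacement; gene lists from real
  data will differ modestly from shrinkage-based analyses at the margins
  of significance.
* Only the Exp5 model family is fitted; there is no multi-model "best
  BMD" selection or model averaging, and no BMDL/BMDU profile-likelihood
  bounds.
* The Williams permutation p is bounded below by 1/(permutations + 1);
  genes needing extreme significance require raising the permutation
  count.
* Viability enters as a user-supplied percent-of-control table; the
  underlying viability assay is not modelled.
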