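---
title: "Methods: sex-specific miRNA-mRNA integration analysis"
author: "miRstress authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-specific miRNA-mRNA integration analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miRstress)
```

# The analytical problem

Chronic stress induces depression-like behavior in female but not male
mice, and paired small-RNA and mRNA sequencing of nucleus accumbens tissue
from a 2 x 2 sex-by-stress design asks which microRNAs (miRs) and which
transcripts respond, how differently per sex, and whether the miR and mRNA
responses are coupled in the repressive (anti-correlated) direction miR
biology predicts. `miRstress` implements that full analysis path on count
matrices, with a synthetic-data generator standing in for sequencing data
so every stage is testable end to end.

# Differential expression model

Counts enter as features x samples matrices paired with a design (sex,
condition, estrous stage, pool size). The pipeline is deliberately close to
the voom/limma approach, implemented in-package:

* **Filter.** A feature is kept when, in at least one sex-by-condition
  cell, more than `filter_min_count` (default 5) reads are seen in at least
  `filter_min_fraction` (default 0.8) of that cell's samples. Filtering
  before modeling keeps the mean-variance trend estimable and defines the
  candidate universe that all downstream backgrounds refer to.
* **Scale.** log2-CPM with offsets, `log2((count + 0.5)/(libsize + 1) *
  1e6)`. Library sizes are plain column totals: no compositional (TMM-type)
  normalization is applied by default, because the factorial contrasts and
  every downstream quantity here depend on within-feature comparisons, and
  the balanced design gives compositional shifts little leverage. Users
  can normalize upstream if their data demand it.
* **Precision weights.** Unweighted gene-wise fits give residual SDs; a
  lowess trend (span 0.5) of sqrt-SD against mean log2 count is
  interpolated at each observation's fitted log2 count (clamped at the
  trend ends) and the weight is the predicted sqrt-SD to the power -4.
  One pass only, matching the cited tool's default; a reweighting
  iteration changes little at this design size. The span and the single
  pass are the published defaults of the voom method; the predicted value
  is floored at 1e-4 to keep weights finite on degenerate trends.
* **Fit.** Weighted least squares per feature on the saturated group-means
  parameterization (four cells). Per-sex stress effects are contrasts:
  `stress_in_males = (-1, +1, 0, 0)`, `stress_in_females = (0, 0, -1, +1)`
  over (male-control, male-stress, female-control, female-stress). A
  saturated model with contrasts and a main-effects + interaction coding
  give identical fitted cell means; the group-means form was chosen for
  simpler contrast bookkeeping. Baseline sex differences are absorbed by
  the sex-specific intercepts, which is what "controlling for baseline
  variation" amounts to in this design.
* **Moderate.** The residual variances are shrunk toward a prior fitted by
  moment matching on the log variances (prior df from the inverse trigamma,
  infinite prior handled by collapsing to the prior variance), and each
  contrast is tested with a moderated t on prior + residual df, two-sided.
  The implementation reproduces limma's `voom`/`lmFit`/`eBayes` to within
  1e-8 on shared inputs (asserted in the test suite), while remaining
  independent code.
* **Call.** *Up* when p < `p_cut` (0.05, uncorrected) and log2FC >=
  log2(`fc_cut`) (1.3 linear); *down* symmetric; otherwise *neutral*. The
  uncorrected-p-plus-fold-change rule is intentionally liberal; it is the
  discovery threshold this analysis tradition uses, and the network stage
  applies its own FDR control afterwards.

One detail worth knowing: when every residual variance is identical the
moment-matched prior is the log-scale-unbiased back-transform, which sits
`exp(log(d/2) - digamma(d/2))` above the common variance (about 13% at 8
residual df). This is a property of the method of moments, not a bug, and
it is what the reference implementation does too.

# Overlap testing

Two directional lists of sizes $n_A$, $n_B$ from a background of $N$
candidates sharing $k$ members are scored with the exact hypergeometric
enrichment tail $P(X \ge k)$, summed in log space so that p-values in the
1e-11 range keep full relative precision. The background is *fixed* at the
candidate-universe size (19,827 mRNAs and 781 miRs at full scale,
configurable in `analysisThresholds`), not at the union of the lists. No
multiplicity correction is applied across the pairwise family; the raw
p-values are reported, as is conventional for these overlap summaries.
Because the statistic is discrete, the p-value is super-uniform under the
null: its distribution steps below the diagonal, which is why calibration
is asserted as a band on the empirical CDF at 0.05 rather than strict
uniformity.

# miR-target integration

This is the package's core procedure:

1. **Consensus targets.** A (miR, gene) prediction is kept only when every
   required source reports it, then restricted to the analyzed (filtered)
   mRNA universe. Restricting to the universe is required for the
   frequency comparison below to be coherent: the background trichotomy is
   computed over exactly that universe. "Neutral" means
   analyzed-but-not-DE; genes that never passed the count filter are
   outside the universe entirely.
2. **Per-miR chi-squared.** For each differentially expressed miR with at
   least `minTargets` (default 5, for chi-squared validity) in-universe
   targets, the observed (up, down, neutral) counts of its targets are
   compared to expected counts proportional to the universe-wide
   frequencies: a goodness-of-fit test with df 2. The wording "versus the
   background" could also support a 2 x 3 contingency of targets vs
   non-targets; that variant is available via `mode = "contingency"` and
   differs negligibly when targets are a small fraction of the universe.
   Cells with expected count < 1 are flagged (`low_expected`), not
   dropped.
3. **Selection.** Benjamini-Hochberg across all tested miRs of one sex
   (the per-sex family matches how surviving counts are reported), reject
   at adjusted p < 0.05.
4. **Network.** Each surviving miR is joined to its differentially
   expressed targets; the edge is *negative* when the two move in opposite
   directions, *positive* when they move together; neutral targets never
   enter. Export formats: SIF (relation tokens `represses`/`coexpressed`,
   since SIF requires a relation word), GraphML with node kind, direction
   and log2FC attributes, and a lossless edge-TSV. By convention the
   Cytoscape-facing SIF is usually filtered to negative edges in published
   figures; the package exports all edges and leaves filtering to the
   caller.
5. **Summary.** Counts and fractions of DE genes targeted, sign patterns
   per gene (negative-only / positive-only / both), genes hit by one vs
   two-plus miRs, and the fraction of DE miRs surviving.

# Overrepresentation

Generic Fisher's-exact ORA of a query list in a GMT collection against an
explicit universe, significant when -log10(p) >= 1.3 (i.e. p <= 0.05, the
rule used by the pathway tools this stands in for). The default universe is
the sex's filtered DE universe rather than a whole-genome background --
standard ORA practice, and the conservative choice when the knowledgebase
background is unrecoverable; a BH-adjusted column is reported alongside but
the raw -log10(p) rule is the significance flag.

# qPCR validation

Relative quantification by 2^-ddCt: per sample, the target Ct minus the
mean of the reference Cts (arithmetic mean on the Ct scale = geometric mean
in linear space; the combination rule is not standardized, this is the
common choice); then centered on the control-group mean dCt and exponentiated.
Fold changes are rescaled so the control mean is *exactly* 1 (the naive
back-transform leaves it slightly off 1 because the mean of `2^-x` is not
`2^-mean`). Outliers are handled per group on the fold-change scale --
the scale on which group comparisons are made -- by a two-sided Grubbs test
(critical value from t quantiles, one removal per group by default); a
cruder `"2sd"` mode (drop points beyond two SDs) is provided because both
rules circulate in practice. The two-group test is a pooled-variance t-test
unless a two-sided F-test at 0.05 declares the variances unequal, in which
case a two-tailed Mann-Whitney U is used. The F-test gate is a concrete
choice for an informally stated rule ("when variances were unequal") and is
documented as such.

# The synthetic-data generator

`simulateExperiment` emulates the study design rather than sequencing
reads:

* **Design.** 2 sexes x 2 conditions x `librariesPerCell` (3) libraries,
  each a pool of `poolSize` (5) animals. A library count is the sum of
  animal-level negative-binomial draws -- pooling happened at tissue
  homogenization, and summation is the count-scale analogue. Female
  libraries are drawn in estrus or proestrus only, mirroring the estrous
  control of the design.
* **Abundance.** Baseline means are log-normal (`meanlog log(20)`, `sdlog
  2.3`), spanning roughly four orders of magnitude. No tissue-specific
  baseline distribution is available to copy, so this is an explicit
  stand-in calibrated only by the qualitative shape of bulk expression
  data. Dispersion follows the standard trend `a0 + a1/mean` (0.05 + 2/mean)
  at the animal level; summing animals divides the effective dispersion,
  as real pooling does. Library-size factors are log-normal with CV 0.2,
  the usual depth-heterogeneity model.
* **Effects.** Per sex, a fraction of genes (5%) and miRs (5% male, 3.5%
  female -- the sexes' miR responses are asymmetric in this direction in
  the motivating data) receive a +/-1 log2 stress effect, applied only to
  stressed animals of that sex; the up/down split is biased toward
  downregulation for genes (30/33% up in males/females) and upward for
  miRs, again following the motivating asymmetries.
* **Coupling.** Every miR owns a true target set (Poisson mean
  `targetsPerMir` = 25). When a miR is regulated with effect delta, each
  true target independently (probability `couplingProb` = 0.8) receives
  the opposing effect `-delta * attenuation` with attenuation 0.5 --
  single miR-target interactions have modest downstream amplitude, so the
  planted coupling is deliberately weaker than the direct effects. The
  product of miR effect and added target effect is negative for every
  planted pair by construction.
* **Predictions.** Each source reports each true edge with its sensitivity
  (defaults 0.85 / 0.80) and adds Poisson false edges per miR (default 10
  per source). Intersecting two noisy sources is what makes the consensus
  step meaningful in testing.
* **Determinism.** Identical config + seed reproduces identical bytes.

Default dimensions (5000 genes, 400 miRs) are scaled down from the
full-size universe (19,827 / 781) so that the complete test battery and
demo pipeline run in minutes; full scale is a config change. What the
generator does *not* emulate: read-level artifacts (adapters, mapping
bias), compositional distortion between conditions, correlated effects
among co-regulated gene modules, estrous-cycle dynamics over days, and any
real secondary structure in the target predictions (sources err
independently here; real predictors share systematic biases). Passing
recovery tests on this generator therefore demonstrates the pipeline's
statistical correctness under its own assumptions, not performance on any
particular real dataset.

# Numerical and degenerate-input choices

* Hypergeometric tails are log-sum-exp'd; chi-squared p-values come from
  the exact df-2 survival function.
* The lowess trend is interpolated monotonically and clamped at its range
  ends; predicted sqrt-SDs are floored at 1e-4.
* The trigamma inverse uses the standard Newton iteration to 1e-10.
* Zero residual variances are excluded from prior estimation (all-zero is
  an error); singular designs, empty filter results, zero-total samples,
  and out-of-universe list members are errors with named coordinates.
* miRs with no or too few in-universe targets are excluded from the
  chi-squared stage with warnings, never silently.
* Grubbs on fewer than 3 values, or zero variance, returns the input with
  a warning.
* Ties in the output ordering are broken lexicographically everywhere
  (pair names, set names), so artifacts are byte-reproducible.

# Problem sizes used in the shipped tests

Calibration and recovery tests run at 2000-5000 genes, 100-400 miRs, 5
seeds; the chi-squared uniformity check draws 1000 random target sets of
1000 genes from a 100k-feature direction table, a regime where the
multinomial assumption of the df-2 approximation holds cleanly; the overlap
enumeration oracle covers every (list, list, overlap) instance on universes
up to 30. These sizes were chosen as the smallest that make the statistical
assertions stable across seeds.

# Known limitations

* The package starts at count matrices; trimming, alignment and
  quantification live upstream.
* Target predictions are inputs; no seed-match prediction is performed.
* The overlap module reports raw pairwise p-values only; multi-way exact
  intersection distributions are not implemented.
* No amplification-efficiency correction in the qPCR module (ddCt assumes
  ~100% efficiency for target and references alike).
* The enrichment module is a generic ORA; it does not reproduce any
  proprietary knowledgebase's content or clustering.
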