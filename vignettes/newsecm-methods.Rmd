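---
title: "Methods: quantitative analysis of newly synthesized ECM proteomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative analysis of newly synthesized ECM proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(newsecm)
```

## The problem

Cells cultured on a decellularized extracellular-matrix (dECM) scaffold
deposit new ECM on top of a large background of pre-existing scaffold
protein. Metabolic labeling with an azido-sugar (Ac4GalNAz) marks the
glycans of newly synthesized glycoproteins; click conjugation to
alkyne-PEG4-desthiobiotin and streptavidin capture enrich those proteins
into an *eluate* fraction, while the bulk lysate forms the *input*. The
quantitative questions downstream are: which proteins are enriched by the
label (GalNAz vs vehicle), how the newly synthesized ECM differs between
culture models (dECM-tumor vs tumoroid), how selective the capture is for
cell-derived (human) over scaffold-derived (rat) protein, and how the
matrisome composition of the newly synthesized fraction compares with the
bulk. This package implements that analysis as a tested pipeline; because
the underlying mass-spectrometry data are not publicly deposited, a
synthetic-data module generates inputs with the same statistical structure
so every stage can be validated against known ground truth.

## Normalization model

Within a *scope* — a set of samples declared to be normalized together —
each sample's intensities are scaled by

$$X_{\text{norm}} = X_{\text{orig}} \cdot \frac{\overline{\sum}}{\sum_{\text{sample}}},$$

where $\sum_{\text{sample}}$ is the sample's total intensity over a
declared protein subset and $\overline{\sum}$ is the mean of those totals
over the scope. Three scope conventions cover the search workflows:

* labeled-vs-vehicle eluate comparisons: each treatment group is its own
  scope, with sums over human proteins only (between-group abundance
  differences — the enrichment itself — are preserved);
* cross-model comparisons of labeled eluates: one scope over all samples,
  sums over human proteins;
* inputs: one scope over all input samples, sums over all proteins.

Scope membership is declared, never inferred from sample names. Zeros (not
observed) contribute nothing to sums and remain zero after scaling. Two
algebraic consequences are asserted in the tests: per-sample subset totals
within a scope are equal after normalization (relative tolerance 1e-9), and
the operation is idempotent. Note that rescaling one sample's raw values by
a constant cancels out of that sample's scale factor but shifts the
scope-wide $\overline{\sum}$, so the normalized matrix is invariant only up
to one common multiplier across the scope; the tests state the property in
that form (it is exact for single-sample scopes).

## Filtering, missingness, and QRILC imputation

Label-free intensities are missing not at random: low-abundance proteins
fall below the detection limit, censoring the left tail. The pipeline
handles this in two ways, matching each workflow's design:

* **Pre-filter.** A protein must have at least `min_nonzero = 2` nonzero
  values in *every* treatment group to be testable; this is the standard
  "minimum valid values in each group" convention. Filtered-out proteins
  are not discarded silently — the within-model workflow reports their
  per-group mean intensities separately, since a protein present only under
  labeling is biologically informative even without a p-value.
* **QRILC imputation** (cross-model workflow). Per sample, the observed
  values are treated as the upper tail of a Normal whose lower tail was
  censored. Sorting the $k$ observed values of a sample with $n$ total
  entries and $m = n - k$ missing, the order statistic $y_{(i)}$ (rank
  $m + i$ in the complete sample) is regressed on
  $\Phi^{-1}\!\big((m + i - 0.375) / (n + 0.25)\big)$; the least-squares
  intercept and slope estimate $\mu$ and $\sigma$ of the complete
  distribution. Each missing entry is then drawn from
  $\mathcal{N}(\mu, \sigma \cdot \texttt{tune\_sigma})$ truncated above at
  the sample's minimum observed value, by inverse-CDF sampling. Blom's
  plotting positions were chosen as the conventional near-unbiased choice
  for normal quantile regression; the published QRILC description does not
  pin down the plotting-position formula, so this is one defensible
  reading, validated by parameter recovery (on 2000 draws from
  $\mathcal{N}(25, 2)$ censored at the lowest 20%, $\hat\mu$ is within
  $\pm 0.2$ and $\hat\sigma$ within $\pm 0.3$ per seed, with mean bias
  within $\pm 0.1$ / $\pm 0.2$ over ten seeds). `tune_sigma` defaults to 1;
  the truncation point is the per-sample minimum observed value, consistent
  with censoring at a detection limit. Imputation is per sample
  (column-wise), deterministic given the seed, and never alters observed
  entries.

The within-model branch deliberately does *not* impute — its statistical
path runs on fully observed proteins after the filter — so its inferential
results never depend on imputation draws.

## Differential testing and permutation FDR

Per protein, a two-tailed Welch t-test compares the two groups:
$t = (\bar a - \bar b) / \sqrt{s_a^2/n_a + s_b^2/n_b}$ with
Welch–Satterthwaite degrees of freedom. Fold changes are ratios of
geometric means, so $\log_2 \mathrm{FC}$ equals the difference of mean
log2 intensities and is consistent between the decimal and log scales.

Multiple testing is controlled by a permutation-based FDR in the style of
significance analysis of microarrays. Group labels are reshuffled — every
distinct assignment when there are at most 1000 (e.g. all 252 splits of a
5-vs-5 design), otherwise 250 seeded random permutations. At each observed
$|t|$ threshold, the estimated FDR is the mean permuted count of statistics
at or above the threshold divided by the observed count (inclusive
counting at ties), clipped to $[0, 1]$; a protein's q-value is the smallest
FDR at which it is called significant, then made monotone non-decreasing in
the p-rank (the $|t|$ ordering and p ordering can differ because Welch
degrees of freedom vary across proteins). An optional SAM-style fudge
factor $s_0$ (default 0, as nothing suggests a nonzero value was used) is
added to the standard error in both observed and permuted statistics, and
the permuted-count aggregator can be switched from mean to median. The
exhaustive path is tested for exact agreement with a brute-force
enumeration oracle, and calibration is checked under a global null
(fraction with $q < 0.05$ at most 0.07 for 1000 null proteins, 4 vs 4).

Volcano categories follow the inclusive-boundary rule: significant high in
A requires $\log_2\mathrm{FC} > 1$ *and* $q < 0.05$; equality on either
threshold is non-significant.

Auxiliary statistics — pairwise Pearson correlations on shared observed
proteins, Grubbs's single-outlier test (two-sided, t-based critical value),
paired t-tests, and one-way ANOVA with Tukey HSD at 0.95 confidence — use
the standard formulas (ANOVA/Tukey and the paired test call R's own
implementations; the test suite checks them against independently coded
textbook formulas). Outlier screens are advisory: the run report flags
samples (Grubbs on per-sample protein-ID counts) but removal is an explicit
user decision, because the decision rule linking the screens to sample
removal is not mechanizable from the method description.

## Species selectivity and matrisome accounting

The species summary totals human and rat intensities per fraction on
*original* (un-normalized) values and reports the percent change
$(\text{eluate} - \text{input})/\text{input} \times 100$ per species —
capture selectivity shows up as a much smaller reduction (or a gain) for
labeled human protein than for unlabeled rat protein.

Matrisome accounting matches gene symbols (exact, case-insensitive)
against an annotation table of the six matrisome categories (collagens,
ECM glycoproteins, proteoglycans — core matrisome; ECM regulators,
ECM-affiliated proteins, secreted factors — matrisome-associated).
"Identified" in a fraction means at least one nonzero intensity in that
fraction's samples; the published figures count protein groups per fraction
without stating a presence rule, and this is the weakest sensible one.
Category counts plus the non-matrisome remainder partition the identified
set exactly. Annotation is symbol-keyed because matrisome lists are
published by gene symbol; the real list is loadable via `read_matrisome()`
and the bundled generator produces a synthetic stand-in for tests.

## Azido-glycan modification masses

The two custom Ser/Thr search modifications are defined from
first-principles elemental compositions with pinned monoisotopic atomic
masses (C = 12 exactly, H = 1.0078250319, N = 14.0030740, O = 15.9949146,
S = 31.97207117 Da): the GalNAz glycan residue C8H12N4O5 (an N-acetyl
hexosamine residue whose acetyl carries an azide) at +244.0808 Da, and its
click adduct with alkyne-PEG4-desthiobiotin C21H37N3O6 — the cycloaddition
conserves all atoms, so the adduct is the element-wise composition sum
C29H49N7O11 at +671.3490 Da. Both printed masses reproduce to four decimal
places, which is the validation that the inferred compositions are right.

## DAPI-map immunofluorescence quantification

The tissue mask is built from the blue (DAPI) channel by a fixed pipeline:

1. *balance*: linear percentile contrast stretch, clipping at the 1st/99th
   percentiles and rescaling to full range — the common meaning of
   auto-balancing a channel; the original program's exact operation is not
   recoverable, so the quantiles are exposed as a parameter;
2. *threshold* at 20% of the balanced channel's own maximum (not the
   bit-depth maximum);
3. *size filtration*: remove 8-connected components below
   `min_component_area` (default 30 px) to discard non-nuclear debris;
4. *closing*: dilation then erosion with a disk structuring element
   (default radius 3 px), connecting nucleus blobs into an approximation of
   the underlying tissue.

Neither the area threshold nor the disk radius is stated in the method
description; the defaults are sensible for nuclei of roughly 5-10 px
radius and are configurable. An all-zero blue channel yields an empty map
with a warning rather than an error. Channel means inside and outside the
mask are reported on the normalized 0-1 scale
(value / $(2^{\text{bit depth}} - 1)$); marker scores can be normalized by
mask area or by another channel's inside mean (e.g. a junction marker),
the latter making the score invariant to global illumination scaling.

The synthetic tissue image places overlapping nuclei on a jittered,
radius-spaced lattice inside a disk-shaped tissue region, plus a ring of
nuclei lining the boundary, with centres kept one radius inside it — so the
union of nucleus disks (the ground-truth mask) tiles the region almost
exactly, as in a confluent section. Marker channels are uniform inside and
outside that mask, giving region statistics exact expected values. At
default parameters the recovered DAPI map reaches Jaccard ≈ 0.99 against
the truth and region means within 1-2% relative error. What this does
*not* demonstrate: performance on real sections with intensity gradients,
sparse nuclei, debris, or out-of-focus light — there the mask is
parameter-sensitive, which is why all four pipeline parameters are exposed.

## Synthetic LFQ generator: what it emulates and what it does not

`simulate_lfq()` draws per-protein baseline log2 abundances once from
$\mathcal{N}(25, 2)$ (the scale of typical LFQ intensities), adds i.i.d.
Gaussian within-protein noise (default sd 0.5 log2 units, a realistic
between-replicate spread), applies a global enrichment of human proteins in
GalNAz eluates (default +4.5 log2 units, the order of the tens-fold eluate
intensity augmentation the capture produces), optionally spikes a fraction
of proteins with a protein-specific differential along a chosen contrast,
and finally censors the lowest 20% of each sample's intensities to zero —
rank-based per sample, the abundance-dependent missingness QRILC assumes.
The missingness rate of the real data is unknown; 20% is a typical LFQ
figure, a choice, not a claim. Organism tags are human/rat only
(contaminants are not simulated), sample sizes default to 5 per group
(the study's arms ranged 3-5), and the generator is bit-deterministic given
its seed, with censored cells recorded so tests can verify that emitted
zeros are exactly the censored entries.

It does not emulate peptide-level roll-up, match-between-runs, shared
peptides, correlated protein covariation, or intensity-dependent variance —
so passing recovery tests demonstrates that the statistical machinery is
correct under its own model, not that the model captures every feature of
real LFQ data.

## End-to-end recovery and a known limitation

The search workflows are validated by spike-recovery: with 100 proteins
spiked at log2 fold change 3 (within-protein sd 0.5, 5 samples per group),
both search-1 workflows recall at least 90% of spikes at
$(|\log_2\mathrm{FC}| > 1, q < 0.05)$ across seeds, and call at most 5% of
proteins significant on matching no-spike null fixtures. Each branch is
tested under the missingness regime it is designed for: the within-model
branch (no imputation; statistics on fully observed proteins) on complete
fixtures, the cross-model branch (QRILC) with censoring at the generator
default.

One artifact is worth knowing about. On a *spiked* fixture with rank-based
censoring, strong spikes confined to one group push borderline null
proteins below that group's per-sample censor rank and inflate that group's
total (shifting its normalization factor); imputation then fills those
nulls with low values in one group only, so some nulls acquire apparent
fold changes. This is a genuine property of missing-not-at-random data
under proportional normalization and left-censored imputation — not an
implementation bug — and it is the reason null calibration is assessed on
null fixtures. On real data the analogous caveat is that q-values near the
fold-change boundary deserve skepticism when a protein's observations are
heavily one-sided between groups.

## Problem sizes and determinism

The shipped tests use 300-1000 simulated proteins, groups of 4-5 samples,
252-exhaustive or 250 random permutations, 2000-value imputation fixtures,
and 256x256 synthetic images — sizes chosen so the full suite exercises
every code path in well under a minute of statistical computation while
keeping Monte-Carlo error far from the asserted bounds. Every stochastic
step (simulation, imputation, random permutations) takes an explicit seed,
and identical seeds give bit-identical outputs end to end.
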