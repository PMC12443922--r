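---
title: "Purity-aware analysis of segmented GeoMx data: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Purity-aware analysis of segmented GeoMx data: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery:
what each stage assumes, which knobs matter, what the synthetic cohorts do
and do not emulate, and where the design was genuinely open. It states no
empirical result beyond what the test suite and `scripts/acceptance.R`
themselves compute.

## Why purity filtering comes first

Segmented GeoMx profiling assigns barcodes to morphology-defined
compartments — SOX2+ tumor cells and IBA1+ macrophages/microglia (TAMs)
here. Segmentation is imperfect, and in recurrent glioblastoma, where tumor
density is low, a SOX2+ area of illumination (AOI) can be dominated by
oligodendrocytes and TAMs. Any downstream contrast on "tumor cell"
expression is then a contrast on composition. The package therefore treats
AOI-level purity classification as the central inference and everything
after it as conditional on the surviving AOIs.

The filter deliberately combines two orthogonal kinds of evidence:

* **Copy number.** IDH-wildtype GBM carries chromosome 7 gain and
  chromosome 10 loss in the large majority of tumors; both are broad,
  clonal events, detectable from expression alone by reference-based
  log-ratio smoothing. An AOI showing either hallmark contains malignant
  cells, whatever its signature profile — so copy-number evidence can only
  veto exclusion, never cause it.
* **Signatures.** Hallmark-negative AOIs are classified by aggregated
  Z-scores: excluded only when a non-malignant panel (oligodendrocyte or
  TAM) dominates *and* no malignant cell-state signature is expressed. The
  malignant criterion takes the **max** over state signatures because the
  states are alternatives — a tumor cell need express only one.

## Stage-by-stage model notes

**Gene selection against negative probes.** Negative probes estimate
background capture. Their counts are pooled over probes and AOIs into a
single mean `m` and SD `s` — one global limit of detection, the simplest
stable reading. A gene survives if its mean exceeds `m + k·s` or its
variance exceeds `(m + k·s)^2` (`k = 2`). The variance arm is compared on
the squared scale so both rules live in consistent units; it exists to
rescue genes expressed strongly but only in a small subpopulation of AOIs,
whose mean may sit in the background.

**Quantile normalization.** Classic order-statistic averaging: every
column adopts the across-AOI mean of the sorted values; a tie group takes
the mean of the reference quantiles it spans. Implemented directly (rank
with min/max tie bounds over a cumulative sum of the reference) because
the tie-averaging convention makes two properties exact on tie-free data:
all columns share one multiset, and the map is idempotent. With ties these
hold up to tie-averaging only. The log2(x+1) transform afterwards is
required by everything downstream (log-ratio CNV tracks, Z-scores); the
pseudocount keeps zeros finite.

**Batch correction.** Parametric empirical-Bayes location/scale
adjustment via `sva::ComBat`, with treatment arm and tumor setting as
protected design columns. A covariate nested entirely within one batch is
dropped with a warning — effect and batch are then confounded and no
adjustment can separate them. Two things are worth knowing about the EB
model: a constant planted shift shared by all genes is removed essentially
exactly (the prior collapses onto the common value); and on noisy data the
correction slightly *overshoots*, so post-correction batch F-statistics
sit at or below their null — tests assert "no residual batch signal", not
F-statistics exactly at the null median.

**Copy-number inference.** Per gene, the query AOI's log2 expression minus
the mean over reference AOIs. The reference is the IBA1+ compartment of
the same cohort: no external reference is needed, and TAM segments are the
available non-malignant compartment, matching the reference-cell design of
expression-CNV methods. Profiles are median-centered per AOI *before*
clipping — centering first makes the profile invariant to any constant
shift of the AOI, which clipping first would break — then clipped to ±3
log2 units, smoothed by a centered 101-gene moving average within each
chromosome (the window truncates at chromosome edges, so no
cross-chromosome bleed), and re-centered. Chromosome scores are plain
means of the smoothed track; calls use strict thresholds
(gain > 0.15, loss < −0.15, log2 scale). A 2-group Ward clustering on the
(chr7, chr10) score pair is reported alongside the threshold calls as the
supervised grouping aid an analyst would inspect, but it never overrides
them. Marker-gene programs differ between query and reference and leak a
small composition bias into the log-ratios; smoothing over ~100 genes and
scoring whole chromosomes keeps that leak an order of magnitude below the
call thresholds provided chromosomes carry a few hundred genes each.

**Signature scores.** Centered-and-scaled ("aggregated Z") scoring: gene
Z-scores across the chosen population, averaged over a signature's genes.
Scores are population-relative, so the population is an explicit argument
— score within the set of AOIs you intend to compare (e.g. recurrent SOX2+
AOIs when contrasting treated vs untreated recurrences), not the whole
dataset. Zero-variance genes contribute 0 with a warning; signatures
losing more than half their genes to the expression filter warn as well.
Z-scores are computed at AOI level and then averaged per tumor (unweighted
over surviving AOIs); the alternative order — aggregate first, score
after — is a different estimand and is not the default.

**Pseudobulk differential expression.** AOIs of a tumor are summed
(pre-normalization counts) and tumors become the units, which respects the
design: AOIs within a tumor are pseudoreplicates. The test is a
negative-binomial Wald test with median-of-ratios size factors. Dispersion
is estimated per gene by Cox–Reid-adjusted profile likelihood, a
parametric trend `a0 + a1/mean` is fitted robustly across genes, and the
final dispersion is a log-scale weighted average with `prior_weight` on
the trend. The default `prior_weight = 1` (pure trended dispersion) is the
standard small-sample choice: with ~6 tumors per arm, gene-wise estimates
are noisy, and letting individual genes keep underestimated dispersions
inflates the extreme tail of the Wald statistic exactly where BH looks.
The null-calibration suite (20 simulated 6+6 cohorts, 2000 genes,
dispersion 0.1) pins this behavior. No independent filtering, outlier
replacement, or Cook's-distance policing: results are a deterministic
function of the counts, at the cost of robustness to single-tumor
outliers.

**Mixed models and contrasts.** Per-AOI scalar responses (signature
scores, area fractions) are modelled as `y ~ group + (1 | patient)` by
REML (`lmerTest`), with Satterthwaite degrees of freedom and
estimated marginal means with Tukey adjustment (`emmeans`). In a balanced
paired two-group design this reproduces the paired t-test exactly (df
`n − 1`), and Tukey with two groups is the unadjusted comparison — both
asserted in tests. The optimizer runs with tightened tolerances so that
equivalence holds to ~1e-8; a failed mixed fit falls back to OLS with a
warning.

**Exact Wilcoxon tests.** The signed-rank test drops zero differences,
midranks ties, and for n ≤ 25 computes the exact two-sided p
(`2·min(P(W ≤ w), P(W ≥ w))`, capped at 1) from the full null over sign
assignments via a shift algorithm on doubled midranks — doubling makes
midranks integral, so ties are handled exactly, which is why this is
implemented in the package rather than delegated (`stats::wilcox.test`
refuses exact p-values under ties or zeros). Larger n uses the
tie-corrected normal approximation. The rank-sum wrapper delegates to
`stats::wilcox.test`: exact when the pooled sample is ≤ 20 without ties,
normal approximation with tie correction otherwise. For seven pairs all
changing in one direction the exact two-sided p is 2/2^7 = 0.015625 — the
smallest value the design can produce.

**IHC positivity.** Boundary conventions are explicit: cells strictly
smaller than 20 µm² are removed (area exactly 20 is kept, following
"removing cells smaller than" semantics), and an included cell is positive
iff mean DAB OD strictly exceeds 0.3 (a cell exactly at threshold is
negative; no boundary rule is standard, so the strict convention is
adopted and documented). Tumor positivity is the unweighted mean of ROI
percentages, so a 200-cell ROI counts as much as a 2000-cell one — the
estimand is "typical regional positivity", not cell-level prevalence.
Whether the upstream table's area is nuclear or expanded-cell area is the
caller's contract; the module uses whatever it is given.

## The synthetic cohorts

`simulate_cohort()` draws counts from
`NB(mean = libsize × mixture, dispersion φ)` where the mixture is
`p·malignant + (1−p)·(0.7·oligodendrocyte + 0.3·TAM)` for SOX2+ AOIs
(`p` from the purity grid) and `0.15·oligodendrocyte + 0.85·TAM` for IBA1+
AOIs. Programs are disjoint planted gene modules elevated over a shared
baseline — this makes signature scores analytically predictable. CNV
dosage multiplies **all** chr7/chr10 genes of the malignant program (1.5×
and 0.5× by default), not just module genes, because that is what broad
events look like to a smoothing detector. Negative probes share the
background mean of unexpressed genes, which is what gives the 2-SD filter
its meaning. Batch effects are gene-wise log2 offsets (location) plus a
dispersion multiplier (scale) for each of two batches, assigned to tumors
alternately within arm × setting strata so batch is never confounded with
the biology.

Defaults mirror the study conditions: 30 patients, 90% with a matched
primary, two thirds treated at recurrence, 3 ROIs per tumor each yielding
a SOX2+ and an IBA1+ AOI, hallmark alterations in 90% of patients, and a
null treatment effect (planted effects are opt-in via `de_log2fc` /
`n_de_genes`). Sizes are desk-scale by choice: 3000 genes over 10
chromosomes keeps every chromosome above the 101-gene smoothing window
after gene filtering (~250 genes each) while a full run of the pipeline
stays under half a minute; the real panel is ~18k genes over 24
chromosomes, so per-chromosome gene density is of the same order. Values
the study does not report were fixed once at realistic levels and frozen:
marker modules elevated 3 log2 units (8-fold, the enrichment scale of
cell-type markers), a purity grid `{0, 0.5, …, 1}` in which zero-purity
AOIs are a ~14% minority (contamination is the exception in
density-selected cores, not the rule), NB dispersion 0.1, log-normal
library sizes (σ = 0.4).

What the generator does **not** emulate: spatial coordinates and
neighborhood structure, gradual purity mixtures beyond the grid,
probe-level variation within genes, UMI saturation, segmentation errors
that correlate across AOIs of one ROI, and continuous malignant-state
gradients (each tumor gets one dominant state). Passing the planted-truth
suites therefore shows the pipeline recovers the *kind* of structure the
study analyses under honest noise; it does not certify performance on real
tissue.

`simulate_ihc_cells()` draws per-cell OD from a two-component log-normal
mixture (negative ~0.08, positive ~0.6, σ_log = 0.25, so component overlap
across the 0.3 threshold is below 0.3% and planted fractions are
recoverable within binomial error) and areas log-normal around 40 µm² with
~8% under the 20 µm² limit.

## Numerical and degenerate-input choices

* Moving averages use cumulative sums; a brute-force O(n·w) loop is the
  test oracle (agreement to 1e-12).
* Quantile normalization of an all-zero column maps it, as one big tie, to
  the mean of the reference quantiles.
* `score_and_call()` on identical scores returns a single cluster with a
  warning rather than a degenerate dendrogram cut; a score exactly at a
  threshold is *not* a call.
* The NB GLM is fitted by damped Fisher scoring (steps capped at ±5 on the
  natural-log scale, fixed iteration count) — deterministic and safe for
  group means of zero, which are floored at half a count.
* Wilcoxon: all-zero differences return p = 1 with a warning; `n = 1`
  gives p = 1 (the two-sided floor is 2/2).
* ROIs with no included cells are dropped with a warning; tumors with no
  valid ROI are absent from output rather than NaN.

## Known limitations

* The hallmark caller scores whole chromosomes; focal events (e.g. EGFR
  amplification) are out of scope, as is HMM-based subclone inference.
* DE supports exactly two conditions with no covariates — matching the
  treated-vs-untreated recurrence contrast it exists for.
* The purity thresholds (`z_nonmalig = 1`, `z_malig = 0`) encode an
  analyst-supervised boundary; they are exposed as parameters and their
  defaults are validated only against the synthetic cohorts' planted
  truth.
* ComBat's EB shrinkage preserves per-gene grand means only approximately;
  the package asserts shift removal and absence of residual batch signal,
  not exact mean preservation.
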