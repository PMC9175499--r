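---
title: "Scoring p16-positive fibroblastic foci: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring p16-positive fibroblastic foci: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p16foci)
```

## The problem

Fibroblastic foci are the histologic engine of usual interstitial pneumonia
(UIP), but their identification on H&E sections is subjective. A subset of
foci stains for the cell-cycle inhibitor p16, marking senescent
fibroblast/epithelial collectives, and the burden of such p16-positive foci —
expressed as a density per 100 mm² of annotated lung tissue — behaves as a
quantitative, reproducible biomarker: it discriminates idiopathic pulmonary
fibrosis (IPF) from other fibrotic interstitial lung disease and stratifies
lung-transplant-free survival. `p16foci` implements the full quantitative
workflow downstream of the pathologist's annotations: slide quantification,
cohort-level diagnostics, survival modelling, and GeoMX-style digital spatial
profiling (DSP) of focus versus fibrosis versus normal regions of interest
(ROIs), together with seeded synthetic-data generators that make every stage
testable without patient data.

Pixel-level image analysis is deliberately out of scope: the foci are
human-annotated, and the package's unit of input is the annotation file, not
the slide image.

## Slide quantification

A `calibrated_slide` couples annotation geometry (tissue polygons with
optional holes, plus point marks for foci) to an isotropic microns-per-pixel
calibration. Coordinates are 0-based pixels, y down, the convention of
common whole-slide annotation exports. The quantities are elementary but the
conventions matter:

* **Area** is the shoelace formula per ring, holes subtracted, converted by
  `mpp² / 10⁶` to mm². Overlapping tissue regions are summed *without*
  polygon union — the input contract expects disjoint annotations, as
  QuPath-style exports produce, and the reader warns when bounding boxes
  overlap rather than silently resolving the overlap.
* **Containment** is even–odd ray casting; points on a boundary (outer or
  hole) count as in-tissue. The inclusive rule is a deterministic tie-break
  that keeps marginal subpleural foci in the count.
* **Density** is `100 × n_foci / area_mm2`, and the p16-high class is
  `density > cutoff` with the low class inclusive of the boundary
  (`density ≤ cutoff` is low). The default cutoff of 2.1 foci/100 mm² is a
  configuration value, not a constant, so an ROC-derived cutoff can replace
  it.
* Polygonal focus annotations are expected to be reduced to centroids
  upstream; a count needs no shape. Marks outside all tissue are excluded
  and tallied (`n_foci_excluded`), never silently dropped.
* Anisotropic calibrations are rejected: the supported scanners produce
  square pixels, and accepting two scale factors would silently break the
  density unit.

## Cohort statistics

Diagnostic performance of a binary rule (any-foci, or p16-high) against the
multi-disciplinary diagnosis is a 2×2 table with exact Clopper–Pearson 95%
intervals; the source report did not state its interval method, and the
exact interval is the conservative default at these sample sizes.

The ROC implementation follows the "accuracy = sensitivity + specificity"
criterion for cutoff selection (a Youden-type rule). Conventions chosen
where the criterion alone under-determines the answer: thresholds are
midpoints between consecutive distinct observed values plus ∓∞ sentinels;
positivity is `value > threshold`; AUC uses the Mann–Whitney rank identity
with half-credit for ties (and is verified in the tests against brute-force
pair counting); cutoff ties resolve toward the smallest threshold, the most
inclusive rule.

The HRCT visual fibrosis score is the sum of 0–4 extent grades over scan
levels × hemithoraces as a percentage of the maximum, 8 per scan; with the
standard four levels the denominator is 32.

One published inconsistency is worth recording: the specificity of p16-high
for IPF is quoted as 97.6% in the source text, but the per-diagnosis table
yields 33/34 = 97.1%. The package reports what it computes from the counts;
the discrepancy is documented here and not reproduced. Similarly, the text
quotes a "protective" antifibrotic hazard ratio of 2.64 while the
accompanying table prints 0.28 (0.10–0.66); the table is the
self-consistent source and is what the generators and tests use.

## Transplant-free survival

The endpoint is composite: death or lung transplantation, whichever comes
first; living subjects are censored. Transplantation is an *event*, not a
censoring — treating it as censoring would misstate transplant-free
survival, and the published 64% combined incidence is only reproducible
under the composite definition. Records with non-positive follow-up are
rejected with a log message.

Kaplan–Meier curves use the product-limit estimator with Greenwood standard
errors; the log-rank test uses the pooled-event-time hypergeometric
variance. The Cox model is fitted by Newton–Raphson on the partial
likelihood with Efron's tie correction by default (Breslow behind a flag for
cross-checking; with continuous times the two coincide, which the tests
assert to 1e-10). Convergence is declared when the largest score component
falls below 1e-8, capped at 50 iterations with step-halving; divergent
coefficient paths — monotone likelihood under perfect separation — are
flagged via `converged = FALSE` and a warning rather than returned silently.
Confidence intervals are Wald on the log-hazard scale, `exp(β ± 1.96·se)`,
again because the source does not state its method and Wald is what its
printed interval widths are consistent with. The test suite cross-checks
coefficients and standard errors against an independent fitter
(`survival::coxph`) on tied and untied data, and against a brute-force grid
of the exact partial likelihood on a four-subject example.

The multivariate model mirrors the published one: p16-high and antifibrotic
treatment, fitted on the IPF subset after removing subjects flagged with
post-biopsy lung cancer (a column in the cohort table, not an inference).
Age, sex, BMI, FVC% and DLCO% are carried as screening covariates.

## Digital spatial profiling

The DSP module ingests a genes × ROIs count matrix (the study design:
12 fibroblastic-focus, 6 dense-fibrosis, 6 normal ROIs from a ~1825-gene
panel with 31 housekeeping genes) and applies:

* **QC**: ROIs below a total-count floor and genes below a mean-count floor
  are dropped with logging; housekeeping genes are never dropped; removing
  an entire ROI class is an error, not a warning. The source's "outlier
  probe" criterion is never defined there and is not implemented.
* **Normalization**: housekeeping scaling (per-ROI factor = geometric mean
  of housekeeping counts over the study geometric mean of those means) or
  Q3 scaling (75th percentile, linear interpolation, over the geometric mean
  of Q3s). Both are idempotent and invariant to global rescaling — tested
  properties. Zero housekeeping counts are a hard error naming the gene and
  ROI; silent pseudo-count imputation would bias the factors. Housekeeping
  normalization is the default input to differential expression; the choice
  is recorded in the output metadata.
* **Differential expression**: Welch's t on log2(count + 1) per gene
  (Mann–Whitney behind a flag), Benjamini–Hochberg adjustment over all
  tested genes, selection at q < 0.05 with linear fold change ≥ 1.5
  inclusive, in either direction. The test statistic was not stated at the
  source; Welch on the log scale is the convention for small-n ROI
  comparisons on this platform. The q-value is implemented as BH-adjusted p
  (the "minimal false discovery rate" definition matches the step-up
  estimate); Storey's estimator is out of scope. The +1 pseudo-count keeps
  zeros finite on the log scale.
* **Clustering**: average linkage on 1 − uncentered Pearson correlation,
  the Cluster 3.0 convention, with Newick export; zero vectors are an error
  because the uncentered correlation is undefined for them. Heat-map export
  scales each gene by its maximal absolute centered value into [−1, 1].
* **PCA**: log2, per-gene centering, SVD of the ROI profiles; components
  ordered by variance with the sign convention that the largest-magnitude
  loading is positive (verified against a direct covariance
  eigendecomposition in the tests).
* **GSEA**: weighted Kolmogorov–Smirnov running sum with weight exponent 1
  on |score|, where the deviation is taken against the uniform position CDF
  i/N; the enrichment score is the extremum of largest magnitude (a
  single top-ranked gene in an equal-score list of N therefore scores
  1 − 1/N). Significance uses *gene-set* permutation — sets of matching size
  resampled from the ranked universe under a mandatory seed — because 6–12
  ROIs per class cannot support phenotype permutation. NES divides ES by the
  mean |permuted ES| of matching sign; the batch interface pools permuted
  NES for the standard FDR-q ratio estimate.

The "focus versus fibrosis-or-normal" contrast behind the published 97-gene
signature is implemented as focus versus pooled others, with pairwise
contrasts available.

## Synthetic data: what it emulates, and what it does not

The generators define the study conditions used throughout the tests:

* `gen_cohort()` defaults: n = 86; diagnosis mix 52/16/11/6/1; IPF density
  zero-inflated lognormal with P(zero) = 12/52, median 1.97 (meanlog =
  log 1.97) and sdlog = 0.9, chosen so the positive-case quantiles at n ≈ 40
  roughly span the published 0.43–26.32 range (per-case densities are
  unpublished, so only these summaries are matched); non-IPF cases positive
  with probability 3/34 and then weakly so. Survival times are exponential
  with log-hazard log(0.02/month) + log(2.40)·p16_high +
  log(0.28)·antifibrotic (the published multivariate estimates), censoring
  exponential at 0.019/month; these rates give roughly the published 64%
  combined event incidence and ~35% censoring. The exponential baseline is a
  deliberate simplification — it permits closed-form sampling and unbiased
  Cox recovery, which is exactly what the recovery experiments need.
  Transplant is drawn among events at the published 13:42 ratio.
* `gen_dsp()` defaults: 1825 genes, 31 housekeeping (stable, higher
  baseline), 12/6/6 ROIs, negative-binomial counts with dispersion 0.1
  (typical targeted-panel overdispersion), lognormal depth factors (sdlog
  0.25), and 97 planted focus-up genes at log2 fold change 2, labelled by
  readable families (CDK-inhibitor-, metalloproteinase-, collagen-like).
* `gen_slide()` emits exact-area rectangles with uniformly placed foci, so
  quantification can be checked against ground truth to machine precision.

What the synthetic data do **not** emulate: real annotation geometry
(concavities, fragmented parenchyma, holes drawn by pathologists),
inter-observer variability in focus calling, non-proportional hazards or
informative censoring, probe-level chemistry, gene–gene correlation beyond
the planted signature, and batch structure across cases. Passing tests
therefore demonstrate algorithmic correctness and calibrated statistical
behaviour under the stated models — not clinical validity on real slides.

## Problem sizes and numerical choices

The recovery experiments use 50 replicates of n = 2000 cohorts for the Cox
hazard-ratio checks (mean estimate compared within ±0.15 and 3 Monte-Carlo
SEs of the generating value) and a single n = 1000 cohort for the ROC cutoff
check (±0.25); the log-rank type-I calibration uses 200 null cohorts at
n = 86. These sizes give Monte-Carlo standard errors comfortably inside the
tolerances while keeping the whole suite fast. Other fixed numerics:
score-convergence tolerance 1e-8 and 50 Newton iterations with step-halving
for the Cox fitter; |β| > 20 treated as divergence; BH is used exactly as
`p.adjust` defines it; Q3 uses the interpolated (type-7) quantile; the
geometry boundary tolerance is 1e-9 relative to coordinate magnitude.

## Known limitations

* No polygon union: overlapping tissue annotations double-count area (by
  contract, with a warning).
* No competing-risks decomposition of the composite endpoint and no
  time-varying covariates.
* GSEA's gene-set permutation answers "is this set ranked unusually high
  relative to random sets of its size", which is weaker than phenotype
  permutation against inter-ROI correlation; with 24 ROIs this is the only
  honest option.
* The q-value is BH, not Storey; for the ~1825-gene panel the difference is
  conservative.
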