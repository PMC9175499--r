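# p16foci

Quantitative scoring of cellular senescence in fibrotic interstitial lung
disease (ILD). Fibroblastic foci that stain for the senescence marker p16
can be annotated on digitized surgical lung biopsies; their density —

```
density = 100 × (number of p16-positive foci) / (annotated tissue area in mm²)
```

— dichotomized at 2.1 foci per 100 mm² (p16-low ≤ 2.1 < p16-high), acts as a
biomarker that is specific for idiopathic pulmonary fibrosis (IPF) and
stratifies lung-transplant-free survival. `p16foci` is an R package for the
full analysis pipeline downstream of the pathologist's annotations:

* **Slide quantification** — GeoJSON-dialect annotation files (tissue
  polygons with holes + focus point marks, µm/px calibration) to foci
  counts, tissue area, density and p16 class (shoelace area, even–odd
  containment with inclusive boundaries).
* **Cohort statistics** — descriptive summaries, sensitivity/specificity of
  p16 scores against the multidisciplinary diagnosis with exact binomial
  CIs, the HRCT visual fibrosis score, and ROC analysis with an
  accuracy-maximizing (sensitivity + specificity) cutoff.
* **Survival** — the death-or-transplant composite endpoint, Kaplan–Meier
  curves with Greenwood errors, the log-rank test, and a Newton–Raphson Cox
  partial-likelihood fitter (Efron/Breslow ties) for models such as
  `~ p16_high + antifibrotic`.
* **Digital spatial profiling** — GeoMX-style ROI count matrices:
  housekeeping and upper-quartile normalization, Welch-on-log2 differential
  expression with BH q-values and the q < 0.05 & FC ≥ 1.5 selection rule,
  average-linkage clustering on uncentered correlation, PCA, and seeded
  gene-set enrichment (GMT input) with gene-set permutation.
* **Synthetic data** — seeded generators for slides, cohorts and DSP
  matrices with serialized ground truth, so the whole pipeline is testable
  without patient data.

Intended users: pulmonary pathology and ILD research groups wanting a
reproducible, scriptable version of this scoring workflow, and
methodologists who need the generators for benchmarking.

## Worked example

```r
library(p16foci)

# a synthetic slide with known ground truth: 8 foci on 250 mm² of tissue
g <- gen_slide(seed = 7, tissue_area_mm2 = 250, n_foci_inside = 8, mpp = 0.5)
quantify_slide(g$slide)
#> Slide synthetic_7: 8 foci in 250.000 mm^2 tissue -> 3.20 per 100 mm^2 (p16-high)

# a synthetic 86-subject cohort with the published structure
co <- gen_cohort(cohort_sim_spec(n = 86), seed = 7)$cohort
diagnostic_performance(co, co$density > 0, co$diagnosis == "IPF")
#> sensitivity 78.4% (95% CI 64.7-88.7), specificity 97.1% (CI 85.1-99.9)
#> tp fp tn fn
#> 40  1 34 11

rec <- ltx_free_records(co)              # death-or-transplant endpoint
cox_fit(rec, c("p16_high", "antifibrotic"))
#> Cox proportional hazards (efron ties), 86 subjects, 39 events
#>                 coef     HR lower95 upper95      p
#> p16_high      0.6673 1.9490  0.9543  3.9805 0.0670
#> antifibrotic -1.4223 0.2411  0.1020  0.5699 0.0012
```

The quantified density is exactly `100 × 8 / 250 = 3.2` per 100 mm², above
the 2.1 cutoff, hence p16-high. In the cohort, any-foci positivity is
sensitive and highly specific for IPF (the generator plants foci almost
exclusively in IPF cases), and the Cox fit recovers the generator's
hazard structure: p16-high is deleterious (HR ≈ 1.9 here, generating value
2.40 — an n = 86 cohort is noisy) while antifibrotic treatment is protective
(HR ≈ 0.24, generating value 0.28). At n = 2000 the estimates settle onto
the generating values (see the tests).

Annotation files are read with `read_slide_geojson()`, cohort tables with
`read_cohort()`, DSP inputs with `read_dsp()`/`read_gmt()`; `run_quantify()`,
`run_study()` and `run_dsp()` assemble the full per-module output bundles
(TSV/JSON plus a run manifest). A thin command-line wrapper ships in
`inst/cli/p16foci`.

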